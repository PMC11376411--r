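# Fragment-based ANI with aligned-coverage reporting.

# Cut contigs into consecutive non-overlapping windows of fragment_len,
# dropping tails shorter than fragment_len.
cut_fragments <- function(contigs, fragment_len) {
  frags <- character(0)
  for (s in as.character(contigs)) {
    n <- nchar(s)
    if (n < fragment_len) next
    starts <- seq(1, n - fragment_len + 1, by = fragment_len)
    frags <- c(frags, substring(s, starts, starts + fragment_len - 1))
  }
  frags
}

# Best seed diagonal of `fragment` against pre-matched seed hit table.
# hits: data.frame(diag, contig, strand); returns the modal row group.
best_diagonal <- function(hits) {
  key <- paste(hits$contig, hits$strand, hits$diag)
  tab <- sort(table(key), decreasing = TRUE)
  top <- names(tab)[1]
  hits[key == top, , drop = FALSE][1, ]
}

#' Fragment-based average nucleotide identity (ANI) of two genomes
#'
#' The smaller genome is cut into consecutive `fragment_len` bp fragments
#' (tails dropped). Each fragment is placed in the larger genome by exact
#' k-mer seeding (seeds sampled along the fragment, matched on both
#' strands), then aligned to the best-supported window with a gapped
#' global-local alignment. Per-fragment identity is the fraction of matching
#' bases over aligned non-gap columns; fragments reaching
#' `min_fragment_identity` count as matched. ANI is the mean identity of
#' matched fragments (x100) and coverage the matched fraction of fragments.
#' Pairs with no matched fragment report `ani = NA` and coverage 0 and are
#' treated as different species downstream.
#'
#' @param a,b `genome_record` objects carrying sequences.
#' @param fragment_len Fragment length in bp (default 1000, >= 100).
#' @param min_fragment_identity Identity floor for a fragment to count as
#'   matched (default 0.8).
#' @param seed_len Exact seed length (default 15).
#' @param seed_step Spacing of seeds along a fragment (default 50).
#' @param band Window margin in bp around the seeded diagonal (default 60).
#' @return A one-row data.frame with `genome_a`, `genome_b`, `ani`
#'   (percent or `NA`), `coverage` (fraction of fragments of the smaller
#'   genome), `n_fragments`, and `fragmented` (which genome was cut).
#' @export
fragment_ani <- function(a, b, fragment_len = 1000, min_fragment_identity = 0.8,
                         seed_len = 15, seed_step = 50, band = 60) {
  if (fragment_len < 100) stopf("fragment_len must be >= 100")
  for (g in list(a, b))
    if (!inherits(g, "genome_record") || is.null(g$sequence))
      stopf("fragment_ani needs genome_record objects with sequences")
  # fragment the smaller genome
  if (a$total_length <= b$total_length) { qry <- a; sub <- b } else { qry <- b; sub <- a }
  if (qry$total_length < fragment_len)
    stopf("genome %s is shorter than fragment_len", qry$genome_id)
  frags <- cut_fragments(qry$sequence, fragment_len)
  n_frag <- length(frags)
  if (!n_frag) stopf("no fragments produced for %s", qry$genome_id)

  sub_fwd <- as.character(sub$sequence)
  sub_rev <- as.character(Biostrings::reverseComplement(sub$sequence))

  # seeds: equal-width exact k-mers sampled along each fragment
  offs <- seq(1, fragment_len - seed_len + 1, by = seed_step)
  seed_seq <- unlist(lapply(frags, function(f) substring(f, offs, offs + seed_len - 1)))
  seed_frag <- rep(seq_len(n_frag), each = length(offs))
  seed_off <- rep(offs, times = n_frag)
  ok <- !grepl("[^ACGT]", seed_seq)
  hit_tab <- NULL
  if (any(ok)) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq[ok]))
    idx_map <- which(ok)
    collect <- function(subject_list, strand) {
      out <- list()
      for (ci in seq_along(subject_list)) {
        m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject_list[[ci]]))
        st <- Biostrings::startIndex(m)
        for (pi in seq_along(st)) {
          if (is.null(st[[pi]]) || !length(st[[pi]])) next
          gi <- idx_map[pi]
          out[[length(out) + 1]] <- data.frame(
            frag = seed_frag[gi],
            diag = st[[pi]] - seed_off[gi] + 1,
            contig = ci, strand = strand)
        }
      }
      out
    }
    hit_tab <- do.call(rbind, c(collect(sub_fwd, "+"), collect(sub_rev, "-")))
  }

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  identities <- rep(NA_real_, n_frag)
  if (!is.null(hit_tab)) {
    for (fi in unique(hit_tab$frag)) {
      h <- best_diagonal(hit_tab[hit_tab$frag == fi, , drop = FALSE])
      subject <- if (h$strand == "+") sub_fwd[[h$contig]] else sub_rev[[h$contig]]
      from <- max(1, h$diag - band)
      to <- min(nchar(subject), h$diag + fragment_len - 1 + band)
      if (to - from + 1 < fragment_len / 2) next
      window <- substr(subject, from, to)
      aln <- tryCatch(
        Biostrings::pairwiseAlignment(frags[fi], window, type = "global-local",
                                      substitutionMatrix = submat,
                                      gapOpening = 5, gapExtension = 2),
        error = function(e) NULL)
      if (is.null(aln)) next
      nm <- Biostrings::nmatch(aln)
      nmm <- Biostrings::nmismatch(aln)
      if (nm + nmm > 0) identities[fi] <- nm / (nm + nmm)
    }
  }
  matched <- !is.na(identities) & identities >= min_fragment_identity
  data.frame(genome_a = a$genome_id, genome_b = b$genome_id,
             ani = if (any(matched)) 100 * mean(identities[matched]) else NA_real_,
             coverage = sum(matched) / n_frag,
             n_fragments = n_frag,
             fragmented = qry$genome_id,
             stringsAsFactors = FALSE)
}

#' Pairwise fragment ANI over a set of genomes
#'
#' @param genomes Named list of `genome_record` objects.
#' @param pairs Optional two-column matrix/data.frame of genome-id pairs to
#'   compare; defaults to all unordered pairs.
#' @param ... Passed to [fragment_ani()].
#' @return A data.frame, one row per compared pair.
#' @export
fragment_ani_matrix <- function(genomes, pairs = NULL, ...) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- ids
  if (is.null(pairs)) {
    if (length(ids) < 2)
      return(data.frame(genome_a = character(), genome_b = character(),
                        ani = numeric(), coverage = numeric()))
    pairs <- t(utils::combn(ids, 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    fragment_ani(genomes[[pairs[i, 1]]], genomes[[pairs[i, 2]]], ...)
  })
  do.call(rbind, rows)
}
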