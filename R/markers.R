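# Species-specific marker-gene selection: coreness/uniqueness candidate
# scoring, 150 bp fragment remapping, and marker database export.

#' Construct a pangenome object
#'
#' A per-species gene-family presence/absence and copy-count matrix with
#' family metadata, in the layout produced by standard pangenome tools
#' (family rows, conspecific genome columns).
#'
#' @param species_id Species label.
#' @param presence Binary matrix, families x genomes, with dimnames.
#' @param copy_count Integer matrix of the same shape (defaults to
#'   `presence`).
#' @param length_aa Named numeric vector: protein length per family (aa).
#' @param dna Named [Biostrings::DNAStringSet]: representative DNA allele
#'   per family.
#' @return An object of class `pangenome`.
#' @export
pangenome <- function(species_id, presence, copy_count = NULL,
                      length_aa = NULL, dna = NULL) {
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stopf("presence matrix needs family rownames and genome colnames")
  if (is.null(copy_count)) copy_count <- presence
  if (any(copy_count < presence))
    stopf("copy_count must be >= presence elementwise")
  structure(list(species_id = species_id,
                 presence = (presence > 0) * 1L,
                 copy_count = copy_count,
                 length_aa = length_aa, dna = dna),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome> %s: %d families x %d genomes\n", x$species_id,
              nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

#' Coreness of a gene family
#'
#' The proportion of a species' conspecific genomes containing the family.
#'
#' @param p A `pangenome`.
#' @param family_id One or more family ids; default all families.
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
coreness <- function(p, family_id = rownames(p$presence)) {
  unknown <- setdiff(family_id, rownames(p$presence))
  if (length(unknown))
    stopf("unknown family id(s): %s", paste(unknown, collapse = ", "))
  rowSums(p$presence[family_id, , drop = FALSE]) / ncol(p$presence)
}

#' Cross-species family index
#'
#' @param pangenomes List of `pangenome` objects covering the catalog.
#' @return Named list: family id -> character vector of species whose
#'   pangenome contains it.
#' @export
build_family_index <- function(pangenomes) {
  idx <- list()
  for (p in pangenomes) {
    fams <- rownames(p$presence)[rowSums(p$presence) > 0]
    for (f in fams) idx[[f]] <- union(idx[[f]], p$species_id)
  }
  idx
}

#' Uniqueness of a gene family
#'
#' The number of distinct species whose pangenome contains the family
#' (the family's own species included), per the cross-species index.
#'
#' @param family_id Family id(s).
#' @param index Index from [build_family_index()].
#' @return Named integer vector (>= 1 for families present anywhere).
#' @export
uniqueness <- function(family_id, index) {
  vapply(family_id, function(f) length(index[[f]]), integer(1))
}

#' Marker-gene candidates for one species
#'
#' Retains families with protein length in \[`min_len`, `max_len`\] aa,
#' mean copies per containing genome below `max_copies`, coreness at least
#' `coreness_large` when the species has more than `large_n` conspecific
#' genomes (else `coreness_small`), and uniqueness at most
#' `uniqueness_max`. At most `cap` candidates are kept, ranked by
#' (uniqueness ascending, coreness descending, length descending,
#' family id). For a single-genome species every family is trivially core.
#'
#' @param p A `pangenome`.
#' @param index Cross-species index from [build_family_index()].
#' @param min_len,max_len Protein length bounds in aa (150, 1500).
#' @param max_copies Mean-copy ceiling (1.5, exclusive).
#' @param coreness_large,coreness_small Coreness floors (0.5 / 0.6).
#' @param large_n Conspecific-genome count above which the relaxed
#'   coreness floor applies (100).
#' @param uniqueness_max Maximum species count for a family (10).
#' @param cap Candidate cap per species (800).
#' @return data.frame: `family_id`, `species_id`, `coreness`,
#'   `uniqueness`, `length_aa`, `mean_copies`.
#' @export
candidate_markers <- function(p, index, min_len = 150, max_len = 1500,
                              max_copies = 1.5, coreness_large = 0.5,
                              coreness_small = 0.6, large_n = 100,
                              uniqueness_max = 10, cap = 800) {
  fams <- rownames(p$presence)
  core <- coreness(p)
  uniq <- uniqueness(fams, index)
  len <- p$length_aa[fams]
  containing <- rowSums(p$presence > 0)
  copies <- rowSums(p$copy_count) / pmax(containing, 1)
  n_genomes <- ncol(p$presence)
  core_min <- if (n_genomes > large_n) coreness_large else coreness_small
  keep <- len >= min_len & len <= max_len & copies < max_copies &
    core >= core_min & uniq <= uniqueness_max & containing > 0
  df <- data.frame(family_id = fams, species_id = p$species_id,
                   coreness = unname(core), uniqueness = unname(uniq),
                   length_aa = unname(len), mean_copies = unname(copies),
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- df[order(df$uniqueness, -df$coreness, -df$length_aa, df$family_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  head(df, cap)
}

#' Fragment a gene sequence into 150 bp segments
#'
#' Consecutive non-overlapping windows; a final window shorter than
#' `fragment_len` is dropped. A sequence shorter than `fragment_len`
#' yields an empty result with a warning.
#'
#' @param dna A single DNA sequence (character or `DNAString`).
#' @param fragment_len Window size in bp (default 150).
#' @return Character vector of fragments.
#' @export
fragment_genes <- function(dna, fragment_len = 150) {
  s <- as.character(dna)
  if (length(s) != 1) stopf("fragment_genes fragments one sequence at a time")
  n <- nchar(s)
  if (n < fragment_len) {
    warning("sequence shorter than fragment_len; no fragments produced",
            call. = FALSE)
    return(character(0))
  }
  starts <- seq(1, n - fragment_len + 1, by = fragment_len)
  substring(s, starts, starts + fragment_len - 1)
}

hamming_leq <- function(a, b, max_mm) {
  sum(charToRaw(a) != charToRaw(b)) <= max_mm
}

#' Map marker fragments against genomes
#'
#' A fragment hits a genome if a full-length ungapped match of identity at
#' least `min_identity` exists on either strand. Matching is by pigeonhole
#' seeding (with at most m mismatches over length L, at least one of m + 1
#' equal chunks is exact) followed by Hamming verification at the implied
#' offset.
#'
#' @param fragments Named character vector or `DNAStringSet` of equal-width
#'   fragments.
#' @param genomes Named `DNAStringSet` (one sequence per genome, contigs
#'   concatenated) or list of `genome_record` objects.
#' @param min_identity Identity floor over the full fragment (default
#'   0.95).
#' @return Logical matrix: fragments x genomes.
#' @export
map_fragments <- function(fragments, genomes, min_identity = 0.95) {
  frag_chr <- stats::setNames(as.character(fragments), names(fragments))
  if (is.null(names(frag_chr)))
    names(frag_chr) <- paste0("frag", seq_along(frag_chr))
  if (inherits(genomes, "list") &&
      all(vapply(genomes, inherits, logical(1), "genome_record"))) {
    gseq <- vapply(genomes, function(g)
      paste(as.character(g$sequence), collapse = ""), character(1))
    names(gseq) <- vapply(genomes, function(g) g$genome_id, character(1))
  } else {
    gseq <- stats::setNames(as.character(genomes), names(genomes))
  }
  L <- unique(nchar(frag_chr))
  if (length(L) != 1) stopf("fragments must have equal width")
  max_mm <- floor(L * (1 - min_identity))
  n_chunks <- max_mm + 1
  w <- L %/% n_chunks
  offs <- 1 + (seq_len(n_chunks) - 1) * w

  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  oriented <- c(frag_chr, rc(frag_chr))  # fwd then rc, same order
  n_frag <- length(frag_chr)
  chunk_seq <- unlist(lapply(oriented, function(f)
    substring(f, offs, offs + w - 1)), use.names = FALSE)
  chunk_frag <- rep(seq_along(oriented), each = n_chunks)
  chunk_off <- rep(offs, times = length(oriented))
  ok <- !grepl("[^ACGT]", chunk_seq)
  hits <- matrix(FALSE, n_frag, length(gseq),
                 dimnames = list(names(frag_chr), names(gseq)))
  if (!any(ok)) return(hits)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(chunk_seq[ok]))
  idx_map <- which(ok)

  for (gi in seq_along(gseq)) {
    subject <- gseq[[gi]]
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
    st <- Biostrings::startIndex(m)
    glen <- nchar(subject)
    for (pi in seq_along(st)) {
      pos <- st[[pi]]
      if (is.null(pos) || !length(pos)) next
      ci <- idx_map[pi]
      oi <- chunk_frag[ci]               # oriented fragment index
      fi <- ((oi - 1) %% n_frag) + 1     # underlying fragment
      if (hits[fi, gi]) next
      starts <- pos - chunk_off[ci] + 1
      starts <- unique(starts[starts >= 1 & starts + L - 1 <= glen])
      for (s0 in starts) {
        if (hamming_leq(substr(subject, s0, s0 + L - 1), oriented[[oi]],
                        max_mm)) {
          hits[fi, gi] <- TRUE
          break
        }
      }
    }
  }
  hits
}

#' Refine marker candidates by fragment remapping
#'
#' Per candidate gene, the remapped coreness is the fraction of its own
#' species' genomes hit by at least half of the gene's fragments; the
#' remapped uniqueness is 1 plus the number of other species with hit
#' genomes (for candidates of species with more than `large_n` conspecific
#' genomes, another species counts only when more than `large_frac` of its
#' genomes are hit). Genes with remapped coreness >= `coreness_min` and
#' uniqueness exactly 1 are kept; each species keeps at most `cap` genes,
#' the longest first (ties by family id).
#'
#' @param candidates data.frame from [candidate_markers()] (possibly
#'   several species).
#' @param hits Logical fragment x genome matrix from [map_fragments()];
#'   fragment names must be `species|family|i`.
#' @param genome_species Named character vector: genome id -> species id.
#' @param dna Named list (by species) of named `DNAStringSet`s with the
#'   candidate gene sequences.
#' @param coreness_min Remapped coreness floor (default 0.6).
#' @param large_n,large_frac Cross-species hit tolerance for large species
#'   (defaults 100 genomes, 1%).
#' @param cap Final marker cap per species (default 200).
#' @return Named list of `marker_set` objects, one per candidate species.
#' @export
refine_markers <- function(candidates, hits, genome_species, dna,
                           coreness_min = 0.6, large_n = 100,
                           large_frac = 0.01, cap = 200) {
  frag_meta <- do.call(rbind, strsplit(rownames(hits), "|", fixed = TRUE))
  frag_species <- frag_meta[, 1]
  frag_family <- frag_meta[, 2]
  species_of <- genome_species[colnames(hits)]
  out <- list()
  for (sp in sort(unique(candidates$species_id))) {
    cand <- candidates[candidates$species_id == sp, , drop = FALSE]
    own <- colnames(hits)[species_of == sp]
    n_own <- length(own)
    rows <- list()
    for (fam in cand$family_id) {
      sel <- frag_species == sp & frag_family == fam
      if (!any(sel)) next
      h <- hits[sel, , drop = FALSE]
      # per-genome gene presence: at least half the fragments hit
      present <- colSums(h) >= nrow(h) / 2
      re_core <- if (n_own) mean(present[own]) else 0
      genome_hit <- colSums(h) > 0
      others <- 0L
      for (osp in setdiff(unique(species_of), sp)) {
        og <- colnames(hits)[species_of == osp]
        frac <- mean(genome_hit[og])
        counts <- if (n_own > large_n) frac > large_frac else frac > 0
        if (counts) others <- others + 1L
      }
      re_uniq <- 1L + others
      seq_nt <- as.character(dna[[sp]][[fam]])
      rows[[fam]] <- data.frame(family_id = fam, dna = seq_nt,
                                length_nt = nchar(seq_nt),
                                coreness = re_core, uniqueness = re_uniq,
                                stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(family_id = character(), dna = character(),
                 length_nt = integer(), coreness = numeric(),
                 uniqueness = integer(), stringsAsFactors = FALSE)
    df <- df[df$coreness >= coreness_min & df$uniqueness == 1, , drop = FALSE]
    df <- df[order(-df$length_nt, df$family_id), , drop = FALSE]
    df <- head(df, cap)
    rownames(df) <- NULL
    out[[sp]] <- structure(list(species_id = sp, markers = df),
                           class = "marker_set")
  }
  out
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s: %d marker(s)\n", x$species_id,
              nrow(x$markers)))
  invisible(x)
}

#' Select species-specific markers for a catalog
#'
#' Orchestrates [candidate_markers()], [fragment_genes()],
#' [map_fragments()] and [refine_markers()] over all species.
#'
#' @param pangenomes Named list of `pangenome` objects (names = species).
#' @param genomes Named `DNAStringSet` or list of `genome_record`s: the
#'   conspecific genomes of all species.
#' @param genome_species Named character vector: genome id -> species id.
#' @param fragment_len Fragment size in bp (default 150).
#' @param min_identity Mapping identity floor (default 0.95).
#' @param ... Further arguments to [candidate_markers()] and
#'   [refine_markers()] (`cap`, `coreness_min`, ...).
#' @return Named list of `marker_set` objects.
#' @export
select_markers <- function(pangenomes, genomes, genome_species,
                           fragment_len = 150, min_identity = 0.95, ...) {
  dots <- list(...)
  cand_args <- dots[intersect(names(dots),
                              names(formals(candidate_markers)))]
  ref_args <- dots[intersect(names(dots), names(formals(refine_markers)))]
  index <- build_family_index(pangenomes)
  cands <- do.call(rbind, lapply(pangenomes, function(p)
    do.call(candidate_markers, c(list(p, index), cand_args))))
  if (is.null(cands) || !nrow(cands)) stopf("no marker candidates found")
  frags <- character(0)
  dna <- list()
  for (sp in unique(cands$species_id)) {
    p <- pangenomes[[sp]]
    fams <- cands$family_id[cands$species_id == sp]
    dna[[sp]] <- p$dna[fams]
    for (fam in fams) {
      fr <- suppressWarnings(fragment_genes(p$dna[[fam]], fragment_len))
      if (length(fr))
        frags[paste(sp, fam, seq_along(fr), sep = "|")] <- fr
    }
  }
  hits <- map_fragments(frags, genomes, min_identity = min_identity)
  do.call(refine_markers,
          c(list(cands, hits, genome_species, dna), ref_args))
}

#' Export / read a marker database
#'
#' FASTA headers are `species_id|family_id|length`; the metadata TSV
#' carries final coreness and uniqueness. Species whose marker set is empty
#' are listed in a sidecar report and absent from the FASTA.
#'
#' @param sets Named list of `marker_set` objects.
#' @param fasta_path Output FASTA path.
#' @param meta_path Output metadata TSV path.
#' @param report_path Optional sidecar TSV listing species with zero
#'   markers.
#' @return Invisibly, the metadata data.frame.
#' @export
export_marker_db <- function(sets, fasta_path, meta_path,
                             report_path = NULL) {
  if (!length(sets)) stopf("no marker sets to export")
  sets <- sets[order(names(sets))]
  meta <- do.call(rbind, lapply(sets, function(ms) {
    if (!nrow(ms$markers)) return(NULL)
    data.frame(species_id = ms$species_id, ms$markers,
               stringsAsFactors = FALSE)
  }))
  if (is.null(meta)) stopf("every marker set is empty; nothing to export")
  seqs <- Biostrings::DNAStringSet(meta$dna)
  names(seqs) <- paste(meta$species_id, meta$family_id, meta$length_nt,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv_table(meta[, c("species_id", "family_id", "length_nt",
                           "coreness", "uniqueness")], meta_path)
  empty <- names(sets)[vapply(sets, function(ms) nrow(ms$markers) == 0,
                              logical(1))]
  if (!is.null(report_path))
    write_tsv_table(data.frame(species_id = empty), report_path)
  invisible(meta)
}

#' @rdname export_marker_db
#' @param fasta_path,meta_path Paths written by [export_marker_db()].
#' @export
read_marker_db <- function(fasta_path, meta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- read_tsv_table(meta_path, required = c("species_id", "family_id",
                                                 "length_nt", "coreness",
                                                 "uniqueness"))
  meta$dna <- as.character(seqs)
  out <- lapply(split(meta, meta$species_id), function(df) {
    df <- df[order(-df$length_nt, df$family_id),
             c("family_id", "dna", "length_nt", "coreness", "uniqueness")]
    rownames(df) <- NULL
    structure(list(species_id = df$family_id[0], markers = df),
              class = "marker_set")
  })
  for (sp in names(out)) out[[sp]]$species_id <- sp
  out
}
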