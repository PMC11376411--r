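# MinHash sketching and Mash-style distance estimation.

#' MinHash sketch of a genome
#'
#' The bottom-s sketch: the `s` smallest distinct 64-bit hash values over all
#' canonical k-mers of the genome (canonical = lexicographic minimum of a
#' k-mer and its reverse complement under 2-bit encoding). K-mers containing
#' non-ACGT characters are skipped. Deterministic for a fixed hash seed,
#' which is recorded in the sketch so databases are reproducible.
#'
#' @param g A `genome_record` with sequences, a `DNAStringSet`, or a
#'   character vector of contig sequences.
#' @param k K-mer length (default 21, <= 31).
#' @param s Sketch size: number of retained hashes (default 10000).
#' @param seed Hash seed (default 42).
#' @return An object of class `minhash_sketch` with fields `genome_id`,
#'   `k`, `s`, `seed` and the ascending `hashes`.
#' @export
minhash_sketch <- function(g, k = 21, s = 10000, seed = 42) {
  if (inherits(g, "genome_record")) {
    if (is.null(g$sequence)) stopf("genome %s carries no sequence", g$genome_id)
    contigs <- as.character(g$sequence)
    id <- g$genome_id
  } else if (is(g, "DNAStringSet")) {
    contigs <- as.character(g)
    id <- NA_character_
  } else {
    contigs <- as.character(g)
    id <- NA_character_
  }
  if (max(nchar(contigs)) < k)
    stopf("sequence shorter than k = %d", k)
  hashes <- sketch_hashes_cpp(contigs, as.integer(k), as.integer(s),
                              as.numeric(seed))
  structure(list(genome_id = id, k = as.integer(k), s = as.integer(s),
                 seed = as.numeric(seed), hashes = hashes),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("<minhash_sketch> %s: k=%d, s=%d, |hashes|=%d, seed=%g\n",
              ifelse(is.na(x$genome_id), "(unnamed)", x$genome_id),
              x$k, x$s, length(x$hashes), x$seed))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated from the merged bottom-s sketch of the
#' union: j = |intersection within bottom-s of the union| / |bottom-s of the
#' union|. The distance is d = -(1/k) ln(2j / (1 + j)); d = 1 is reported
#' when j = 0. The equivalent Mash ANI is 100 (1 - d).
#'
#' @param a,b `minhash_sketch` objects with identical `k`, `s` and `seed`.
#' @return A one-row data.frame (a `pairwise_comparison` row) with columns
#'   `genome_a`, `genome_b`, `jaccard`, `mash_d`, `ani`, `coverage`.
#' @export
mash_distance <- function(a, b) {
  if (!inherits(a, "minhash_sketch") || !inherits(b, "minhash_sketch"))
    stopf("mash_distance expects two minhash_sketch objects")
  if (a$k != b$k) stopf("sketch k mismatch: %d vs %d", a$k, b$k)
  if (a$s != b$s) stopf("sketch size mismatch: %d vs %d", a$s, b$s)
  if (a$seed != b$seed) stopf("sketch hash seed mismatch")
  merged <- sort(unique(c(a$hashes, b$hashes)))
  bottom <- merged[seq_len(min(a$s, length(merged)))]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- if (length(bottom)) shared / length(bottom) else 0
  d <- if (j <= 0) 1 else min(1, -log(2 * j / (1 + j)) / a$k)
  data.frame(genome_a = a$genome_id, genome_b = b$genome_id,
             jaccard = j, mash_d = d, ani = 100 * (1 - d),
             coverage = NA_real_, stringsAsFactors = FALSE)
}

#' All pairwise Mash distances for a set of sketches
#'
#' @param sketches A named list of `minhash_sketch` objects.
#' @return A data.frame with one row per unordered pair.
#' @export
mash_distance_matrix <- function(sketches) {
  n <- length(sketches)
  if (n < 2) return(data.frame(genome_a = character(), genome_b = character(),
                               jaccard = numeric(), mash_d = numeric(),
                               ani = numeric(), coverage = numeric()))
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    rows[[length(rows) + 1]] <- mash_distance(sketches[[i]], sketches[[j]])
  }
  do.call(rbind, rows)
}

#' Write / read sketches as TSV
#'
#' One row per sketch: `genome_id`, `k`, `s`, `seed`, and the hash list as a
#' comma-separated field. Round-trips exactly (hashes are 53-bit integers).
#'
#' @param sketches Named list of `minhash_sketch` objects.
#' @param path Output path.
#' @return `path` invisibly for the writer; a named list of sketches for the
#'   reader.
#' @export
write_sketches <- function(sketches, path) {
  df <- do.call(rbind, lapply(sketches, function(sk) {
    data.frame(genome_id = sk$genome_id, k = sk$k, s = sk$s, seed = sk$seed,
               hashes = paste(format(sk$hashes, scientific = FALSE, trim = TRUE),
                              collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write_tsv_table(df, path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  df <- read_tsv_table(path, required = c("genome_id", "k", "s", "seed", "hashes"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(genome_id = df$genome_id[i], k = as.integer(df$k[i]),
                   s = as.integer(df$s[i]), seed = as.numeric(df$seed[i]),
                   hashes = as.numeric(strsplit(df$hashes[i], ",")[[1]])),
              class = "minhash_sketch")
  })
  names(out) <- df$genome_id
  out
}
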