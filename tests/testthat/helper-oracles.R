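# Independent oracles used to cross-check the implementation, plus shared
# tiny fixtures. Kept deliberately naive.

options(catforge.verbose = FALSE)

# N50 by exhaustive candidate scan: the largest contig length L such that
# contigs of length >= L cover at least half the assembly.
oracle_n50 <- function(lens) {
  total <- sum(lens)
  cands <- sort(unique(lens), decreasing = TRUE)
  for (L in cands) if (sum(lens[lens >= L]) >= total / 2) return(L)
  min(lens)
}

# Exact canonical k-mer set of a sequence (string-level, no hashing).
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  unique(pmin(kmers, rc))
}

# Naive average-linkage agglomeration: repeatedly merge the pair of
# clusters with the smallest average pairwise distance until it exceeds
# the threshold. Returns a membership vector comparable up to relabelling.
oracle_average_linkage <- function(d, threshold) {
  ids <- rownames(d)
  clusters <- as.list(ids)
  repeat {
    if (length(clusters) == 1) break
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best_d) { best_d <- avg; best <- c(i, j) }
    }
    if (best_d > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(length(ids)); names(out) <- ids
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# Two partitions describe the same clustering (up to label permutation).
same_partition <- function(p, q) {
  p <- p[sort(names(p))]; q <- q[sort(names(q))]
  identical(as.integer(factor(p, levels = unique(p))),
            as.integer(factor(q, levels = unique(q))))
}

# Two-sided Fisher exact p by direct enumeration of the hypergeometric
# pmf from binomial coefficients (independent of stats::dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  denom <- choose(m + n, k)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / denom
  p0 <- choose(m, a) * choose(n, k - a) / denom
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# One genome_record wrapping a single-contig sequence.
make_record <- function(id, seq, completeness = 95, contamination = 1,
                        css = 0.1) {
  genome_record(id, sequence = Biostrings::DNAStringSet(setNames(seq, id)),
                completeness = completeness, contamination = contamination,
                css = css)
}
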