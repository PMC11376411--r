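# Annotation-rate accounting, bacterial GO filtering, GO-profile
# clustering homogeneity, shared proportions, Fisher/Bonferroni
# enrichment, lowest-common-rank specificity, and a fixture-scale greedy
# protein-family clusterer.

#' Annotation rate of a family set
#'
#' Percentage of families carrying at least one term in the given
#' namespace.
#'
#' @param families Character vector of family ids.
#' @param table Long-format annotation data.frame with columns
#'   `family_id`, `namespace`, `term`.
#' @param namespace Namespace to count (e.g. `"GO"`, `"KO"`, `"PFAM"`).
#' @return Percent (0-100).
#' @export
annotation_rate <- function(families, table, namespace) {
  if (!length(families)) stopf("families must be non-empty")
  annotated <- unique(table$family_id[table$namespace == namespace &
                                        !is.na(table$term) & table$term != ""])
  100 * mean(families %in% annotated)
}

#' Restrict GO annotations to bacteria-associated terms
#'
#' GO terms outside the whitelist, or in the exclusion set (by default the
#' uninformative cellular-component term GO:0110165 that sequence-based
#' predictors over-assign), are removed; other namespaces are untouched.
#'
#' @param table Long-format annotation data.frame.
#' @param bacterial_go_whitelist Non-empty character vector of allowed GO
#'   terms.
#' @param exclude Terms to drop even if whitelisted (default
#'   `"GO:0110165"`).
#' @return The filtered annotation data.frame.
#' @export
filter_bacterial_go <- function(table, bacterial_go_whitelist,
                                exclude = "GO:0110165") {
  if (!length(bacterial_go_whitelist)) stopf("whitelist must be non-empty")
  allowed <- setdiff(bacterial_go_whitelist, exclude)
  drop <- table$namespace == "GO" & !(table$term %in% allowed)
  table[!drop, , drop = FALSE]
}

#' Jaccard distance between two term sets
#'
#' 1 - |a intersect b| / |a union b|; two empty sets are at distance 0 by
#' convention, so unannotated genomes cluster together.
#'
#' @param terms_a,terms_b Character vectors (sets) of terms.
#' @return A fraction in \[0, 1\].
#' @export
go_jaccard_distance <- function(terms_a, terms_b) {
  a <- unique(terms_a); b <- unique(terms_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Taxonomic homogeneity across cluster counts
#'
#' Genomes are average-linkage clustered on pairwise Jaccard distances of
#' their term profiles; for each cluster count n the tree is cut to n
#' clusters (capped at the genome count) and homogeneity is the
#' size-weighted modal-label fraction (purity): sum over clusters of the
#' count of the most common taxon label, divided by the total genome
#' count. Purity is 1 when every cluster is label-pure, in particular at
#' n = genome count.
#'
#' @param profiles Named list: genome id -> character vector of terms.
#' @param labels Named character vector: genome id -> taxon label.
#' @param n_range Cluster counts to evaluate (default 1:200).
#' @return data.frame of class `homogeneity_curve`: `n_clusters`,
#'   `homogeneity`.
#' @export
homogeneity_curve <- function(profiles, labels, n_range = 1:200) {
  ids <- sort(names(profiles))
  if (length(ids) < 2) stopf("need at least two labelled genomes")
  labels <- labels[ids]
  if (any(is.na(labels))) stopf("every genome needs a taxon label")
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    d[i, j] <- d[j, i] <- go_jaccard_distance(profiles[[ids[i]]],
                                              profiles[[ids[j]]])
  }
  hc <- hclust(as.dist(d), method = "average")
  n_range <- n_range[n_range >= 1]
  pts <- vapply(n_range, function(k) {
    part <- cutree(hc, k = min(k, n))
    sum(vapply(split(labels, part), function(l) max(table(l)), numeric(1))) / n
  }, numeric(1))
  structure(data.frame(n_clusters = n_range, homogeneity = pts),
            class = c("homogeneity_curve", "data.frame"))
}

#' Shared proportion of two sets
#'
#' Reports the intersection size and the percentage of each set that is
#' shared, rounded to one decimal for reporting (raw fractions retained).
#'
#' @param set_a,set_b Vectors treated as sets.
#' @return List: `n_shared`, `pct_a`, `pct_b` (one-decimal percents),
#'   `frac_a`, `frac_b` (raw fractions), `n_a`, `n_b`.
#' @export
shared_proportion <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  ns <- length(intersect(a, b))
  fa <- if (length(a)) ns / length(a) else 0
  fb <- if (length(b)) ns / length(b) else 0
  list(n_shared = ns, pct_a = round(100 * fa, 1), pct_b = round(100 * fb, 1),
       frac_a = fa, frac_b = fb, n_a = length(a), n_b = length(b))
}

#' Two-sided Fisher exact p-value by hypergeometric enumeration
#'
#' For the 2x2 table (a, b; c, d) the p-value sums, over the support of
#' the hypergeometric distribution with the table's margins, every
#' probability not exceeding that of the observed table (with the
#' customary relative tolerance for ties).
#'
#' @param a,b,c,d Cell counts: group 1 with/without the term, group 2
#'   with/without. Vectorized.
#' @return Two-sided p-value(s).
#' @export
fisher_exact_p <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p0 <- dhyper(a, m, n, k)
    sum(probs[probs <= p0 * (1 + 1e-7)])
  }, a, b, c, d)
}

#' Term enrichment between two groups of species
#'
#' Per term, the 2x2 table counts species carrying / lacking the term in
#' each group; the two-sided Fisher exact p is computed by hypergeometric
#' enumeration and Bonferroni-adjusted over all tested terms (terms
#' present in at least one species of either group). The log2 fold change
#' compares carrier proportions with a small-sample shift eps = 1 / (2 x
#' group size) per group to avoid logs of zero; the sample odds ratio
#' (ad)/(bc) is reported alongside.
#'
#' @param presence1,presence2 Logical matrices (terms x species) or named
#'   lists term -> character vector of carrier species; both groups must
#'   be non-empty.
#' @return data.frame: `term`, `a`, `b`, `c`, `d`, `prop1`, `prop2`,
#'   `odds_ratio`, `log2_fold_change`, `p`, `p_adj`.
#' @export
term_species_enrichment <- function(presence1, presence2) {
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    terms <- names(x)
    species <- unique(unlist(x))
    m <- matrix(FALSE, length(terms), length(species),
                dimnames = list(terms, species))
    for (tm in terms) m[tm, x[[tm]]] <- TRUE
    m
  }
  m1 <- as_mat(presence1); m2 <- as_mat(presence2)
  n1 <- ncol(m1); n2 <- ncol(m2)
  if (!n1 || !n2) stopf("both species groups must be non-empty")
  terms <- sort(union(rownames(m1), rownames(m2)))
  a <- vapply(terms, function(tm)
    if (tm %in% rownames(m1)) sum(m1[tm, ]) else 0L, numeric(1))
  c_ <- vapply(terms, function(tm)
    if (tm %in% rownames(m2)) sum(m2[tm, ]) else 0L, numeric(1))
  tested <- (a + c_) > 0
  terms <- terms[tested]; a <- a[tested]; c_ <- c_[tested]
  b <- n1 - a; d <- n2 - c_
  p <- fisher_exact_p(a, b, c_, d)
  eps1 <- 1 / (2 * n1); eps2 <- 1 / (2 * n2)
  lfc <- log2((a / n1 + eps1) / (c_ / n2 + eps2))
  or <- (a * d) / (b * c_)
  data.frame(term = terms, a = a, b = b, c = c_, d = d,
             prop1 = a / n1, prop2 = c_ / n2,
             odds_ratio = or, log2_fold_change = lfc,
             p = p, p_adj = pmin(1, p * length(terms)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Lowest common taxonomic rank of a species set
#'
#' The deepest of the seven ranks at which all given species share a
#' single label; a singleton set is species-specific by definition.
#'
#' @param species_set Character vector of species ids.
#' @param taxonomy data.frame with `species_id` and the seven rank
#'   columns.
#' @return Rank name (`"species"` ... `"domain"`), or `"none"` when even
#'   the domain differs.
#' @export
lowest_common_rank <- function(species_set, taxonomy) {
  species_set <- unique(species_set)
  if (!length(species_set)) stopf("species set is empty")
  rows <- taxonomy[match(species_set, taxonomy$species_id), , drop = FALSE]
  if (any(is.na(rows$species_id)))
    stopf("species missing from taxonomy: %s",
          paste(species_set[is.na(rows$species_id)], collapse = ", "))
  if (length(species_set) == 1) return("species")
  for (r in rev(TAXONOMY_RANKS)) {
    labs <- rows[[r]]
    if (!any(is.na(labs)) && length(unique(labs)) == 1) return(r)
  }
  "none"
}

#' Greedy star clustering of sequences by identity
#'
#' A fixture-scale stand-in for large-scale linear-time protein
#' clustering: sequences are processed in (length descending, id) order;
#' each joins the first earlier centroid reaching `min_identity` over at
#' least `min_coverage` of the shorter sequence, otherwise it founds a new
#' family. Identity is matched bases over the shorter sequence's length in
#' a gapped global-local alignment.
#'
#' @param sequences Named character vector or `XStringSet`.
#' @param min_identity Identity threshold in \[0, 1\].
#' @param min_coverage Coverage floor over the shorter sequence (default
#'   0.8).
#' @return Named character vector: sequence id -> family (centroid) id.
#' @export
greedy_identity_cluster <- function(sequences, min_identity,
                                    min_coverage = 0.8) {
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  if (!length(seqs)) stopf("sequences must be non-empty")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  centroids <- character(0)
  fam <- setNames(character(length(seqs)), names(seqs))
  for (id in names(seqs)) {
    assigned <- NA_character_
    for (cid in centroids) {
      shorter <- seqs[[id]]; longer <- seqs[[cid]]
      cov_len <- nchar(shorter)
      aln <- tryCatch(
        Biostrings::pairwiseAlignment(shorter, longer, type = "global-local",
                                      substitutionMatrix = submat,
                                      gapOpening = 5, gapExtension = 2),
        error = function(e) NULL)
      if (is.null(aln)) next
      # the pattern (shorter sequence) is fully aligned under global-local,
      # so identity over its length subsumes the coverage gate
      aligned_frac <- (Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)) /
        cov_len
      ident <- Biostrings::nmatch(aln) / cov_len
      if (ident >= min_identity && aligned_frac >= min_coverage) {
        assigned <- cid
        break
      }
    }
    if (is.na(assigned)) {
      centroids <- c(centroids, id)
      assigned <- id
    }
    fam[id] <- assigned
  }
  fam[names(sequences)]
}
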