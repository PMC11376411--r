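# Two-tier species clustering, conspecific dereplication and
# representative selection.

# Number clusters deterministically: clusters appear in order of their
# smallest (lexicographically) member id.
relabel_partition <- function(part) {
  ids <- sort(names(part))
  part <- part[ids]
  seen <- character(0)
  out <- integer(length(part))
  names(out) <- ids
  for (i in seq_along(part)) {
    key <- as.character(part[i])
    if (!key %in% seen) seen <- c(seen, key)
    out[i] <- match(key, seen)
  }
  out
}

#' Average-linkage clustering cut at a distance threshold
#'
#' Agglomerative average-linkage clustering; the tree is cut so that items
#' whose merge height exceeds `threshold` stay in separate clusters.
#' Items are processed in lexicographic id order so the result does not
#' depend on input order; clusters are numbered by their smallest member id.
#' Missing distances should be encoded as the maximal distance by the
#' caller before constructing the matrix.
#'
#' @param d A symmetric numeric matrix with genome ids as dimnames (or a
#'   `dist` object with labels).
#' @param threshold Cut height (merges at height <= threshold are kept).
#' @return A named integer vector: cluster index per item.
#' @export
average_linkage <- function(d, threshold) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) stopf("distance matrix must carry ids as dimnames")
  ids <- sort(ids)
  if (length(ids) == 1) return(setNames(1L, ids))
  d <- d[ids, ids]
  hc <- hclust(as.dist(d), method = "average")
  relabel_partition(cutree(hc, h = threshold))
}

# Square distance matrix from a long pair table; unseen pairs get
# `missing` (maximal distance, so they can never merge).
pair_dist_matrix <- function(ids, pairs_a, pairs_b, dist_values, missing = 1) {
  m <- matrix(missing, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  keep <- pairs_a %in% ids & pairs_b %in% ids
  for (i in which(keep)) {
    m[pairs_a[i], pairs_b[i]] <- dist_values[i]
    m[pairs_b[i], pairs_a[i]] <- dist_values[i]
  }
  m
}

#' Preliminary clustering by Mash distance within taxonomic orders
#'
#' Genomes are grouped by their order-rank assignment (a genome without an
#' order forms its own group, so it can never co-cluster at this stage);
#' Mash distances are computed within groups only and average-linkage
#' clusters are cut at `threshold`.
#'
#' @param sketches Named list of `minhash_sketch` objects (names = genome
#'   ids).
#' @param taxonomy data.frame with `genome_id` and `order` columns, or
#'   `NULL` to treat all genomes as one group.
#' @param threshold Mash distance cut (default 0.2).
#' @return A named character vector: preliminary cluster label per genome.
#' @export
preliminary_cluster <- function(sketches, taxonomy = NULL, threshold = 0.2) {
  ids <- names(sketches)
  if (is.null(ids)) stopf("sketches must be a named list")
  orders <- setNames(rep("(all)", length(ids)), ids)
  if (!is.null(taxonomy)) {
    ord <- setNames(as.character(taxonomy$order), taxonomy$genome_id)
    orders[ids] <- ord[ids]
    miss <- is.na(orders)
    orders[miss] <- paste0("(missing-order)", ids[miss])
  }
  out <- character(0)
  for (grp in sort(unique(orders))) {
    gids <- sort(ids[orders == grp])
    if (length(gids) == 1) {
      part <- setNames(1L, gids)
    } else {
      cmp <- mash_distance_matrix(sketches[gids])
      m <- pair_dist_matrix(gids, cmp$genome_a, cmp$genome_b, cmp$mash_d,
                            missing = 1)
      part <- average_linkage(m, threshold)
    }
    out[names(part)] <- paste0(grp, "::", part)
  }
  labs <- relabel_partition(out)
  setNames(sprintf("P%03d", labs), names(labs))
}

#' Construct a species cluster object
#'
#' @param cluster_id Cluster label.
#' @param member_ids Genome ids in the cluster.
#' @param nonredundant_ids Non-redundant subset (default: all members until
#'   dereplication runs).
#' @param representative_id Chosen representative (or `NA`).
#' @param lineage Named character vector over the seven ranks, or `NULL`.
#' @return An object of class `species_cluster`.
#' @export
species_cluster <- function(cluster_id, member_ids, nonredundant_ids = member_ids,
                            representative_id = NA_character_, lineage = NULL) {
  stopifnot(all(nonredundant_ids %in% member_ids))
  structure(list(cluster_id = cluster_id,
                 member_ids = sort(member_ids),
                 nonredundant_ids = sort(nonredundant_ids),
                 representative_id = representative_id,
                 lineage = lineage),
            class = "species_cluster")
}

#' @export
print.species_cluster <- function(x, ...) {
  cat(sprintf("<species_cluster> %s: %d member(s), %d non-redundant, rep %s\n",
              x$cluster_id, length(x$member_ids), length(x$nonredundant_ids),
              x$representative_id))
  invisible(x)
}

# ANI-based distance with the coverage gate applied: pairs below the
# coverage floor, or with missing ANI, get the maximal distance 1.
ani_dist_matrix <- function(ids, comparisons, min_coverage) {
  ok <- !is.na(comparisons$ani) & !is.na(comparisons$coverage) &
    comparisons$coverage >= min_coverage
  pair_dist_matrix(ids,
                   comparisons$genome_a[ok], comparisons$genome_b[ok],
                   1 - comparisons$ani[ok] / 100, missing = 1)
}

#' Secondary (species-level) clustering by fragment ANI
#'
#' Within each preliminary cluster, genomes are average-linkage clustered on
#' distance 1 - ANI/100 and cut at `1 - ani_min/100`, so the conventional
#' 95% ANI species threshold maps to a 0.05 cut. Pairs whose aligned
#' coverage falls below `min_coverage`, or with no measurable ANI, are
#' assigned the maximal distance and can never merge.
#'
#' @param prelim Named character vector of preliminary labels per genome.
#' @param comparisons data.frame from [fragment_ani_matrix()].
#' @param ani_min Species ANI threshold in percent (default 95).
#' @param min_coverage Aligned-coverage floor (default 0.6).
#' @return A list of `species_cluster` objects, labelled `SP0001`, ... in
#'   order of smallest member id.
#' @export
secondary_cluster <- function(prelim, comparisons, ani_min = 95,
                              min_coverage = 0.6) {
  cut_h <- 1 - ani_min / 100
  out <- character(0)
  for (p in sort(unique(prelim))) {
    gids <- sort(names(prelim)[prelim == p])
    part <- if (length(gids) == 1) setNames(1L, gids) else
      average_linkage(ani_dist_matrix(gids, comparisons, min_coverage), cut_h)
    out[names(part)] <- paste0(p, "::", part)
  }
  labs <- relabel_partition(out)
  lapply(sort(unique(labs)), function(k) {
    species_cluster(sprintf("SP%04d", k), names(labs)[labs == k])
  })
}

#' Dereplicate conspecific genomes within a species cluster
#'
#' Members are sub-clustered by average linkage at `ani_min` (default
#' 99.9%) with an aligned-coverage floor of `min_coverage` (default 0.81,
#' the product of the minimum completeness fractions of two near-complete
#' genomes; see [conspecific_coverage_floor()]). One genome per subcluster
#' (the highest intactness score, ties to the smaller id) is retained as
#' non-redundant; the number of subclusters is the conspecific genome
#' count.
#'
#' @param cluster A `species_cluster`.
#' @param comparisons data.frame from [fragment_ani_matrix()].
#' @param quality data.frame with `genome_id`, `completeness`,
#'   `contamination`, `n50`.
#' @param ani_min Dereplication ANI threshold in percent (default 99.9).
#' @param min_coverage Coverage floor (default 0.81).
#' @param transform N50 transform for the intactness score.
#' @return The cluster with `nonredundant_ids` and `conspecific_count` set.
#' @export
dereplicate_conspecific <- function(cluster, comparisons, quality,
                                    ani_min = 99.9,
                                    min_coverage = conspecific_coverage_floor(),
                                    transform = "log10") {
  gids <- cluster$member_ids
  part <- if (length(gids) == 1) setNames(1L, gids) else
    average_linkage(ani_dist_matrix(gids, comparisons, min_coverage),
                    1 - ani_min / 100)
  scores <- intactness_lookup(quality, transform)
  keep <- vapply(sort(unique(part)), function(k) {
    ids <- sort(names(part)[part == k])
    ids[order(-scores[ids], ids)][1]
  }, character(1))
  cluster$nonredundant_ids <- sort(unname(keep))
  cluster$conspecific_count <- length(unique(part))
  cluster
}

# Named vector of intactness scores from a quality table.
intactness_lookup <- function(quality, transform = "log10") {
  setNames(intactness_score(quality$completeness, quality$contamination,
                            quality$n50, transform),
           quality$genome_id)
}

#' Select the representative genome of a species cluster
#'
#' The member with the highest intactness score S; ties broken by the
#' lexicographically smaller genome id.
#'
#' @inheritParams dereplicate_conspecific
#' @return The representative genome id.
#' @export
select_representative <- function(cluster, quality, transform = "log10") {
  scores <- intactness_lookup(quality, transform)
  ids <- sort(cluster$member_ids)
  ids[order(-scores[ids], ids)][1]
}
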