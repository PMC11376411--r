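# End-to-end catalog construction.

#' Run the catalog-construction pipeline
#'
#' Ordered stages: medium-quality gate (completeness >= 50, contamination
#' <= 5) -> near-complete gate (completeness >= 90) -> chimerism (CSS) gate
#' -> MinHash sketching -> preliminary Mash clustering within taxonomic
#' orders -> secondary fragment-ANI species clustering -> conspecific
#' dereplication -> representative selection. Retention counts are logged
#' per stage and returned with the catalog.
#'
#' @param genomes Named list of `genome_record` objects carrying sequences.
#' @param quality Optional data.frame (`genome_id`, `completeness`,
#'   `contamination`, optionally `css`, `n50`); defaults to the metrics on
#'   the records.
#' @param taxonomy Optional data.frame with `genome_id` and rank columns
#'   (at least `order`); `NULL` treats all genomes as one order group.
#' @param config Named list of overrides: `css_max` (0.45), `sketch_k`
#'   (21), `sketch_s` (10000), `sketch_seed` (42), `prelim_threshold`
#'   (0.2), `ani_min` (95), `min_coverage` (0.6), `derep_ani` (99.9),
#'   `nc_completeness` (90; the dereplication coverage floor is recomputed
#'   as its squared fraction), `fragment_len` (1000), `transform`
#'   ("log10").
#' @return An object of class `catforge_catalog` with elements `clusters`
#'   (list of `species_cluster`), `stage_counts`, `comparisons`, `quality`,
#'   `config`.
#' @export
run_catalog_pipeline <- function(genomes, quality = NULL, taxonomy = NULL,
                                 config = list()) {
  cfg <- utils::modifyList(list(
    css_max = 0.45, sketch_k = 21, sketch_s = 10000, sketch_seed = 42,
    prelim_threshold = 0.2, ani_min = 95, min_coverage = 0.6,
    derep_ani = 99.9, nc_completeness = 90, fragment_len = 1000,
    transform = "log10"), config)
  cfg$derep_coverage <- conspecific_coverage_floor(cfg$nc_completeness)

  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  names(genomes) <- ids
  if (is.null(quality)) {
    quality <- data.frame(
      genome_id = ids,
      completeness = vapply(genomes, function(g) g$completeness, numeric(1)),
      contamination = vapply(genomes, function(g) g$contamination, numeric(1)),
      css = vapply(genomes, function(g) g$css, numeric(1)),
      n50 = vapply(genomes, function(g) g$n50, numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (is.null(quality$n50))
    quality$n50 <- vapply(genomes[quality$genome_id], function(g) g$n50, numeric(1))
  missing_q <- setdiff(ids, quality$genome_id)
  if (length(missing_q))
    stopf("stage quality-gate: no quality row for %s",
          paste(missing_q, collapse = ", "))
  rownames(quality) <- quality$genome_id

  counts <- c(input = length(ids))
  gate <- function(keep, stage) {
    cf_msg(sprintf("[%s] retained %d / dropped %d", stage, sum(keep),
                   sum(!keep)))
    keep
  }

  tier <- vapply(ids, function(i)
    classify_quality(quality[i, "completeness"], quality[i, "contamination"]),
    character(1))
  ids <- ids[gate(tier %in% c("NC", "MQ"), "MQ gate")]
  counts["mq_gate"] <- length(ids)
  ids <- ids[gate(tier[ids] == "NC", "NC gate")]
  counts["nc_gate"] <- length(ids)

  # CSS gate
  for (i in ids) genomes[[i]]$css <- quality[i, "css"]
  kept <- css_filter(genomes[ids], css_max = cfg$css_max)
  cf_msg(sprintf("[CSS gate] retained %d / dropped %d", length(kept),
                 length(ids) - length(kept)))
  ids <- vapply(kept, function(g) g$genome_id, character(1))
  counts["css_gate"] <- length(ids)

  if (!length(ids)) {
    return(structure(list(clusters = list(), stage_counts = counts,
                          comparisons = NULL, quality = quality,
                          taxonomy = taxonomy, config = cfg),
                     class = "catforge_catalog"))
  }

  sketches <- lapply(genomes[ids], minhash_sketch, k = cfg$sketch_k,
                     s = cfg$sketch_s, seed = cfg$sketch_seed)
  counts["sketch"] <- length(sketches)

  prelim <- preliminary_cluster(sketches, taxonomy,
                                threshold = cfg$prelim_threshold)
  counts["preliminary"] <- length(prelim)
  cf_msg(sprintf("[preliminary] %d cluster(s)", length(unique(prelim))))

  # fragment ANI for all within-preliminary pairs
  pair_rows <- list()
  for (p in unique(prelim)) {
    gids <- names(prelim)[prelim == p]
    if (length(gids) < 2) next
    pair_rows[[p]] <- fragment_ani_matrix(genomes[gids],
                                          fragment_len = cfg$fragment_len)
  }
  comparisons <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(genome_a = character(), genome_b = character(),
               ani = numeric(), coverage = numeric())

  clusters <- secondary_cluster(prelim, comparisons, ani_min = cfg$ani_min,
                                min_coverage = cfg$min_coverage)
  counts["secondary"] <- length(prelim)
  cf_msg(sprintf("[secondary] %d species cluster(s)", length(clusters)))

  clusters <- lapply(clusters, dereplicate_conspecific, comparisons,
                     quality, ani_min = cfg$derep_ani,
                     min_coverage = cfg$derep_coverage,
                     transform = cfg$transform)
  counts["nonredundant"] <- sum(vapply(clusters, function(cl)
    length(cl$nonredundant_ids), integer(1)))

  clusters <- lapply(clusters, function(cl) {
    cl$representative_id <- select_representative(cl, quality, cfg$transform)
    if (!is.null(taxonomy)) {
      row <- taxonomy[taxonomy$genome_id == cl$representative_id, , drop = FALSE]
      ranks <- intersect(TAXONOMY_RANKS, names(taxonomy))
      if (nrow(row)) cl$lineage <- setNames(as.character(row[1, ranks]), ranks)
    }
    cl
  })
  counts["species"] <- length(clusters)

  structure(list(clusters = clusters, stage_counts = counts,
                 comparisons = comparisons, quality = quality,
                 taxonomy = taxonomy, config = cfg),
            class = "catforge_catalog")
}

#' @export
print.catforge_catalog <- function(x, ...) {
  cat(sprintf("<catforge_catalog> %d species cluster(s), %d non-redundant genome(s)\n",
              length(x$clusters),
              sum(vapply(x$clusters, function(cl) length(cl$nonredundant_ids),
                         integer(1)))))
  cat("stage counts:\n")
  print(x$stage_counts)
  invisible(x)
}

#' @export
summary.catforge_catalog <- function(object, ...) {
  df <- catalog_membership(object)
  cat(sprintf("Catalog of %d species over %d genome(s)\n",
              length(object$clusters), nrow(df)))
  sizes <- table(df$cluster_id)
  if (length(sizes)) {
    cat(sprintf("cluster sizes: min %d, median %s, max %d\n",
                min(sizes), format(stats::median(sizes)), max(sizes)))
  }
  invisible(df)
}

#' Catalog membership table
#'
#' @param catalog A `catforge_catalog`.
#' @return data.frame: `genome_id`, `cluster_id`, `is_nonredundant`,
#'   `is_representative`.
#' @export
catalog_membership <- function(catalog) {
  rows <- lapply(catalog$clusters, function(cl) {
    data.frame(genome_id = cl$member_ids, cluster_id = cl$cluster_id,
               is_nonredundant = cl$member_ids %in% cl$nonredundant_ids,
               is_representative = cl$member_ids == cl$representative_id,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(genome_id = character(), cluster_id = character(),
                      is_nonredundant = logical(), is_representative = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
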