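# Genome-size normalization, presence/prevalence calls, profiler
# evaluation metrics, CLR transform and benchmark designs.

#' Construct an abundance profile
#'
#' @param abundances Named non-negative numeric vector (species ->
#'   relative abundance); renormalized to sum to 1.
#' @param sample_id Sample label.
#' @param depth_bp Optional total sequencing depth in bp.
#' @return Named numeric vector of class `abundance_profile` with
#'   attributes `sample_id` and `depth_bp`.
#' @export
abundance_profile <- function(abundances, sample_id = NA_character_,
                              depth_bp = NA_real_) {
  if (is.null(names(abundances))) stopf("abundances must be named by species")
  if (any(abundances < 0)) stopf("abundances must be non-negative")
  tot <- sum(abundances)
  if (tot <= 0) stopf("abundance profile sums to zero")
  structure(abundances / tot, sample_id = sample_id, depth_bp = depth_bp,
            class = "abundance_profile")
}

#' Genome-size normalization of read counts
#'
#' DNA-based profilers assign more reads to species with larger genomes;
#' dividing each species' read count by the genome size of its
#' representative genome before renormalizing removes that bias:
#' a_i = (r_i / L_i) / sum_j (r_j / L_j).
#'
#' @param read_counts Named numeric vector: species -> read count.
#' @param genome_sizes Named numeric vector: species -> genome size (bp).
#' @param sample_id,depth_bp Passed to [abundance_profile()].
#' @return An `abundance_profile`.
#' @export
genome_size_normalize <- function(read_counts, genome_sizes,
                                  sample_id = NA_character_,
                                  depth_bp = NA_real_) {
  if (all(read_counts == 0)) stopf("all read counts are zero")
  sp <- names(read_counts)
  sizes <- genome_sizes[sp]
  if (any(is.na(sizes) & read_counts > 0))
    stopf("missing genome size for species with reads: %s",
          paste(sp[is.na(sizes) & read_counts > 0], collapse = ", "))
  if (any(sizes <= 0, na.rm = TRUE)) stopf("genome sizes must be positive")
  w <- read_counts / sizes
  w[is.na(w)] <- 0
  abundance_profile(w, sample_id = sample_id, depth_bp = depth_bp)
}

#' Presence call at an abundance threshold
#'
#' A taxon is called present only when its relative abundance strictly
#' surpasses the threshold (default 1e-6).
#'
#' @param a Relative abundance(s) in \[0, 1\].
#' @param threshold Presence threshold (default 1e-6).
#' @return Logical vector.
#' @export
presence_call <- function(a, threshold = 1e-6) {
  if (any(a < 0 | a > 1)) stopf("abundances must lie in [0, 1]")
  a > threshold
}

#' Taxon prevalence across samples
#'
#' Samples with sequencing depth below `min_depth_bp` (or missing depth)
#' are dropped; per taxon, prevalence is the fraction of retained samples
#' in which the summed abundance of the taxon's species passes
#' [presence_call()].
#'
#' @param profiles List of `abundance_profile` objects (with `depth_bp`
#'   attributes).
#' @param taxon_map Named character vector: species id -> taxon label at
#'   the surveyed rank.
#' @param min_depth_bp Depth floor in bp (default 1e8, i.e. 100 Mbp).
#' @param threshold Presence threshold (default 1e-6).
#' @return data.frame: `taxon`, `prevalence`, `n_samples`.
#' @export
prevalence_survey <- function(profiles, taxon_map, min_depth_bp = 1e8,
                              threshold = 1e-6) {
  depths <- vapply(profiles, function(p) attr(p, "depth_bp"), numeric(1))
  if (any(is.na(depths)))
    warning(sprintf("dropping %d sample(s) with missing depth", sum(is.na(depths))),
            call. = FALSE)
  keep <- !is.na(depths) & depths >= min_depth_bp
  if (!any(keep)) stopf("no samples retained above the depth floor")
  profiles <- profiles[keep]
  taxa <- sort(unique(taxon_map))
  prev <- vapply(taxa, function(tx) {
    sp_tx <- names(taxon_map)[taxon_map == tx]
    mean(vapply(profiles, function(p)
      presence_call(sum(p[intersect(names(p), sp_tx)]), threshold),
      logical(1)))
  }, numeric(1))
  data.frame(taxon = taxa, prevalence = unname(prev),
             n_samples = length(profiles), stringsAsFactors = FALSE)
}

#' Evaluate a predicted profile against truth
#'
#' Recall and precision are computed over species called present by
#' [presence_call()] in each profile; Bray-Curtis similarity is
#' 1 - 0.5 sum_i |p_i - q_i| over the union of species.
#'
#' @param truth,pred `abundance_profile`s (or named numeric vectors
#'   summing to 1).
#' @param threshold Presence threshold (default 1e-6).
#' @return List with `recall`, `precision`, `bray_curtis`.
#' @export
eval_profile <- function(truth, pred, threshold = 1e-6) {
  if (!length(truth)) stopf("truth profile is empty")
  t_sp <- names(truth)[presence_call(as.numeric(truth), threshold)]
  p_sp <- names(pred)[presence_call(as.numeric(pred), threshold)]
  if (!length(t_sp)) stopf("truth profile has no present species")
  common <- intersect(t_sp, p_sp)
  union_sp <- union(names(truth), names(pred))
  p <- setNames(numeric(length(union_sp)), union_sp)
  q <- p
  p[names(truth)] <- as.numeric(truth)
  q[names(pred)] <- as.numeric(pred)
  list(recall = length(common) / length(t_sp),
       precision = if (length(p_sp)) length(common) / length(p_sp) else 0,
       bray_curtis = 1 - 0.5 * sum(abs(p - q)))
}

#' Centered log-ratio transform
#'
#' x_i = ln((a_i + eps) / g) with g the geometric mean of (a_i + eps);
#' components sum to zero. A pseudocount is required when any abundance is
#' zero.
#'
#' @param p Named numeric vector of relative abundances.
#' @param pseudocount Added to every component (default 1e-9).
#' @return Named numeric vector summing to 0.
#' @export
clr_transform <- function(p, pseudocount = 1e-9) {
  x <- as.numeric(p) + pseudocount
  if (any(x <= 0)) stopf("pseudocount must be positive when zeros are present")
  lx <- log(x)
  setNames(lx - mean(lx), names(p))
}

#' Community benchmark designs
#'
#' Enumerates one design per (community size, genome-selection strategy,
#' replicate): `representative` takes one representative genome per
#' species, `random_one` one random conspecific genome per species, and
#' `random_five` five random conspecific genomes from each of size/5
#' species. Every member genome receives equal abundance. Deterministic
#' under `seed`.
#'
#' @param catalog data.frame with `genome_id`, `species_id`,
#'   `is_representative` columns, or a `catforge_catalog`.
#' @param sizes Community sizes in genomes (default 40, 150, 600).
#' @param strategies Subset of `c("representative", "random_one",
#'   "random_five")`.
#' @param replicates Random samples per configuration (default 3).
#' @param seed RNG seed.
#' @return List of design lists (`design_id`, `size`, `strategy`,
#'   `replicate`, `members`, `abundance`).
#' @export
community_designs <- function(catalog, sizes = c(40, 150, 600),
                              strategies = c("representative", "random_one",
                                             "random_five"),
                              replicates = 3, seed = 1) {
  if (inherits(catalog, "catforge_catalog")) catalog <- catalog_membership(catalog)
  strategies <- match.arg(strategies, several.ok = TRUE)
  sp_genomes <- split(catalog$genome_id, catalog$species_id)
  reps <- catalog$genome_id[catalog$is_representative]
  rep_of <- setNames(reps, catalog$species_id[catalog$is_representative])
  n_species <- length(sp_genomes)
  multi5 <- names(sp_genomes)[vapply(sp_genomes, length, integer(1)) >= 5]

  with_seed(seed, {
    designs <- list()
    for (size in sizes) for (strat in strategies) for (r in seq_len(replicates)) {
      if (strat == "random_five") {
        if (size %% 5 != 0)
          stopf("random_five requires a community size divisible by 5 (got %d)",
                size)
        n_sp <- size / 5
        if (length(multi5) < n_sp)
          stopf("need %d species with >= 5 conspecific genomes, have %d",
                n_sp, length(multi5))
        sel_sp <- sort(sample(multi5, n_sp))
        members <- unlist(lapply(sel_sp, function(sp)
          sort(sample(sp_genomes[[sp]], 5))), use.names = FALSE)
      } else {
        if (n_species < size)
          stopf("need %d species, catalog has %d", size, n_species)
        sel_sp <- sort(sample(names(sp_genomes), size))
        members <- if (strat == "representative") {
          miss <- setdiff(sel_sp, names(rep_of))
          if (length(miss))
            stopf("species without a representative: %s",
                  paste(head(miss, 5), collapse = ", "))
          unname(rep_of[sel_sp])
        } else {
          vapply(sel_sp, function(sp)
            if (length(sp_genomes[[sp]]) == 1) sp_genomes[[sp]] else
              sample(sp_genomes[[sp]], 1), character(1))
        }
      }
      designs[[length(designs) + 1]] <- list(
        design_id = sprintf("size%d_%s_rep%d", size, strat, r),
        size = size, strategy = strat, replicate = r,
        members = unname(members),
        abundance = setNames(rep(1 / length(members), length(members)),
                             unname(members)))
    }
    designs
  })
}

#' Sequencing-depth titration design
#'
#' Cartesian product of samples and read-pair counts; the depth in bp is
#' `n_pairs * bp_per_pair` (300 bp per pair for 2 x 150 bp reads), so the
#' default series spans 150 Mbp to 37.5 Gbp.
#'
#' @param samples Character vector of sample ids.
#' @param read_pairs Read-pair counts (default 0.5, 2.5, 5, 10, 20, 40,
#'   80, 125 million).
#' @param bp_per_pair Bases per read pair (default 300).
#' @return data.frame: `sample_id`, `n_pairs`, `depth_bp`.
#' @export
depth_titration_design <- function(samples,
                                   read_pairs = c(0.5, 2.5, 5, 10, 20, 40,
                                                  80, 125) * 1e6,
                                   bp_per_pair = 300) {
  if (!length(samples)) stopf("samples must be non-empty")
  out <- expand.grid(sample_id = samples, n_pairs = read_pairs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$depth_bp <- out$n_pairs * bp_per_pair
  out[order(out$sample_id, out$n_pairs), , drop = FALSE]
}

#' Profile reads by exact matching against a marker database
#'
#' A deliberately naive profiler used to close the loop in end-to-end
#' tests: a read is assigned to a species when it occurs as an exact
#' substring (either strand) of one of that species' marker sequences;
#' reads matching several species are discarded as ambiguous.
#'
#' @param reads `DNAStringSet` (equal-width reads).
#' @param sets Named list of `marker_set` objects.
#' @return Named integer vector of read counts per species.
#' @export
exact_marker_profile <- function(reads, sets) {
  counts <- setNames(integer(length(sets)), names(sets))
  reads <- Biostrings::DNAStringSet(unname(as.character(reads)))
  rc_reads <- Biostrings::reverseComplement(reads)
  pd <- Biostrings::PDict(c(reads, rc_reads))
  n <- length(reads)
  assign_sp <- vector("list", n)
  for (sp in names(sets)) {
    seqs <- sets[[sp]]$markers$dna
    if (!length(seqs)) next
    subject <- Biostrings::DNAString(paste(seqs, collapse = strrep("N", 10)))
    hit <- which(Biostrings::countPDict(pd, subject) > 0)
    hit <- unique(((hit - 1) %% n) + 1)
    for (i in hit) assign_sp[[i]] <- c(assign_sp[[i]], sp)
  }
  for (i in seq_len(n)) {
    sp <- unique(assign_sp[[i]])
    if (length(sp) == 1) counts[sp] <- counts[sp] + 1L
  }
  counts
}
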