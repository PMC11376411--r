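# Synthetic genomes, populations, pangenomes, communities and reads with
# planted truth.

DNA_BASES <- c("A", "C", "G", "T")

#' Random genome sequence
#'
#' @param length Sequence length in bp.
#' @param seed Optional RNG seed.
#' @return A single character string of A/C/G/T.
#' @export
random_genome <- function(length, seed = NULL) {
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE),
                        collapse = ""))
}

#' Evolve a genome to a target ANI
#'
#' Applies per-site substitutions at rate (100 - target_ani)/100 (each
#' substitution changes the base) plus a small indel component at
#' `indel_frac` of the substitution rate (single-base insertions and
#' deletions, equal odds), so that the realized ANI is
#' substitution-dominated. The planted mutation counts are recorded as
#' attributes `n_substitutions` and `n_indels`.
#'
#' @param ancestor Character string or `DNAString`.
#' @param target_ani Target percent identity to the ancestor, in
#'   \[70, 100\].
#' @param seed Optional RNG seed (same seed, same output).
#' @param indel_frac Indel rate as a fraction of the substitution rate
#'   (default 0.1).
#' @return The evolved sequence (character) with mutation-count
#'   attributes.
#' @export
evolve_genome <- function(ancestor, target_ani, seed = NULL,
                          indel_frac = 0.1) {
  if (target_ani < 70 || target_ani > 100)
    stopf("target_ani must lie in [70, 100]")
  s <- toupper(as.character(ancestor))
  r <- (100 - target_ani) / 100
  with_seed(seed, {
    v <- strsplit(s, "")[[1]]
    n <- length(v)
    sub_idx <- which(runif(n) < r)
    if (length(sub_idx)) {
      # shift the 0..3 base code by 1-3 so the base always changes
      code <- match(v[sub_idx], DNA_BASES) - 1L
      shift <- sample(1:3, length(sub_idx), replace = TRUE)
      v[sub_idx] <- DNA_BASES[((code + shift) %% 4L) + 1L]
    }
    ind_idx <- which(runif(n) < r * indel_frac)
    if (length(ind_idx)) {
      del <- runif(length(ind_idx)) < 0.5
      keep <- rep(TRUE, n)
      keep[ind_idx[del]] <- FALSE
      ins <- character(n)
      ins[ind_idx[!del]] <- sample(DNA_BASES, sum(!del), replace = TRUE)
      out <- paste0(ifelse(keep, v, ""), ins)
    } else {
      out <- v
    }
    structure(paste(out, collapse = ""),
              n_substitutions = length(sub_idx),
              n_indels = length(ind_idx))
  })
}

#' Generate a catalog of genomes with planted species structure
#'
#' Each species descends from an independent random ancestor (so
#' between-species identity is effectively nil, well under the
#' `between_ani` ceiling); conspecific genomes are evolved at a per-genome
#' divergence of half the within-species target, so pairwise ANI within a
#' species is approximately `within_ani`. Quality metrics are assigned
#' metadata sampled from NC-passing ranges unless overridden; genomes are
#' split into one or more contigs so N50 varies.
#'
#' @param n_species Number of planted species (default 3).
#' @param genomes_per_species Conspecific genomes per species (default
#'   10).
#' @param within_ani Planted within-species pairwise ANI in percent
#'   (default 99.5; must exceed 95).
#' @param between_ani Ceiling on between-species ANI (default 90; must be
#'   below 95).
#' @param genome_length Ancestor length in bp (default 20000).
#' @param max_contigs Maximum contigs per genome (default 3).
#' @param completeness_range,contamination_range,css_range Sampling ranges
#'   for the assigned quality metadata.
#' @param seed RNG seed (default 1).
#' @return List of class `planted_catalog`: `genomes` (named list of
#'   `genome_record`), `species_truth` (genome id -> species label),
#'   `quality` (data.frame), `taxonomy` (data.frame with the seven
#'   ranks).
#' @export
make_planted_catalog <- function(n_species = 3, genomes_per_species = 10,
                                 within_ani = 99.5, between_ani = 90,
                                 genome_length = 20000, max_contigs = 3,
                                 completeness_range = c(90, 100),
                                 contamination_range = c(0, 4),
                                 css_range = c(0, 0.4), seed = 1) {
  if (!(within_ani > 95 && between_ani < 95))
    stopf("need within_ani > 95 > between_ani so the species threshold separates truth")
  with_seed(seed, {
    genomes <- list()
    truth <- character(0)
    qual <- list()
    tax <- list()
    per_genome_ani <- (100 + within_ani) / 2
    for (sidx in seq_len(n_species)) {
      sp <- sprintf("SPT%02d", sidx)
      ancestor <- paste(sample(DNA_BASES, genome_length, replace = TRUE),
                        collapse = "")
      for (gidx in seq_len(genomes_per_species)) {
        gid <- sprintf("S%02dG%02d", sidx, gidx)
        seq <- evolve_genome(ancestor, per_genome_ani)
        n <- nchar(seq)
        k <- sample(seq_len(max_contigs), 1)
        cuts <- if (k > 1) sort(sample(seq(2000, n - 2000), k - 1)) else integer(0)
        starts <- c(1, cuts + 1)
        ends <- c(cuts, n)
        contigs <- Biostrings::DNAStringSet(substring(seq, starts, ends))
        names(contigs) <- sprintf("%s_c%d", gid, seq_along(starts))
        comp <- runif(1, completeness_range[1], completeness_range[2])
        cont <- runif(1, contamination_range[1], contamination_range[2])
        css <- runif(1, css_range[1], css_range[2])
        genomes[[gid]] <- genome_record(gid, sequence = contigs,
                                        completeness = comp,
                                        contamination = cont, css = css)
        truth[gid] <- sp
        qual[[gid]] <- data.frame(genome_id = gid, completeness = comp,
                                  contamination = cont, css = css,
                                  n50 = genomes[[gid]]$n50,
                                  stringsAsFactors = FALSE)
        tax[[gid]] <- data.frame(
          genome_id = gid, domain = "d__Bacteria", phylum = "p__Planted",
          class = "c__Planted", order = "o__PlantedOrder",
          family = sprintf("f__Fam%02d", sidx),
          genus = sprintf("g__Gen%02d", sidx),
          species = sprintf("s__%s", sp), stringsAsFactors = FALSE)
      }
    }
    structure(list(genomes = genomes, species_truth = truth,
                   quality = do.call(rbind, qual),
                   taxonomy = do.call(rbind, tax)),
              class = "planted_catalog")
  })
}

#' @export
print.planted_catalog <- function(x, ...) {
  cat(sprintf("<planted_catalog> %d genome(s), %d planted species\n",
              length(x$genomes), length(unique(x$species_truth))))
  invisible(x)
}

#' Generate a pangenome fixture with planted marker truth
#'
#' Per species: `n_unique_core` families present in a `core_presence`
#' fraction of conspecific genomes and in no other species;
#' shared families (split evenly with the two ring-neighbouring species,
#' so each species carries `n_shared` of them at core-like presence); and
#' `n_accessory` families present in under half the genomes. Copy counts
#' are 1, except `n_paralogs` unique-core families per species planted at
#' 2 copies per containing genome (so the mean-copy filter removes them).
#' Genome sequences are the concatenation of each genome's present genes
#' with short random spacers, so fragment remapping has a ground truth.
#'
#' @param n_species Number of species (default 5).
#' @param genomes_per_species Conspecific genomes per species (default
#'   20).
#' @param n_unique_core,n_shared,n_accessory Family counts per species
#'   (defaults 50, 20, 30; `n_shared` must be even).
#' @param gene_len_range DNA length range per gene in bp (default
#'   450-900).
#' @param core_presence Presence fraction for unique-core and shared
#'   families (default 0.95).
#' @param accessory_presence Presence fraction for accessory families
#'   (default 0.3).
#' @param n_paralogs Unique-core families per species planted at 2 copies
#'   (default 0).
#' @param seed RNG seed.
#' @return List of class `pangenome_fixture`: `pangenomes` (named list),
#'   `genomes` (named `DNAStringSet`), `genome_species`, `marker_truth`
#'   (named list: species -> planted unique-core families, excluding
#'   planted paralogs), `family_truth` (data.frame family_id, species_id,
#'   role).
#' @export
make_pangenome_fixture <- function(n_species = 5, genomes_per_species = 20,
                                   n_unique_core = 50, n_shared = 20,
                                   n_accessory = 30,
                                   gene_len_range = c(450, 900),
                                   core_presence = 0.95,
                                   accessory_presence = 0.3,
                                   n_paralogs = 0, seed = 1) {
  if (n_shared %% 2 != 0) stopf("n_shared must be even (ring-shared design)")
  with_seed(seed, {
    species <- sprintf("SP%02d", seq_len(n_species))
    G <- genomes_per_species
    rand_gene <- function() paste(sample(DNA_BASES,
                                         sample(seq(gene_len_range[1],
                                                    gene_len_range[2]), 1),
                                         replace = TRUE), collapse = "")
    fam_dna <- list(); fam_species <- list(); fam_role <- list()
    add_family <- function(fid, sps, role) {
      fam_dna[[fid]] <<- rand_gene()
      fam_species[[fid]] <<- sps
      fam_role[[fid]] <<- role
    }
    for (si in seq_len(n_species)) {
      sp <- species[si]
      for (i in seq_len(n_unique_core))
        add_family(sprintf("%s_core%03d", sp, i), sp,
                   if (i <= n_paralogs) "paralog_core" else "unique_core")
      for (i in seq_len(n_accessory))
        add_family(sprintf("%s_acc%03d", sp, i), sp, "accessory")
      nxt <- species[(si %% n_species) + 1]
      if (n_species > 1) {
        for (i in seq_len(n_shared / 2))
          add_family(sprintf("SH_%s_%s_%02d", sp, nxt, i), c(sp, nxt),
                     "shared")
      }
    }
    fams <- names(fam_dna)

    pangenomes <- list()
    genome_seqs <- character(0)
    genome_species <- character(0)
    present_count <- function(frac) max(1L, round(frac * G))
    for (si in seq_len(n_species)) {
      sp <- species[si]
      sp_f <- fams[vapply(fam_species, function(x) sp %in% x, logical(1))]
      gids <- sprintf("%sG%02d", sp, seq_len(G))
      pres <- matrix(0L, length(sp_f), G, dimnames = list(sp_f, gids))
      for (f in sp_f) {
        k <- if (fam_role[[f]] == "accessory")
          max(1L, floor(accessory_presence * G)) else present_count(core_presence)
        pres[f, sample(G, k)] <- 1L
      }
      copy <- pres
      par_f <- sp_f[vapply(sp_f, function(f)
        fam_role[[f]] == "paralog_core", logical(1))]
      copy[par_f, ] <- copy[par_f, , drop = FALSE] * 2L
      dna <- Biostrings::DNAStringSet(unlist(fam_dna[sp_f]))
      names(dna) <- sp_f
      pangenomes[[sp]] <- pangenome(
        sp, pres, copy_count = copy,
        length_aa = setNames(floor(nchar(fam_dna[sp_f]) / 3), sp_f),
        dna = dna)
      for (g in seq_len(G)) {
        genes <- sp_f[pres[, g] == 1L]
        pieces <- unlist(lapply(genes, function(f) {
          reps <- copy[f, g]
          rep(fam_dna[[f]], reps)
        }))
        spacers <- vapply(seq_along(pieces), function(i)
          paste(sample(DNA_BASES, 30, replace = TRUE), collapse = ""),
          character(1))
        genome_seqs[gids[g]] <- paste0(
          paste(sample(DNA_BASES, 100, replace = TRUE), collapse = ""),
          paste(paste0(pieces, spacers), collapse = ""))
        genome_species[gids[g]] <- sp
      }
    }
    marker_truth <- lapply(setNames(species, species), function(sp)
      sort(fams[vapply(seq_along(fams), function(i)
        identical(fam_species[[i]], sp) && fam_role[[i]] == "unique_core",
        logical(1))]))
    structure(list(
      pangenomes = pangenomes,
      genomes = Biostrings::DNAStringSet(genome_seqs),
      genome_species = genome_species,
      marker_truth = marker_truth,
      family_truth = data.frame(
        family_id = fams,
        species_id = vapply(fam_species, paste, character(1), collapse = ","),
        role = unlist(fam_role), row.names = NULL,
        stringsAsFactors = FALSE)),
      class = "pangenome_fixture")
  })
}

#' Simulate shotgun reads from a community
#'
#' Reads are drawn with genome probability proportional to abundance x
#' genome length (the coverage bias that genome-size normalization
#' corrects), uniform start positions on a uniformly chosen strand, and
#' independent substitution errors at `error_rate`.
#'
#' @param community A design from [community_designs()], or a named
#'   abundance vector (genome id -> abundance).
#' @param genomes Named `DNAStringSet` (one sequence per genome) or list
#'   of `genome_record`s.
#' @param n_reads Number of reads (>= 1).
#' @param read_len Read length in bp (default 150).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed RNG seed.
#' @return List: `reads` (`DNAStringSet`), `source` (named character:
#'   read id -> genome id), `truth` (the community abundance profile).
#' @export
simulate_reads <- function(community, genomes, n_reads, read_len = 150,
                           error_rate = 0, seed = 1) {
  if (n_reads < 1) stopf("n_reads must be >= 1")
  ab <- if (is.list(community) && !is.null(community$abundance))
    community$abundance else community
  if (is.null(names(ab))) stopf("community abundances must be named by genome")
  if (inherits(genomes, "list") &&
      all(vapply(genomes, inherits, logical(1), "genome_record"))) {
    gseq <- vapply(genomes, function(g)
      paste(as.character(g$sequence), collapse = ""), character(1))
    names(gseq) <- vapply(genomes, function(g) g$genome_id, character(1))
  } else {
    gseq <- stats::setNames(as.character(genomes), names(genomes))
  }
  miss <- setdiff(names(ab), names(gseq))
  if (length(miss)) stopf("missing genome sequences: %s",
                          paste(miss, collapse = ", "))
  lens <- nchar(gseq[names(ab)])
  if (any(lens < read_len)) stopf("a community genome is shorter than read_len")
  with_seed(seed, {
    w <- ab * lens
    src <- sample(names(ab), n_reads, replace = TRUE, prob = w / sum(w))
    starts <- floor(runif(n_reads) * (lens[src] - read_len + 1)) + 1
    reads <- substring(gseq[src], starts, starts + read_len - 1)
    minus <- runif(n_reads) < 0.5
    if (any(minus)) {
      reads[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[minus])))
    }
    if (error_rate > 0) {
      reads <- vapply(reads, function(rd) {
        v <- strsplit(rd, "")[[1]]
        idx <- which(runif(read_len) < error_rate)
        if (length(idx)) {
          code <- match(v[idx], DNA_BASES) - 1L
          shift <- sample(1:3, length(idx), replace = TRUE)
          v[idx] <- DNA_BASES[((code + shift) %% 4L) + 1L]
        }
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    read_ids <- sprintf("read%06d", seq_len(n_reads))
    out_reads <- Biostrings::DNAStringSet(reads)
    names(out_reads) <- read_ids
    list(reads = out_reads, source = setNames(unname(src), read_ids),
         truth = abundance_profile(ab))
  })
}
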