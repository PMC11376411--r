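# Marker-gene candidate scoring, fragment remapping, and export.

make_pg <- function(species = "SPX", fams, genomes = 5, pres = NULL,
                    copy = NULL, len_aa = NULL, dna = NULL) {
  gids <- sprintf("%sG%02d", species, seq_len(genomes))
  if (is.null(pres)) pres <- matrix(1L, length(fams), genomes)
  dimnames(pres) <- list(fams, gids)
  if (!is.null(copy)) dimnames(copy) <- list(fams, gids)
  if (is.null(len_aa)) len_aa <- setNames(rep(200, length(fams)), fams)
  pangenome(species, pres, copy_count = copy, length_aa = len_aa, dna = dna)
}

test_that("coreness is the containing-genome fraction", {
  pres <- rbind(f1 = c(1, 1, 1, 0, 0), f2 = rep(1, 5), f3 = rep(0, 5))
  p <- make_pg(fams = rownames(pres), pres = pres)
  expect_equal(unname(coreness(p, "f1")), 0.6)
  expect_equal(unname(coreness(p, "f2")), 1.0)
  expect_equal(unname(coreness(p, "f3")), 0.0)
  expect_error(coreness(p, "nope"), "unknown family")
})

test_that("uniqueness counts species in the cross-species index", {
  idx <- list(own = "A", ten = LETTERS[1:10], eleven = LETTERS[1:11])
  expect_equal(unname(uniqueness("own", idx)), 1L)
  expect_equal(unname(uniqueness("ten", idx)), 10L)
  expect_equal(unname(uniqueness("eleven", idx)), 11L)
})

test_that("candidate filters apply length, copy, coreness and uniqueness", {
  fams <- c("good", "short", "toolong", "paralog", "rare", "promiscuous")
  pres <- matrix(1L, 6, 10)
  pres[5, ] <- c(rep(1L, 3), rep(0L, 7))        # coreness 0.3
  copy <- pres
  copy[4, ] <- 2L                               # mean copies 2.0
  len <- setNames(c(200, 100, 1600, 200, 200, 200), fams)
  p <- make_pg(fams = fams, genomes = 10, pres = pres, copy = copy,
               len_aa = len)
  idx <- c(setNames(rep(list("SPX"), 5), fams[1:5]),
           list(promiscuous = paste0("S", 1:11)))
  cand <- candidate_markers(p, idx)
  expect_equal(cand$family_id, "good")
  expect_equal(cand$coreness, 1.0)
  expect_equal(cand$uniqueness, 1L)
})

test_that("the candidate cap keeps the best-ranked 800", {
  fams <- sprintf("f%04d", 1:900)
  p <- make_pg(fams = fams, genomes = 4,
               len_aa = setNames(sample(150:1500, 900, replace = TRUE), fams))
  idx <- setNames(rep(list("SPX"), 900), fams)
  cand <- candidate_markers(p, idx)
  expect_equal(nrow(cand), 800)
  # all tie on uniqueness/coreness, so the 800 longest survive
  expect_equal(sort(cand$length_aa, decreasing = TRUE),
               unname(sort(p$length_aa, decreasing = TRUE)[1:800]))
})

test_that("a single-genome species keeps all its families as trivially core", {
  fams <- c("f1", "f2")
  p <- make_pg(fams = fams, genomes = 1)
  idx <- setNames(rep(list("SPX"), 2), fams)
  cand <- candidate_markers(p, idx)
  expect_equal(sort(cand$family_id), fams)
  expect_equal(cand$coreness, c(1, 1))
})

test_that("gene fragmentation drops sub-window tails", {
  expect_length(fragment_genes(random_genome(450, seed = 1)), 3)
  expect_length(fragment_genes(random_genome(460, seed = 1)), 3)
  expect_length(fragment_genes(random_genome(150, seed = 1)), 1)
  expect_warning(out <- fragment_genes(random_genome(100, seed = 1)),
                 "shorter")
  expect_length(out, 0)
})

test_that("fragment mapping honors identity and strand", {
  g <- random_genome(5000, seed = 61)
  frag <- substr(g, 1001, 1150)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  mutate_n <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    idx <- round(seq(5, 145, length.out = n))
    v[idx] <- vapply(v[idx], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    paste(v, collapse = "")
  }
  frags <- c(exact = frag, revcomp = rc,
             mm7 = mutate_n(frag, 7),    # identity 143/150 > 0.95
             mm10 = mutate_n(frag, 10))  # identity 140/150 < 0.95
  hits <- map_fragments(frags, c(gen = g), min_identity = 0.95)
  expect_true(hits["exact", "gen"])
  expect_true(hits["revcomp", "gen"])
  expect_true(hits["mm7", "gen"])
  expect_false(hits["mm10", "gen"])
  # a fragment absent from the genome never hits
  hits2 <- map_fragments(c(alien = random_genome(150, seed = 62)), c(gen = g))
  expect_false(any(hits2))
})

test_that("refinement keeps planted unique-core genes and drops shared ones", {
  fx <- make_pangenome_fixture(n_species = 3, genomes_per_species = 6,
                               n_unique_core = 8, n_shared = 4,
                               n_accessory = 5, seed = 71)
  sets <- select_markers(fx$pangenomes, fx$genomes, fx$genome_species)
  for (sp in names(fx$marker_truth)) {
    expect_equal(sort(sets[[sp]]$markers$family_id), fx$marker_truth[[sp]])
  }
  shared <- fx$family_truth$family_id[fx$family_truth$role == "shared"]
  for (sp in names(sets))
    expect_length(intersect(sets[[sp]]$markers$family_id, shared), 0)
})

test_that("the final cap keeps the longest genes with a total order", {
  cand <- data.frame(family_id = sprintf("f%03d", 1:5), species_id = "SPX",
                     coreness = 1, uniqueness = 1L,
                     length_aa = c(200, 180, 160, 150, 220),
                     mean_copies = 1, stringsAsFactors = FALSE)
  dna_seqs <- Biostrings::DNAStringSet(
    vapply(cand$length_aa * 3, function(n) random_genome(n), character(1)))
  names(dna_seqs) <- cand$family_id
  frags <- character(0)
  for (fam in cand$family_id) {
    fr <- fragment_genes(as.character(dna_seqs[[fam]]))
    frags[paste("SPX", fam, seq_along(fr), sep = "|")] <- fr
  }
  genomes <- c(SPXG01 = paste(as.character(dna_seqs), collapse = ""))
  hits <- map_fragments(frags, genomes)
  sets <- refine_markers(cand, hits, c(SPXG01 = "SPX"),
                         list(SPX = dna_seqs), cap = 3)
  m <- sets$SPX$markers
  expect_equal(nrow(m), 3)
  expect_equal(m$family_id, c("f005", "f001", "f002"))  # longest first
  expect_true(all(diff(m$length_nt) <= 0))
})

test_that("the marker database round-trips and reports empty species", {
  fx <- make_pangenome_fixture(n_species = 2, genomes_per_species = 4,
                               n_unique_core = 5, n_shared = 2,
                               n_accessory = 2, seed = 81)
  sets <- select_markers(fx$pangenomes, fx$genomes, fx$genome_species)
  sets$EMPTY <- structure(list(species_id = "EMPTY",
                               markers = sets$SP01$markers[0, ]),
                          class = "marker_set")
  fa <- tempfile(fileext = ".fa"); meta <- tempfile(fileext = ".tsv")
  rep_path <- tempfile(fileext = ".tsv")
  export_marker_db(sets, fa, meta, report_path = rep_path)
  back <- read_marker_db(fa, meta)
  expect_setequal(names(back), c("SP01", "SP02"))
  for (sp in names(back)) {
    expect_equal(back[[sp]]$markers$family_id, sets[[sp]]$markers$family_id)
    expect_equal(back[[sp]]$markers$dna, sets[[sp]]$markers$dna)
  }
  expect_equal(read_tsv_table(rep_path)$species_id, "EMPTY")
  expect_error(export_marker_db(list(), fa, meta), "no marker sets")
})
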