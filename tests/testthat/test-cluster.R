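# Average linkage, two-tier species clustering, dereplication and
# representative selection.

cmp_row <- function(a, b, ani, coverage) {
  data.frame(genome_a = a, genome_b = b, ani = ani, coverage = coverage,
             stringsAsFactors = FALSE)
}

test_that("average linkage matches naive agglomeration on random matrices", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    ids <- paste0("g", sample(100, n))
    d <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    thr <- runif(1, 0.2, 0.8)
    expect_true(same_partition(average_linkage(d, thr),
                               oracle_average_linkage(d, thr)))
  }
})

test_that("average linkage edge cases behave", {
  ids <- c("a", "b", "c")
  z <- matrix(0, 3, 3, dimnames = list(ids, ids))
  expect_equal(unname(average_linkage(z, 0.1)), rep(1L, 3))
  d <- z; d["a", "b"] <- d["b", "a"] <- 0.5; d["a", "c"] <- d["c", "a"] <- 0.5
  d["b", "c"] <- d["c", "b"] <- 0.5
  expect_equal(sort(unique(average_linkage(d, 0.4))), 1:3)  # all singletons
  # two tight blocks far apart
  ids <- c("a1", "a2", "b1", "b2")
  m <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(m) <- 0
  m["a1", "a2"] <- m["a2", "a1"] <- 0.01
  m["b1", "b2"] <- m["b2", "b1"] <- 0.01
  part <- average_linkage(m, 0.05)
  expect_equal(part[["a1"]], part[["a2"]])
  expect_equal(part[["b1"]], part[["b2"]])
  expect_false(part[["a1"]] == part[["b1"]])
})

test_that("preliminary clustering never merges across taxonomic orders", {
  s1 <- random_genome(4000, seed = 31)
  sketches <- list(g1 = minhash_sketch(s1, s = 500),
                   g2 = minhash_sketch(s1, s = 500))
  sketches$g1$genome_id <- "g1"; sketches$g2$genome_id <- "g2"
  tax <- data.frame(genome_id = c("g1", "g2"), order = c("o__A", "o__B"))
  part <- preliminary_cluster(sketches, tax)
  expect_false(part[["g1"]] == part[["g2"]])
  # identical genomes in the same order co-cluster
  tax$order <- "o__A"
  part2 <- preliminary_cluster(sketches, tax)
  expect_equal(part2[["g1"]], part2[["g2"]])
})

test_that("secondary clustering applies the ANI threshold and coverage gate", {
  prelim <- setNames(rep("P001", 2), c("x", "y"))
  same <- secondary_cluster(prelim, cmp_row("x", "y", 95.0, 0.9))
  expect_length(same, 1)
  low_cov <- secondary_cluster(prelim, cmp_row("x", "y", 99.0, 0.5))
  expect_length(low_cov, 2)
  below <- secondary_cluster(prelim, cmp_row("x", "y", 94.9, 0.9))
  expect_length(below, 2)
  missing_ani <- secondary_cluster(prelim, cmp_row("x", "y", NA_real_, 0))
  expect_length(missing_ani, 2)
})

test_that("conspecific dereplication merges only near-identical genomes", {
  qual <- data.frame(genome_id = c("x", "y"), completeness = c(95, 92),
                     contamination = c(1, 1), n50 = c(1e5, 5e4))
  cl <- species_cluster("SP0001", c("x", "y"))
  merged <- dereplicate_conspecific(cl, cmp_row("x", "y", 99.95, 0.9), qual)
  expect_equal(merged$conspecific_count, 1)
  expect_equal(merged$nonredundant_ids, "x")  # higher S retained
  kept <- dereplicate_conspecific(cl, cmp_row("x", "y", 99.5, 0.9), qual)
  expect_equal(kept$conspecific_count, 2)
  expect_equal(kept$nonredundant_ids, c("x", "y"))
  # high ANI but coverage below the 0.81 floor: not merged
  gated <- dereplicate_conspecific(cl, cmp_row("x", "y", 99.95, 0.7), qual)
  expect_equal(gated$conspecific_count, 2)
})

test_that("dereplication is idempotent", {
  qual <- data.frame(genome_id = c("x", "y", "z"),
                     completeness = c(95, 92, 91), contamination = c(1, 1, 2),
                     n50 = c(1e5, 5e4, 2e4))
  cmp <- rbind(cmp_row("x", "y", 99.95, 0.9), cmp_row("x", "z", 99.0, 0.9),
               cmp_row("y", "z", 99.0, 0.9))
  cl <- dereplicate_conspecific(species_cluster("SP0001", c("x", "y", "z")),
                                cmp, qual)
  again <- dereplicate_conspecific(
    species_cluster("SP0001", cl$nonredundant_ids), cmp, qual)
  expect_equal(again$nonredundant_ids, cl$nonredundant_ids)
})

test_that("representatives maximize the intactness score with id tie-break", {
  qual <- data.frame(genome_id = c("a", "b"), completeness = c(90, 88),
                     contamination = c(1, 0), n50 = c(1e4, 1e4))
  cl <- species_cluster("SP0001", c("a", "b"))
  # S(a) = 90 - 5 + 2 = 87 ; S(b) = 88 - 0 + 2 = 90
  expect_equal(select_representative(cl, qual), "b")
  # +1 contamination on b drops its S by 5 and flips the choice
  qual$contamination[2] <- 1
  expect_equal(select_representative(cl, qual), "a")
  qual2 <- data.frame(genome_id = c("b", "a"), completeness = 90,
                      contamination = 1, n50 = 1e4)
  expect_equal(select_representative(cl, qual2), "a")  # tie -> smaller id
})

test_that("species clustering is invariant to input order", {
  ids <- c("m", "k", "z", "a")
  cmp <- rbind(cmp_row("m", "k", 99, 0.9), cmp_row("z", "a", 98, 0.9),
               cmp_row("m", "z", 80, 0.9), cmp_row("m", "a", 80, 0.9),
               cmp_row("k", "z", 80, 0.9), cmp_row("k", "a", 80, 0.9))
  p1 <- setNames(rep("P001", 4), ids)
  p2 <- setNames(rep("P001", 4), rev(ids))
  c1 <- secondary_cluster(p1, cmp)
  c2 <- secondary_cluster(p2, cmp)
  expect_equal(lapply(c1, `[[`, "member_ids"), lapply(c2, `[[`, "member_ids"))
})

test_that("an all-sub-NC input yields an empty catalog with stage counts", {
  gs <- list(make_record("g1", random_genome(3000, seed = 41),
                         completeness = 60),
             make_record("g2", random_genome(3000, seed = 42),
                         completeness = 85))
  out <- run_catalog_pipeline(gs)
  expect_length(out$clusters, 0)
  expect_equal(unname(out$stage_counts[c("input", "mq_gate", "nc_gate")]),
               c(2, 2, 0))
  expect_equal(nrow(catalog_membership(out)), 0)
})

test_that("byte-identical duplicates do not inflate the conspecific count", {
  pc <- make_planted_catalog(n_species = 2, genomes_per_species = 2,
                             genome_length = 8000, seed = 51)
  base <- run_catalog_pipeline(pc$genomes, quality = pc$quality,
                               taxonomy = pc$taxonomy)
  dup <- pc$genomes[[1]]
  dup$genome_id <- "ZZdup"
  genomes2 <- c(pc$genomes, list(ZZdup = dup))
  q2 <- rbind(pc$quality,
              data.frame(genome_id = "ZZdup",
                         completeness = dup$completeness,
                         contamination = dup$contamination,
                         css = dup$css, n50 = dup$n50))
  tax2 <- rbind(pc$taxonomy, within(pc$taxonomy[1, ], genome_id <- "ZZdup"))
  dup_out <- run_catalog_pipeline(genomes2, quality = q2, taxonomy = tax2)
  counts <- function(x) sort(vapply(x$clusters, `[[`, integer(1),
                                    "conspecific_count"))
  expect_equal(counts(dup_out), counts(base))
})
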