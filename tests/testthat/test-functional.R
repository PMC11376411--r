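# Annotation rates, GO filtering, Jaccard clustering homogeneity,
# enrichment statistics and rank specificity.

ann_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(family_id = r[1], namespace = r[2], term = r[3],
               stringsAsFactors = FALSE)))
}

test_that("annotation rate counts families with any term in a namespace", {
  tab <- ann_table(c("f1", "GO", "GO:1"), c("f1", "GO", "GO:2"),
                   c("f2", "KO", "K001"), c("f3", "GO", "GO:3"))
  fams <- paste0("f", 1:8)
  expect_equal(annotation_rate(fams, tab, "GO"), 25)      # 2 of 8
  expect_equal(annotation_rate(fams, tab, "KO"), 12.5)    # 1 of 8
  expect_equal(annotation_rate(fams, tab, "CAZy"), 0)
  expect_equal(annotation_rate(c("f1", "f3"), tab, "GO"), 100)
  expect_error(annotation_rate(character(0), tab, "GO"), "non-empty")
})

test_that("bacterial GO filtering honors whitelist and exclusions", {
  tab <- ann_table(c("f1", "GO", "GO:0110165"), c("f1", "GO", "GO:0001"),
                   c("f1", "KO", "K001"), c("f2", "GO", "GO:0002"))
  out <- filter_bacterial_go(tab, c("GO:0110165", "GO:0001"))
  expect_equal(out$term[out$namespace == "GO"], "GO:0001")  # 0110165 excluded
  expect_true("K001" %in% out$term)                         # KO untouched
  expect_error(filter_bacterial_go(tab, character(0)), "non-empty")
})

test_that("Jaccard distance satisfies the metric axioms on random sets", {
  expect_equal(go_jaccard_distance(c("x", "y"), c("x", "y")), 0)
  expect_equal(go_jaccard_distance(c("x"), c("y")), 1)
  expect_equal(go_jaccard_distance(c("x", "y"), c("y", "z")), 1 - 1 / 3)
  expect_equal(go_jaccard_distance(character(0), character(0)), 0)
  set.seed(101)
  universe <- paste0("t", 1:12)
  rset <- function() sample(universe, sample(1:8, 1))
  for (i in 1:60) {
    a <- rset(); b <- rset(); c <- rset()
    dab <- go_jaccard_distance(a, b)
    expect_equal(dab, go_jaccard_distance(b, a))           # symmetry
    expect_equal(go_jaccard_distance(a, a), 0)             # identity
    expect_lte(dab, go_jaccard_distance(a, c) + go_jaccard_distance(c, b) + 1e-12)
  }
})

test_that("homogeneity is purity and hits 1 for pure labelings", {
  profiles <- list(g1 = c("a", "b"), g2 = c("a", "b"), g3 = c("x", "y"),
                   g4 = c("x", "z"))
  same <- setNames(rep("gen1", 4), names(profiles))
  hc <- homogeneity_curve(profiles, same, n_range = 1:4)
  expect_equal(hc$homogeneity, rep(1, 4))
  labels <- setNames(c("gen1", "gen1", "gen2", "gen2"), names(profiles))
  hc2 <- homogeneity_curve(profiles, labels, n_range = 1:4)
  # one cluster with labels {g1,g1,g2,g2} -> modal fraction 0.5
  expect_equal(hc2$homogeneity[1], 0.5)
  # singletons are always pure
  expect_equal(hc2$homogeneity[4], 1)
  # the profiles separate the genera perfectly at n = 2
  expect_equal(hc2$homogeneity[2], 1)
})

test_that("denser term profiles give higher homogeneity than noisier ones", {
  # two genera; rich profiles share many within-genus terms, sparse
  # profiles keep only a noisy subset (mimicking orthology-only annotation)
  set.seed(111)
  genera <- rep(c("gA", "gB"), each = 6)
  ids <- sprintf("g%02d", seq_along(genera))
  base <- list(gA = paste0("A", 1:30), gB = paste0("B", 1:30))
  rich <- setNames(lapply(genera, function(g)
    c(sample(base[[g]], 25), paste0("noise", sample(1000, 2)))), ids)
  sparse <- setNames(lapply(genera, function(g)
    c(sample(base[[g]], 3), paste0("noise", sample(1000, 4)))), ids)
  labels <- setNames(genera, ids)
  h_rich <- homogeneity_curve(rich, labels, n_range = 2:6)$homogeneity
  h_sparse <- homogeneity_curve(sparse, labels, n_range = 2:6)$homogeneity
  expect_true(mean(h_rich) >= mean(h_sparse))
  expect_true(all(h_rich >= h_sparse - 1e-9))
})

test_that("shared proportions report both directions", {
  sp <- shared_proportion(paste0("a", 1:10), c(paste0("a", 1:4), "b1"))
  expect_equal(sp$n_shared, 4)
  expect_equal(sp$pct_a, 40)
  expect_equal(sp$pct_b, 80)
  expect_equal(shared_proportion(letters, LETTERS)$pct_a, 0)
  both <- shared_proportion(letters, letters)
  expect_equal(c(both$pct_a, both$pct_b), c(100, 100))
})

test_that("Fisher p matches the enumeration oracle on all small tables", {
  # every 2x2 table with both group margins at most 30
  for (m in 0:30) for (a in 0:m) {
    n <- 30; k_vals <- c(0, 7, 19)
    for (cc in k_vals) {
      if (cc > n) next
      p_impl <- fisher_exact_p(a, m - a, cc, n - cc)
      expect_equal(p_impl, oracle_fisher_p(a, m - a, cc, n - cc),
                   tolerance = 1e-12)
    }
  }
  # cross-check against the standard two-sided test on a random sample
  set.seed(121)
  for (i in 1:40) {
    t <- rmultinom(1, sample(10:50, 1), rep(0.25, 4))
    p_impl <- fisher_exact_p(t[1], t[2], t[3], t[4])
    p_ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(p_impl, p_ref, tolerance = 1e-9)
  }
})

test_that("enrichment reproduces the worked 2x2 example", {
  g1 <- lapply(list(ko1 = paste0("m", 1:60), ko2 = paste0("m", 1:30)),
               identity)
  g2 <- list(ko1 = paste0("h", 1:20), ko2 = paste0("h", 1:30))
  m1 <- matrix(FALSE, 2, 100, dimnames = list(c("ko1", "ko2"), paste0("m", 1:100)))
  m2 <- matrix(FALSE, 2, 100, dimnames = list(c("ko1", "ko2"), paste0("h", 1:100)))
  m1["ko1", 1:60] <- TRUE; m2["ko1", 1:20] <- TRUE
  m1["ko2", 1:30] <- TRUE; m2["ko2", 1:30] <- TRUE
  res <- term_species_enrichment(m1, m2)
  r1 <- res[res$term == "ko1", ]
  expect_equal(r1$odds_ratio, (60 * 80) / (40 * 20))  # 6.0
  expect_equal(r1$p, oracle_fisher_p(60, 40, 20, 80), tolerance = 1e-12)
  expect_equal(r1$p_adj, min(1, r1$p * nrow(res)))
  r2 <- res[res$term == "ko2", ]
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$log2_fold_change, 0)  # identical proportions, shared eps
  # a term in every species of both groups is uninformative
  m1["ko2", ] <- TRUE; m2["ko2", ] <- TRUE
  res2 <- term_species_enrichment(m1, m2)
  expect_equal(res2$p[res2$term == "ko2"], 1)
})

test_that("the lowest common rank walks up the lineage", {
  tax <- data.frame(
    species_id = c("s1", "s2", "s3", "s4"),
    domain = "d__B",
    phylum = c("p__1", "p__1", "p__1", "p__2"),
    class = c("c__1", "c__1", "c__1", "c__9"),
    order = c("o__1", "o__1", "o__1", "o__9"),
    family = c("f__1", "f__1", "f__2", "f__9"),
    genus = c("g__1", "g__1", "g__2", "g__9"),
    species = c("s__1", "s__2", "s__3", "s__4"),
    stringsAsFactors = FALSE)
  expect_equal(lowest_common_rank("s1", tax), "species")
  expect_equal(lowest_common_rank(c("s1", "s2"), tax), "genus")
  expect_equal(lowest_common_rank(c("s1", "s3"), tax), "order")
  expect_equal(lowest_common_rank(c("s1", "s4"), tax), "domain")
  expect_error(lowest_common_rank(character(0), tax), "empty")
  expect_error(lowest_common_rank("nope", tax), "missing")
})

test_that("greedy identity clustering groups mutated copies, not strangers", {
  anc <- random_genome(600, seed = 131)
  mut <- evolve_genome(anc, 95, seed = 132)   # ~5% divergence
  other <- random_genome(600, seed = 133)
  fam <- greedy_identity_cluster(c(a = anc, m = mut, o = other),
                                 min_identity = 0.9)
  expect_equal(fam[["a"]], fam[["m"]])
  expect_false(fam[["o"]] == fam[["a"]])
  dup <- greedy_identity_cluster(c(x = anc, y = anc), min_identity = 1)
  expect_equal(unname(dup), c("x", "x"))
})
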