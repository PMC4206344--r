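test_that("percentile interval follows type-7 order-statistic interpolation", {
  expect_equal(percentile_interval(1:1000), c(25.975, 975.025))
  expect_equal(percentile_interval(rep(4.2, 50)), c(4.2, 4.2))
  set.seed(3)
  x <- rnorm(97)
  ci <- percentile_interval(x)
  expect_gte(ci[1], min(x))
  expect_lte(ci[2], max(x))
  expect_error(percentile_interval(numeric(0)), "no values")
})

test_that("tip shuffle with all tips flagged is degenerate at total length", {
  tr <- read_phylogeny("((A:1,B:1):1,(C:1,D:1):1);")
  out <- tip_shuffle_null(tr, c("A", "B", "C", "D"), n_reps = 50, seed = 1)
  L <- tree_total_length(tr)
  expect_true(all(abs(out$replicates - L) < 1e-12))
  expect_equal(c(out$lower, out$upper), c(L, L))
  expect_equal(out$verdict, "inside")
})

test_that("single flagged tip on an ultrametric tree gives constant nulls", {
  tr <- simulate_yule_tree(12, seed = 4)
  out <- tip_shuffle_null(tr, tr$tip.label[5], n_reps = 100, seed = 2)
  expect_true(all(abs(out$replicates - 1) < 1e-9))  # unit-height tree
})

test_that("replicates follow the exhaustive subset distribution", {
  # ((A:1,B:1):1,(C:1,D:1):1): the 6 two-tip subsets span length 3 (the two
  # cherries, 2/6) or 4 (the four cross pairs, 4/6)
  tr <- read_phylogeny("((A:1,B:1):1,(C:1,D:1):1);")
  subsets <- utils::combn(tr$tip.label, 2, simplify = FALSE)
  exact <- table(vapply(subsets, function(s) faith_pd(tr, s), numeric(1))) / 6
  expect_equal(as.numeric(exact[c("3", "4")]), c(1 / 3, 2 / 3))

  out <- tip_shuffle_null(tr, c("A", "C"), n_reps = 10000, seed = 9)
  p3 <- mean(abs(out$replicates - 3) < 1e-12)
  se <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_lt(abs(p3 - 1 / 3), 3 * se)
  expect_true(all(abs(out$replicates - 3) < 1e-12 |
                    abs(out$replicates - 4) < 1e-12))
})

test_that("flagged taxa must be valid and results reproducible", {
  tr <- simulate_yule_tree(10, seed = 1)
  expect_error(tip_shuffle_null(tr, c("sp001", "nope"), 10, 1), "nope")
  a <- tip_shuffle_null(tr, c("sp001", "sp002"), n_reps = 100, seed = 5)
  b <- tip_shuffle_null(tr, c("sp001", "sp002"), n_reps = 100, seed = 5)
  expect_identical(a$replicates, b$replicates)
})

test_that("random cell draws are uniform, distinct and reproducible", {
  expect_equal(sort(sample_random_cells(5, 5, seed = 1)$cell_ids), 0:4)
  expect_identical(sample_random_cells(100, 10, seed = 3)$cell_ids,
                   sample_random_cells(100, 10, seed = 3)$cell_ids)
  expect_error(sample_random_cells(5, 6), "between")

  # chi-square uniformity of inclusion counts over many draws
  set.seed(11)
  n <- 20; k <- 5
  counts <- integer(n)
  for (i in 1:20000) {
    draw <- sample_random_cells(n, k)$cell_ids + 1L
    counts[draw] <- counts[draw] + 1L
  }
  expected <- 20000 * k / n
  chisq <- sum((counts - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.99, df = n - 1))
})

test_that("average-mode effectiveness follows its defining formula", {
  g <- grid_spec(2, 2)
  prof <- phylocover:::diversity_profile(g, "breeding", "richness",
                                         c(100, 80, 80, 80))
  sites <- phylocover:::site_set(0L, source = "focal")
  out <- effectiveness_average(prof, sites, n_reps = 500, seed = 1)
  # D_site = 100; D_rand is 80 or 100 depending on the draw, so every
  # replicate is 0 or 0.2 and replicates drawing cell 0 reproduce 0
  expect_true(all(abs(out$replicate_effectiveness) < 1e-12 |
                    abs(out$replicate_effectiveness - 0.2) < 1e-12))
  expect_equal(out$observed_site_value, 100)

  const <- phylocover:::diversity_profile(g, "breeding", "richness",
                                          rep(7, 4))
  out2 <- effectiveness_average(const, sites, n_reps = 100, seed = 2)
  expect_equal(c(out2$lower, out2$upper), c(0, 0))
  expect_false(out2$significant)
})

test_that("undefined cells are excluded and degenerate cases error", {
  g <- grid_spec(1, 3)
  prof <- phylocover:::diversity_profile(g, "breeding",
                                         "phylo_distinctiveness",
                                         c(NA, 2, 4))
  sites <- phylocover:::site_set(c(0L, 1L), source = "focal")
  out <- effectiveness_average(prof, sites, n_reps = 50, seed = 1)
  expect_equal(out$observed_site_value, 2)  # NA cell dropped from the mean

  all_na <- phylocover:::site_set(0L, source = "focal")
  expect_error(effectiveness_average(
    phylocover:::diversity_profile(g, "breeding", "phylo_distinctiveness",
                                   c(NA, NA, 1)),
    phylocover:::site_set(c(0L, 1L), source = "focal"), 10, 1), "undefined")
  expect_error(effectiveness_average(
    phylocover:::diversity_profile(g, "breeding", "richness", c(0, 1, 2)),
    all_na, 10, 1), "0")
})

test_that("effectiveness is invariant to profile scale", {
  set.seed(17)
  g <- grid_spec(6, 6)
  vals <- runif(36, 1, 10)
  sites <- sample_random_cells(36, 6, seed = 8)
  p1 <- phylocover:::diversity_profile(g, "breeding", "richness", vals)
  p2 <- phylocover:::diversity_profile(g, "breeding", "richness", vals * 37.5)
  e1 <- effectiveness_average(p1, sites, n_reps = 200, seed = 4)
  e2 <- effectiveness_average(p2, sites, n_reps = 200, seed = 4)
  expect_equal(e1$replicate_effectiveness, e2$replicate_effectiveness,
               tolerance = 1e-12)
})

test_that("top-value focal sites are never beaten by random draws", {
  set.seed(23)
  g <- grid_spec(8, 8)
  vals <- runif(64)
  top <- phylocover:::site_set(order(-vals)[1:6] - 1L, source = "focal")
  prof <- phylocover:::diversity_profile(g, "breeding", "richness", vals)
  out <- effectiveness_average(prof, top, n_reps = 300, seed = 2)
  expect_true(all(out$replicate_effectiveness >= -1e-12))
})

test_that("total-mode effectiveness evaluates union metrics", {
  sc <- generate_scenario(small_config(seed = 41))
  cm <- build_community_matrix(sc$layers, sc$grid, "breeding")
  # sites = every cell -> D_site == D_rand for every replicate
  all_cells <- phylocover:::site_set(0:(phylocover:::n_cells(sc$grid) - 1L),
                                     source = "focal")
  out <- effectiveness_total(cm, sc$tree, sc$table, all_cells, "richness",
                             n_reps = 30, seed = 3)
  expect_true(all(abs(out$replicate_effectiveness) < 1e-12))

  # one cell holding all taxa dominates every random draw
  tr <- read_phylogeny("((A:1,B:1):1,C:2);")
  g <- grid_spec(1, 3)
  inc <- matrix(c(TRUE, FALSE, FALSE,
                  TRUE, TRUE, FALSE,
                  TRUE, FALSE, FALSE), nrow = 3)
  cm2 <- structure(list(grid = g, season = "breeding",
                        incidence = matrix(inc, 3,
                                           dimnames = list(NULL, c("A", "B",
                                                                   "C"))),
                        taxa = c("A", "B", "C")),
                   class = "community_matrix")
  tab <- taxon_table(c("A", "B", "C"), c(0, 1, 0))
  one <- phylocover:::site_set(0L, source = "focal")
  eff <- effectiveness_total(cm2, tr, tab, one, "phylo_richness",
                             n_reps = 100, seed = 7)
  expect_equal(eff$observed_site_value, tree_total_length(tr))
  expect_true(all(eff$replicate_effectiveness >= -1e-12))
})

test_that("total-mode values match a naive two-pass union oracle", {
  sc <- generate_scenario(small_config(seed = 43))
  cm <- build_community_matrix(sc$layers, sc$grid, "breeding")
  sites <- sc$sites
  inc <- cm$incidence
  union_taxa <- cm$taxa[colSums(inc[sites$cell_ids + 1L, , drop = FALSE]) > 0]
  for (metric in c("richness", "rl_richness", "phylo_richness",
                   "phylo_distinctiveness")) {
    out <- effectiveness_total(cm, sc$tree, sc$table, sites, metric,
                               n_reps = 20, seed = 5)
    want <- switch(metric,
      richness = length(union_taxa),
      rl_richness = sum(sc$table$rl_flag[match(union_taxa, sc$table$taxon)]),
      phylo_richness = pd_oracle(sc$tree, union_taxa),
      phylo_distinctiveness = mpd_oracle(sc$tree, union_taxa))
    expect_equal(out$observed_site_value, want, tolerance = 1e-9)
  }
})
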