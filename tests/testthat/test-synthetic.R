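test_that("Yule trees are ultrametric with unit height", {
  for (n in c(2, 5, 40)) {
    tr <- simulate_yule_tree(n, seed = n)
    expect_equal(length(tr$tip.label), n)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_true(all(abs(depths - 1) < 1e-9))
  }
  expect_error(simulate_yule_tree(1), ">= 2")

  two <- simulate_yule_tree(2, seed = 1)
  expect_equal(sort(ape::node.depth.edgelength(two)[1:2]), c(1, 1))
})

test_that("lineage accumulation in relative time is exponential in shape", {
  # pure birth: the log of the number of lineages present at relative depth
  # t should rise roughly linearly in t, averaged over replicates
  set.seed(90)
  times <- seq(0.2, 0.9, by = 0.1)
  counts <- matrix(0, nrow = 60, ncol = length(times))
  for (r in 1:60) {
    tr <- simulate_yule_tree(40)
    bt <- ape::node.depth.edgelength(tr)  # node depths, root = 0
    node_depth <- bt[-seq_len(40)]
    counts[r, ] <- vapply(times, function(t) 1 + sum(node_depth <= t),
                          numeric(1))
  }
  avg <- colMeans(counts)
  expect_true(all(diff(avg) > 0))
  fit <- stats::lm(log(avg) ~ times)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("ranges have the requested size and are 4-connected", {
  cfg <- small_config(seed = 3, range_size = 1)
  rng <- simulate_ranges(cfg, seed = 3)
  breeding <- Filter(function(l) l$season == "breeding", rng$layers)
  expect_true(all(lengths(lapply(breeding, `[[`, "cells")) == 1L))

  cfg2 <- small_config(seed = 4, range_size = 15)
  rng2 <- simulate_ranges(cfg2, seed = 4)
  is_connected <- function(cells, n_rows, n_cols) {
    seen <- cells[1]
    frontier <- cells[1]
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, phylocover:::cell_neighbours,
                                 n_rows = n_rows, n_cols = n_cols)))
      frontier <- setdiff(intersect(nb, cells), seen)
      seen <- c(seen, frontier)
    }
    length(seen) == length(cells)
  }
  for (l in rng2$layers)
    if (l$season == "breeding")
      expect_true(is_connected(l$cells, cfg2$n_rows, cfg2$n_cols))
})

test_that("wintering ranges are the breeding ranges shifted south", {
  cfg <- small_config(seed = 5, wintering_shift = 3)
  rng <- simulate_ranges(cfg, seed = 5)
  by_taxon <- split(rng$layers, vapply(rng$layers, `[[`, "", "taxon"))
  for (pair in by_taxon) {
    seasons <- vapply(pair, `[[`, "", "season")
    b <- pair[[which(seasons == "breeding")]]$cells
    w <- pair[[which(seasons == "wintering")]]$cells
    keep <- (b %/% cfg$n_cols + 3L) < cfg$n_rows
    expect_equal(w, (b + 3L * cfg$n_cols)[keep])
  }
})

test_that("mean richness matches the occupancy identity without gradient", {
  tot <- 0
  reps <- 20
  for (r in 1:reps) {
    cfg <- small_config(seed = 100 + r, richness_gradient = 0,
                        range_size = 10)
    rng <- simulate_ranges(cfg, seed = 100 + r)
    cm <- build_community_matrix(rng$layers, rng$grid, "breeding")
    tot <- tot + mean(rowSums(cm$incidence))
  }
  want <- 12 * 10 / 100  # n_species * range_size / n_cells
  expect_equal(tot / reps, want, tolerance = 0.01)
})

test_that("flag assignment hits the exact count in both modes", {
  tr <- simulate_yule_tree(20, seed = 8)
  tab <- assign_flags(tr, 0.25, "random", seed = 1)
  expect_equal(sum(tab$rl_flag), 5L)

  # fraction forcing all but one tip
  tab2 <- assign_flags(tr, 0.95, "random", seed = 1)
  expect_equal(sum(tab2$rl_flag), 20L - 1L)

  clustered <- assign_flags(tr, 0.25, "clustered")
  expect_equal(sum(clustered$rl_flag), 5L)
  # flagged tips come from one clade: their MRCA subtends few extra tips
  flagged <- clustered$taxon[clustered$rl_flag]
  mrca <- ape::getMRCA(tr, flagged)
  clade_tips <- ape::extract.clade(tr, mrca)$tip.label
  expect_true(all(flagged %in% clade_tips))
  # the smallest enclosing clade cannot be smaller than the flag count
  expect_gte(length(clade_tips), 5L)
})

test_that("site placement honours each mode", {
  sc <- generate_scenario(small_config(seed = 9))
  cfg_top <- small_config(seed = 9, site_mode = "top_richness", n_sites = 1)
  top <- place_sites(sc$profiles, sc$table, cfg_top)
  expect_equal(top$cell_ids,
               which.max(sc$profiles$richness$values) - 1L)

  cfg_rand <- small_config(seed = 9, site_mode = "random")
  r1 <- place_sites(sc$profiles, sc$table, cfg_rand, seed = 4)
  r2 <- place_sites(sc$profiles, sc$table, cfg_rand, seed = 4)
  expect_identical(r1$cell_ids, r2$cell_ids)

  cfg_rl <- small_config(seed = 9, site_mode = "rl_cells")
  rl <- place_sites(sc$profiles, sc$table, cfg_rl, seed = 4)
  expect_true(all(sc$profiles$rl_richness$values[rl$cell_ids + 1L] > 0))

  cfg_starved <- small_config(seed = 9, site_mode = "rl_cells", n_sites = 99)
  eligible <- sum(sc$profiles$rl_richness$values > 0)
  if (eligible < 99)
    expect_error(place_sites(sc$profiles, sc$table, cfg_starved), "cannot")
})

test_that("sites in flagged cells see above-average flagged richness", {
  hits <- 0
  for (r in 1:20) {
    sc <- generate_scenario(small_config(seed = 300 + r,
                                         site_mode = "rl_cells"))
    rlv <- sc$profiles$rl_richness$values
    if (mean(rlv[sc$sites$cell_ids + 1L]) >= mean(rlv)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("scenario generation is reproducible byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 12)
  generate_scenario(cfg, dir = d1)
  generate_scenario(cfg, dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("written scenario files parse back into equal objects", {
  d <- withr::local_tempdir()
  cfg <- small_config(seed = 13)
  sc <- generate_scenario(cfg, dir = d)

  tree_back <- read_phylogeny(file = file.path(d, "tree.nwk"))
  expect_equal(patristic_matrix(tree_back)[sc$tree$tip.label,
                                           sc$tree$tip.label],
               patristic_matrix(sc$tree), tolerance = 1e-9)

  tab_back <- read_taxon_table(file.path(d, "taxa.csv"))
  expect_equal(tab_back$taxon, sc$table$taxon)
  expect_equal(tab_back$rl_flag, sc$table$rl_flag)

  grid <- read_grid_header(list.files(file.path(d, "grids"),
                                      full.names = TRUE)[1])
  for (l in sc$layers) {
    f <- file.path(d, "grids", paste0(l$taxon, ".", l$season, ".grid"))
    expect_equal(read_presence_raster(f, grid, l$taxon, l$season)$cells,
                 l$cells)
  }

  sites_back <- map_points_to_cells(read_sites(file.path(d, "sites.csv")),
                                    grid)
  expect_setequal(sites_back$cell_ids, sc$sites$cell_ids)
})
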