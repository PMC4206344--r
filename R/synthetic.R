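# Synthetic study scenarios: a Yule phylogeny, spatially contiguous species
# ranges grown by spreading dye on a gridded landscape with a north-south
# richness gradient, a southward-shifted wintering season, a flagged
# (red-list) taxon subset, and focal site cells — everything the pipeline
# consumes, with known structure.

#' Scenario configuration
#'
#' Defaults describe the standard study scenario: 200 species on a 60 x 60
#' grid at 0.03-degree cells, contiguous ranges of 150 cells, a moderate
#' southward richness gradient, wintering ranges displaced 10 rows south,
#' 5% of taxa flagged, and 40 focal sites placed in cells holding flagged
#' species (emulating site selection driven by threatened species).
#'
#' @param n_species number of taxa.
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell edge length (degrees).
#' @param range_size cells per species range (before boundary truncation of
#'   the wintering layer).
#' @param richness_gradient strength of the southward seeding bias; a
#'   species' seed cell is drawn with probability proportional to
#'   `exp(richness_gradient * row / (n_rows - 1))`, so 0 means no gradient.
#' @param wintering_shift rows by which wintering ranges are displaced toward
#'   higher row indices (south), truncated at the grid edge.
#' @param rl_fraction fraction of taxa flagged as red-list, in (0, 1).
#' @param rl_mode `"random"` (uniform subset) or `"clustered"` (tips of the
#'   smallest clade of sufficient size — the phylogenetically non-random case
#'   the tip-shuffle null is built to detect).
#' @param site_mode `"random"`, `"top_richness"` or `"rl_cells"` (uniform
#'   among cells holding at least one flagged species).
#' @param n_sites number of focal site cells.
#' @param seed integer seed; scenario generation is a pure function of the
#'   config, so the same config reproduces the same scenario byte for byte.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_species = 200, n_rows = 60, n_cols = 60,
                            cell_size = 0.03, range_size = 150,
                            richness_gradient = 2, wintering_shift = 10,
                            rl_fraction = 0.05, rl_mode = "random",
                            site_mode = "rl_cells", n_sites = 40,
                            seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size = cell_size, range_size = as.integer(range_size),
              richness_gradient = richness_gradient,
              wintering_shift = as.integer(wintering_shift),
              rl_fraction = rl_fraction,
              rl_mode = match.arg(rl_mode, c("random", "clustered")),
              site_mode = match.arg(site_mode,
                                    c("random", "top_richness", "rl_cells")),
              n_sites = as.integer(n_sites), seed = as.integer(seed))
  if (cfg$n_species < 2L) stop("need at least 2 species")
  if (cfg$range_size < 1L || cfg$range_size > cfg$n_rows * cfg$n_cols)
    stop("range_size must be between 1 and the number of grid cells")
  if (cfg$rl_fraction <= 0 || cfg$rl_fraction >= 1)
    stop("rl_fraction must be in (0, 1)")
  if (cfg$n_sites < 1L || cfg$n_sites > cfg$n_rows * cfg$n_cols)
    stop("n_sites must be between 1 and the number of grid cells")
  if (cfg$richness_gradient < 0) stop("richness_gradient must be >= 0")
  if (cfg$wintering_shift < 0) stop("wintering_shift must be >= 0")
  structure(cfg, class = "scenario_config")
}

#' Simulate a pure-birth (Yule) phylogeny scaled to unit height
#'
#' A rooted ultrametric pure-birth tree conditioned on the number of tips,
#' rescaled so every root-to-tip depth is exactly 1, with tips relabelled
#' `sp001`, `sp002`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed.
#' @return a `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(node_depths(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  validate_phylogeny(tree)
  tree
}

cell_neighbours <- function(cell, n_rows, n_cols) {
  row <- cell %/% n_cols; col <- cell %% n_cols
  nb <- integer(0)
  if (row > 0L) nb <- c(nb, cell - n_cols)
  if (row < n_rows - 1L) nb <- c(nb, cell + n_cols)
  if (col > 0L) nb <- c(nb, cell - 1L)
  if (col < n_cols - 1L) nb <- c(nb, cell + 1L)
  nb
}

# spreading dye: grow a 4-connected region of `size` cells from `seed_cell`
# by uniform random accretion over the current frontier
grow_range <- function(seed_cell, size, n_rows, n_cols) {
  n <- n_rows * n_cols
  if (size > n) stop("range larger than the grid")
  occ <- logical(n)
  in_front <- logical(n)
  frontier <- integer(0)
  cells <- integer(size)
  take <- function(cell) {
    occ[cell + 1L] <<- TRUE
    in_front[cell + 1L] <<- FALSE
    for (nb in cell_neighbours(cell, n_rows, n_cols)) {
      if (!occ[nb + 1L] && !in_front[nb + 1L]) {
        frontier[length(frontier) + 1L] <<- nb
        in_front[nb + 1L] <<- TRUE
      }
    }
  }
  take(seed_cell)
  cells[1L] <- seed_cell
  count <- 1L
  while (count < size) {
    if (!length(frontier)) stop("range growth exhausted the grid")
    j <- if (length(frontier) == 1L) 1L else sample.int(length(frontier), 1L)
    cell <- frontier[j]
    frontier[j] <- frontier[length(frontier)]
    frontier <- frontier[-length(frontier)]
    count <- count + 1L
    cells[count] <- cell
    take(cell)
  }
  sort(cells)
}

#' Simulate contiguous seasonal species ranges
#'
#' Each species gets a breeding range grown by spreading dye (uniform
#' 4-neighbour accretion) from a seed cell whose row is biased southward by
#' `richness_gradient`; the wintering range is the breeding range translated
#' `wintering_shift` rows south and truncated at the grid boundary, so
#' breeding/wintering contrasts are controlled and testable.
#'
#' @param config a `scenario_config`.
#' @param seed optional integer seed (omit to draw from the current RNG
#'   state, as [generate_scenario()] does).
#' @return list with `$layers` (presence layers, both seasons), `$grid`.
#' @export
simulate_ranges <- function(config, seed = NULL) {
  grid <- grid_spec(config$n_rows, config$n_cols,
                    cell_size = config$cell_size)
  n <- n_cells(grid)
  rows <- (seq_len(n) - 1L) %/% grid$n_cols
  w <- exp(config$richness_gradient * rows / max(1L, grid$n_rows - 1L))
  taxa <- sprintf("sp%03d", seq_len(config$n_species))
  layers <- with_seed(seed, {
    out <- vector("list", 2L * config$n_species)
    for (i in seq_len(config$n_species)) {
      seed_cell <- sample.int(n, 1L, prob = w) - 1L
      breeding <- grow_range(seed_cell, config$range_size,
                             grid$n_rows, grid$n_cols)
      shifted_row <- breeding %/% grid$n_cols + config$wintering_shift
      wintering <- (breeding + config$wintering_shift * grid$n_cols)[
        shifted_row < grid$n_rows]
      out[[2L * i - 1L]] <- presence_layer(taxa[i], "breeding", breeding, grid)
      out[[2L * i]] <- presence_layer(taxa[i], "wintering", wintering, grid)
    }
    out
  })
  list(layers = layers, grid = grid)
}

clade_tip_lists <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + nn)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(desc[(nt + 1L):(nt + nn)],
         function(ix) tree$tip.label[sort(ix)])
}

#' Flag a red-list subset of taxa
#'
#' `random` mode flags a uniform subset of exactly
#' `ceiling(rl_fraction * n)` tips; `clustered` mode flags the tips of the
#' smallest clade with at least that many tips (truncated to size, in tip
#' order), producing the phylogenetically clustered case a tip-shuffle null
#' should reject.
#'
#' @param tree a `phylo`.
#' @param rl_fraction fraction of tips to flag, in (0, 1).
#' @param rl_mode `"random"` or `"clustered"`.
#' @param seed optional integer seed.
#' @return a taxon table (see [taxon_table()]) with `rl_flag` set.
#' @export
assign_flags <- function(tree, rl_fraction, rl_mode = "random", seed = NULL) {
  rl_mode <- match.arg(rl_mode, c("random", "clustered"))
  if (rl_fraction <= 0 || rl_fraction >= 1)
    stop("rl_fraction must be in (0, 1)")
  tips <- tree$tip.label
  m <- as.integer(ceiling(rl_fraction * length(tips)))
  flagged <- if (rl_mode == "random") {
    with_seed(seed, sample(tips, m))
  } else {
    clades <- clade_tip_lists(tree)
    sizes <- lengths(clades)
    ok <- which(sizes >= m)
    pick <- ok[which.min(sizes[ok])]
    clades[[pick]][seq_len(m)]
  }
  taxon_table(tips, rl_flag = tips %in% flagged)
}

#' Place focal site cells
#'
#' `random`: uniform distinct cells. `top_richness`: the `n_sites` cells of
#' highest species richness (ties by lowest cell index). `rl_cells`: uniform
#' distinct cells among cells holding at least one flagged species — the
#' in-silico analogue of designating sites for threatened species.
#'
#' @param profiles the profile list from [cell_profiles()] (uses
#'   `richness` and `rl_richness`).
#' @param table a taxon table (unused directly; kept for interface symmetry).
#' @param config a `scenario_config` (uses `site_mode`, `n_sites`).
#' @param seed optional integer seed.
#' @return a `site_set` with `source = "focal"`.
#' @export
place_sites <- function(profiles, table, config, seed = NULL) {
  n <- n_cells(profiles$richness$grid)
  k <- config$n_sites
  cells <- switch(config$site_mode,
    random = with_seed(seed, sample.int(n, k) - 1L),
    top_richness = {
      v <- profiles$richness$values
      order(-v, seq_len(n))[seq_len(k)] - 1L
    },
    rl_cells = {
      eligible <- which(profiles$rl_richness$values > 0) - 1L
      if (length(eligible) < k)
        stop("only ", length(eligible),
             " cells contain flagged species; cannot place ", k, " sites",
             call. = FALSE)
      with_seed(seed, eligible[sample.int(length(eligible), k)])
    })
  site_set(cells, source = "focal")
}

# tiny FNV-1a hash for manifest provenance (hex string); 32-bit arithmetic
# carried in doubles because R integers are 32-bit signed
fnv1a <- function(x) {
  xor32 <- function(a, b)
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
    bitwXor(a %% 65536, b %% 65536)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Generate a complete synthetic scenario
#'
#' Draws the tree, seasonal ranges, flags and focal sites from one seeded
#' RNG stream, optionally writing every artefact in the package's file
#' dialects (Newick tree, one text raster per taxon and season, taxon CSV,
#' site CSV and a JSON manifest with the config and its hash). Regenerating
#' with the same config is byte-identical.
#'
#' @param config a `scenario_config`.
#' @param dir optional output directory (created if needed).
#' @return a `scenario` bundle: `$tree`, `$layers`, `$grid`, `$table`,
#'   `$sites`, `$profiles` (breeding-season profiles used for site
#'   placement), `$config`, `$manifest`.
#' @export
generate_scenario <- function(config, dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_species)
  rng <- simulate_ranges(config)
  table <- assign_flags(tree, config$rl_fraction, config$rl_mode)
  community <- build_community_matrix(rng$layers, rng$grid, "breeding")
  profiles <- cell_profiles(community, tree, table)
  sites <- place_sites(profiles, table, config)

  manifest <- list(seed = config$seed, config = unclass(config),
                   n_layers = length(rng$layers),
                   config_hash = fnv1a(paste(
                     names(unclass(config)),
                     vapply(unclass(config), function(v)
                       paste(format(v, digits = 15), collapse = ","),
                       character(1)),
                     sep = "=", collapse = ";")))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "grids"), recursive = TRUE, showWarnings = FALSE)
    write_phylogeny(tree, file.path(dir, "tree.nwk"))
    for (l in rng$layers)
      write_presence_raster(l, file.path(dir, "grids",
                                         paste0(l$taxon, ".", l$season,
                                                ".grid")))
    tab_out <- data.frame(taxon = table$taxon,
                          rl_flag = as.integer(table$rl_flag),
                          lump_group = ifelse(is.na(table$lump_group), "",
                                              table$lump_group))
    utils::write.csv(tab_out, file.path(dir, "taxa.csv"), row.names = FALSE,
                     quote = FALSE)
    rc <- cell_to_rowcol(sites$cell_ids, rng$grid)
    sites_out <- data.frame(
      site_id = sprintf("site%03d", seq_along(sites$cell_ids)),
      x = rng$grid$origin_x + (rc[, "col"] + 0.5) * rng$grid$cell_size,
      y = rng$grid$origin_y + (rc[, "row"] + 0.5) * rng$grid$cell_size)
    utils::write.csv(sites_out, file.path(dir, "sites.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(tree = tree, layers = rng$layers, grid = rng$grid,
                 table = table, sites = sites, profiles = profiles,
                 config = config, manifest = manifest, dir = dir),
            class = "scenario")
}
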