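# End-to-end analysis: load or generate a scenario, run the red-list
# tip-shuffle null, all effectiveness analyses, hotspot masks and coverage
# summaries from one JSON config, writing TSV/JSON/raster outputs.

# deterministic sub-seed stream so one top-level seed reproduces everything
seed_for <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 104729) %% 2147483399) + 1L
}

#' Read the grid header of a text raster
#'
#' @param path a presence-raster path.
#' @return the `grid_spec` declared in the file header.
#' @export
read_grid_header <- function(path) {
  hdr <- as.numeric(strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]])
  if (length(hdr) != 5L || anyNA(hdr)) stop("bad raster header in ", path)
  grid_spec(hdr[1], hdr[2], hdr[3], hdr[4], hdr[5])
}

#' Species and branch-length coverage of a site network
#'
#' For the union of taxa occurring in at least one site cell, reports how
#' many species (and what fraction of the pool), how many flagged species
#' (and what fraction of all flagged), and what fraction of the tree's total
#' branch length (root-inclusive PD of the union over total length) the
#' network captures.
#'
#' @param community a `community_matrix`.
#' @param tree a rooted `phylo` on the community taxa.
#' @param table a taxon table with red-list flags.
#' @param sites a non-empty `site_set`.
#' @return a `coverage_summary` list.
#' @export
coverage_summary <- function(community, tree, table, sites) {
  if (length(sites$cell_ids) == 0L) stop("empty site set", call. = FALSE)
  reconcile_taxa(community$taxa, tree$tip.label, table$taxon)
  inc <- community$incidence
  idx <- sites$cell_ids + 1L
  present <- colSums(inc[idx, , drop = FALSE]) > 0
  taxa_in <- community$taxa[present]
  flags <- table$rl_flag[match(community$taxa, table$taxon)]
  total_len <- tree_total_length(tree)
  pd_in <- faith_pd(tree, taxa_in)
  structure(list(
    season = community$season,
    n_species = length(community$taxa),
    n_species_in_sites = length(taxa_in),
    frac_species = length(taxa_in) / length(community$taxa),
    n_flagged = sum(flags),
    n_flagged_in_sites = sum(flags[present]),
    frac_flagged = if (sum(flags) > 0) sum(flags[present]) / sum(flags)
                   else NA_real_,
    pd_in_sites = pd_in,
    total_branch_length = total_len,
    frac_branch_length = pd_in / total_len), class = "coverage_summary")
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  config$n_reps <- if (is.null(config$n_reps)) 1000L
                   else as.integer(config$n_reps)
  if (is.null(config$seasons)) config$seasons <- c("breeding", "wintering")
  for (s in config$seasons) check_season(s)
  if (is.null(config$metrics)) config$metrics <- PC_METRICS
  bad <- setdiff(config$metrics, PC_METRICS)
  if (length(bad))
    stop("unknown metric name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(config$hotspot_q)) config$hotspot_q <- 0.10
  if (config$hotspot_q <= 0 || config$hotspot_q >= 1)
    stop("hotspot_q must be in (0, 1)", call. = FALSE)
  if (is.null(config$scenario) && is.null(config$inputs))
    stop("config needs either a 'scenario' block or an 'inputs' block",
         call. = FALSE)
  config
}

load_inputs <- function(inputs) {
  tree <- read_phylogeny(file = inputs$tree)
  table <- read_taxon_table(inputs$taxa)
  files <- list.files(inputs$grids_dir, pattern = "\\.grid$",
                      full.names = TRUE)
  if (!length(files)) stop("no .grid files in ", inputs$grids_dir)
  grid <- read_grid_header(files[[1L]])
  layers <- lapply(files, function(f) {
    parts <- strsplit(basename(f), ".", fixed = TRUE)[[1]]
    read_presence_raster(f, grid, taxon = paste(
      parts[seq_len(length(parts) - 2L)], collapse = "."),
      season = parts[length(parts) - 1L])
  })
  lumped <- lump_taxa(layers, table)
  layer_taxa <- unique(vapply(lumped$layers, function(l) l$taxon,
                              character(1)))
  reconcile_taxa(layer_taxa, tree$tip.label, lumped$table$taxon)
  sites <- map_points_to_cells(read_sites(inputs$sites), grid)
  list(tree = tree, layers = lumped$layers, grid = grid,
       table = lumped$table, sites = sites)
}

#' Run the full analysis from a config
#'
#' The config (a list or path to a JSON file) must carry a `seed` and either
#' a `scenario` block (fields of [scenario_config()]) to generate synthetic
#' inputs, or an `inputs` block (`tree`, `grids_dir`, `taxa`, `sites` paths)
#' to load real-format data. Optional fields: `n_reps` (default 1000),
#' `seasons`, `metrics`, `hotspot_q` (default 0.10). The analysis runs the
#' red-list tip-shuffle null, per-cell-average and total-mode effectiveness
#' for every metric and season, hotspot masks and their Jaccard overlaps,
#' and coverage summaries; with `out_dir` set it writes `report.json`,
#' `effectiveness.tsv`, `coverage.tsv`, `rl_null.tsv` and one
#' `hotspot_<metric>_<season>.grid` raster per mask. Given the same config
#' the report is identical run to run.
#'
#' @param config a list or JSON file path.
#' @param out_dir optional output directory.
#' @return an `analysis_report`.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_config(config)
  seed <- as.integer(config$seed)

  if (!is.null(config$scenario)) {
    sc_args <- config$scenario
    sc_args$seed <- if (is.null(sc_args$seed)) seed_for(seed, 0L)
                    else sc_args$seed
    sc <- generate_scenario(do.call(scenario_config, sc_args))
    data <- list(tree = sc$tree, layers = sc$layers, grid = sc$grid,
                 table = sc$table, sites = sc$sites)
  } else {
    data <- load_inputs(config$inputs)
  }

  flagged <- data$table$taxon[data$table$rl_flag]
  rl_null <- tip_shuffle_null(data$tree, flagged, n_reps = config$n_reps,
                              seed = seed_for(seed, 1L))

  effectiveness <- list()
  coverage <- list()
  masks <- list()
  overlaps <- list()
  i <- 10L
  for (season in config$seasons) {
    community <- build_community_matrix(data$layers, data$grid, season)
    profiles <- cell_profiles(community, data$tree, data$table)
    # a degenerate site set (metric zero or undefined on every site cell) is
    # recorded as an explicit skip, never silently dropped
    as_skip <- function(metric, season, mode) function(e)
      structure(list(metric = metric, season = season, mode = mode,
                     skipped = TRUE, reason = conditionMessage(e)),
                class = "skipped_analysis")
    for (metric in config$metrics) {
      effectiveness[[paste(metric, season, "average", sep = ".")]] <-
        tryCatch(effectiveness_average(profiles[[metric]], data$sites,
                                       n_reps = config$n_reps,
                                       seed = seed_for(seed, i <- i + 1L)),
                 error = as_skip(metric, season, "average"))
      effectiveness[[paste(metric, season, "total", sep = ".")]] <-
        tryCatch(effectiveness_total(community, data$tree, data$table,
                                     data$sites, metric,
                                     n_reps = config$n_reps,
                                     seed = seed_for(seed, i <- i + 1L)),
                 error = as_skip(metric, season, "total"))
      masks[[paste(metric, season, sep = ".")]] <-
        hotspot_mask(profiles[[metric]], q = config$hotspot_q)
    }
    ov <- matrix(NA_real_, length(config$metrics), length(config$metrics),
                 dimnames = list(config$metrics, config$metrics))
    for (a in config$metrics) for (b in config$metrics)
      ov[a, b] <- mask_overlap(masks[[paste(a, season, sep = ".")]],
                               masks[[paste(b, season, sep = ".")]])
    overlaps[[season]] <- ov
    coverage[[season]] <- coverage_summary(community, data$tree, data$table,
                                           data$sites)
  }

  report <- structure(list(
    rl_null = rl_null,
    effectiveness = effectiveness,
    coverage = coverage,
    hotspot_overlaps = overlaps,
    masks = masks,
    provenance = list(seed = seed, n_reps = config$n_reps,
                      seasons = config$seasons, metrics = config$metrics,
                      hotspot_q = config$hotspot_q,
                      config = config[setdiff(names(config), "inputs")],
                      n_sites = length(data$sites$cell_ids))),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Tabulate the effectiveness results of a report
#'
#' @param report an `analysis_report`.
#' @return a data frame, one row per metric x season x mode.
#' @export
effectiveness_table <- function(report) {
  do.call(rbind, lapply(unname(report$effectiveness), function(e) {
    if (inherits(e, "skipped_analysis"))
      data.frame(metric = e$metric, season = e$season, mode = e$mode,
                 observed = NA_real_, mean_effectiveness = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 significant = NA, note = e$reason)
    else
      data.frame(metric = e$metric, season = e$season, mode = e$mode,
                 observed = e$observed_site_value,
                 mean_effectiveness = e$mean_effectiveness,
                 ci_lower = e$lower, ci_upper = e$upper,
                 significant = e$significant, note = "")
  }))
}

coverage_table <- function(report) {
  do.call(rbind, lapply(unname(report$coverage), function(cv)
    as.data.frame(unclass(cv))))
}

#' Write an analysis report to disk
#'
#' @param report an `analysis_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(effectiveness_table(report),
                     file.path(out_dir, "effectiveness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(coverage_table(report),
                     file.path(out_dir, "coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rn <- report$rl_null
  utils::write.table(data.frame(observed = rn$observed, lower = rn$lower,
                                upper = rn$upper, n_reps = rn$n_reps,
                                n_flagged = rn$n_flagged,
                                verdict = rn$verdict),
                     file.path(out_dir, "rl_null.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(report$masks)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    write_hotspot_raster(report$masks[[key]],
                         file.path(out_dir, paste0("hotspot_", parts[1],
                                                   "_", parts[2], ".grid")))
  }
  json <- list(
    provenance = report$provenance,
    rl_null = unclass(report$rl_null),
    effectiveness = lapply(report$effectiveness, unclass),
    coverage = lapply(report$coverage, unclass),
    hotspot_overlaps = report$hotspot_overlaps)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(out_dir)
}
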