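# Null models: the tip-shuffle null for the branch length spanned by a
# flagged (red-list) subset, and the random-cell effectiveness analysis.
#
# All randomness is drawn from R's RNG; every entry point takes an optional
# integer seed so a whole analysis can be reproduced from one seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Percentile interval by linear interpolation between order statistics
#'
#' The single quantile convention used throughout the package (type-7
#' interpolation): for n sorted values the p-quantile sits at position
#' 1 + p(n-1), linearly interpolated.
#'
#' @param values numeric vector (at least one value; `NA`s removed with a
#'   warning).
#' @param probs two probabilities, default the 2.5% and 97.5% percentiles.
#' @return numeric vector of the same length as `probs`.
#' @export
percentile_interval <- function(values, probs = c(0.025, 0.975)) {
  if (anyNA(values)) {
    warning("removing ", sum(is.na(values)), " undefined value(s)")
    values <- values[!is.na(values)]
  }
  if (length(values) == 0L) stop("no values to take percentiles of",
                                 call. = FALSE)
  stats::quantile(values, probs = probs, type = 7, names = FALSE)
}

#' Tip-shuffle null for the branch length spanned by flagged taxa
#'
#' Tests whether the (root-inclusive) branch length connecting a flagged
#' subset of tips differs from chance expectation. Each replicate shuffles
#' the taxon labels uniformly across the tips of the fixed tree and measures
#' the branch length spanned by the flagged labels' new positions —
#' equivalently, [faith_pd()] of a uniformly random subset of the same size.
#' The 2.5% and 97.5% percentiles of the replicates form the null confidence
#' interval; an observed value outside it indicates the flagged taxa are
#' non-randomly placed on the tree.
#'
#' @param tree a rooted `phylo`.
#' @param flagged non-empty character vector of flagged tip labels.
#' @param n_reps number of label shuffles (default 1000).
#' @param seed optional integer seed.
#' @return a `null_ci` object: observed value, replicate vector, CI bounds
#'   and a verdict (`"below"`, `"inside"` or `"above"` the interval).
#' @export
tip_shuffle_null <- function(tree, flagged, n_reps = 1000, seed = NULL) {
  validate_phylogeny(tree)
  flagged <- unique(as.character(flagged))
  if (length(flagged) == 0L) stop("'flagged' must be non-empty")
  bad <- setdiff(flagged, tree$tip.label)
  if (length(bad))
    stop("flagged taxa not in tree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  observed <- faith_pd(tree, flagged)
  em <- pd_edge_matrix(tree)
  S <- length(tree$tip.label)
  k <- length(flagged)
  reps <- with_seed(seed, {
    subsets <- matrix(0, nrow = n_reps, ncol = S)
    for (r in seq_len(n_reps)) subsets[r, sample.int(S, k)] <- 1
    pd_batch(em, subsets)
  })
  ci <- percentile_interval(reps)
  verdict <- if (observed < ci[1L]) "below"
             else if (observed > ci[2L]) "above" else "inside"
  structure(list(observed = observed, replicates = reps,
                 lower = ci[1L], upper = ci[2L], n_reps = n_reps,
                 n_flagged = k, seed = seed, verdict = verdict),
            class = "null_ci")
}

#' Draw a uniform random set of distinct grid cells
#'
#' Cells are drawn without replacement with equal inclusion probability, for
#' comparison against the same number of distinct focal-site cells.
#'
#' @param n_total_cells total number of grid cells.
#' @param k number of cells to draw (`1 <= k <= n_total_cells`).
#' @param seed optional integer seed.
#' @return a `site_set` with `source = "random"` and 0-based cell ids.
#' @export
sample_random_cells <- function(n_total_cells, k, seed = NULL) {
  if (k < 1L || k > n_total_cells)
    stop("k must be between 1 and n_total_cells", call. = FALSE)
  cells <- with_seed(seed, sample.int(n_total_cells, k) - 1L)
  site_set(cells, source = "random")
}

effectiveness_result <- function(metric, season, mode, observed, reps,
                                 n_sites, n_reps, seed) {
  reps_ok <- reps[!is.na(reps)]
  ci <- percentile_interval(reps_ok)
  structure(list(metric = metric, season = season, mode = mode,
                 observed_site_value = observed,
                 replicate_effectiveness = reps,
                 mean_effectiveness = mean(reps_ok),
                 lower = ci[1L], upper = ci[2L],
                 significant = ci[1L] > 0 || ci[2L] < 0,
                 n_sites = n_sites, n_reps = n_reps, seed = seed),
            class = "effectiveness_result")
}

#' Site-network effectiveness: per-cell average mode
#'
#' Compares the mean of a per-cell diversity profile over the focal site
#' cells with the mean over an equal number of uniformly drawn random cells.
#' Per replicate r the effectiveness is
#' `E(r) = (D_site - D_rand(r)) / D_site`, and the result summarises the
#' replicates by their mean and 2.5%/97.5% percentiles; the network is called
#' effective for the metric when the interval excludes 0. Cells where the
#' metric is undefined (e.g. distinctiveness of 0- or 1-species cells) are
#' excluded from both means.
#'
#' @param profile a `diversity_profile`.
#' @param sites a `site_set` of focal cells.
#' @param n_reps number of random cell draws (default 1000).
#' @param seed optional integer seed.
#' @return an `effectiveness_result`.
#' @export
effectiveness_average <- function(profile, sites, n_reps = 1000, seed = NULL) {
  vals <- profile$values
  N <- n_cells(profile$grid)
  if (length(vals) != N) stop("profile does not match its grid")
  idx <- sites$cell_ids + 1L
  if (any(idx < 1L | idx > N)) stop("site cells outside the grid")
  site_vals <- vals[idx]
  if (all(is.na(site_vals)))
    stop("metric undefined in every site cell", call. = FALSE)
  d_site <- mean(site_vals, na.rm = TRUE)
  if (d_site == 0)
    stop("site-set mean is 0; effectiveness undefined", call. = FALSE)
  k <- length(idx)
  reps <- with_seed(seed, {
    out <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      draw <- vals[sample.int(N, k)]
      out[r] <- mean(draw, na.rm = TRUE)   # NaN if all drawn cells undefined
    }
    out
  })
  reps[is.nan(reps)] <- NA_real_
  e <- (d_site - reps) / d_site
  effectiveness_result(profile$metric, profile$season, "average",
                       d_site, e, k, n_reps, seed)
}

# metric value on a taxon union given precomputed machinery
union_metric_value <- function(metric, union_mat, flags, em, D) {
  switch(metric,
         richness = rowSums(union_mat),
         rl_richness = as.numeric(union_mat %*% flags),
         phylo_richness = pd_batch(em, union_mat),
         phylo_distinctiveness = mpd_batch(D, union_mat),
         stop("unknown metric: ", metric))
}

#' Site-network effectiveness: complementarity ('total') mode
#'
#' Evaluates a diversity measure on the union of taxa occurring in at least
#' one focal site cell, against the same measure on the union over an equal
#' number of random cells: richness is the union size, red-list richness the
#' number of flagged taxa in the union, phylogenetic richness the
#' root-inclusive Faith's PD of the union, and distinctiveness its mean
#' pairwise distance. The effectiveness statistic and its summary are as in
#' [effectiveness_average()].
#'
#' @param community a `community_matrix`.
#' @param tree a rooted `phylo` matching the community taxa.
#' @param table a taxon table with red-list flags.
#' @param sites a `site_set` of focal cells.
#' @param metric one of `"richness"`, `"rl_richness"`, `"phylo_richness"`,
#'   `"phylo_distinctiveness"`.
#' @param n_reps number of random draws (default 1000).
#' @param seed optional integer seed.
#' @return an `effectiveness_result` with `mode = "total"`.
#' @export
effectiveness_total <- function(community, tree, table, sites, metric,
                                n_reps = 1000, seed = NULL) {
  metric <- match.arg(metric, PC_METRICS)
  validate_phylogeny(tree)
  reconcile_taxa(community$taxa, tree$tip.label, table$taxon)
  inc <- community$incidence[, tree$tip.label, drop = FALSE]
  flags <- table$rl_flag[match(tree$tip.label, table$taxon)]
  N <- nrow(inc)
  idx <- sites$cell_ids + 1L
  if (any(idx < 1L | idx > N)) stop("site cells outside the grid")
  k <- length(idx)

  em <- if (metric == "phylo_richness") pd_edge_matrix(tree) else NULL
  D <- if (metric == "phylo_distinctiveness")
    patristic_matrix(tree)[tree$tip.label, tree$tip.label] else NULL

  site_union <- matrix(as.numeric(colSums(inc[idx, , drop = FALSE]) > 0),
                       nrow = 1)
  if (sum(site_union) == 0)
    stop("no taxa occur in any site cell", call. = FALSE)
  d_site <- union_metric_value(metric, site_union, flags, em, D)
  if (is.na(d_site) || d_site == 0)
    stop("site-set value is ", d_site, "; effectiveness undefined",
         call. = FALSE)

  union_mat <- with_seed(seed, {
    m <- matrix(0, nrow = n_reps, ncol = ncol(inc))
    for (r in seq_len(n_reps)) {
      draw <- sample.int(N, k)
      m[r, ] <- as.numeric(colSums(inc[draw, , drop = FALSE]) > 0)
    }
    m
  })
  d_rand <- union_metric_value(metric, union_mat, flags, em, D)
  e <- (d_site - d_rand) / d_site
  effectiveness_result(metric, community$season, "total",
                       as.numeric(d_site), e, k, n_reps, seed)
}
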