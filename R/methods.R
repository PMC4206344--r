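# print / summary / plot methods for the package's result classes

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d cells of %g at origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' @export
print.null_ci <- function(x, ...) {
  cat("Tip-shuffle null for flagged-subset branch length\n")
  cat(sprintf("  flagged tips: %d   replicates: %d\n", x$n_flagged, x$n_reps))
  cat(sprintf("  observed: %.4g   null 95%% CI: [%.4g, %.4g]\n",
              x$observed, x$lower, x$upper))
  cat(sprintf("  observed is %s the interval%s\n", x$verdict,
              if (x$verdict == "inside")
                " (no departure from random placement)" else ""))
  invisible(x)
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat(sprintf("Effectiveness (%s, %s season, '%s' mode)\n",
              x$metric, x$season, x$mode))
  cat(sprintf("  site-set value: %.4g over %d cells\n",
              x$observed_site_value, x$n_sites))
  cat(sprintf("  mean effectiveness: %.4f   95%% CI: [%.4f, %.4f]  %s\n",
              x$mean_effectiveness, x$lower, x$upper,
              if (x$significant) "(CI excludes 0)" else "(n.s.)"))
  invisible(x)
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("Coverage (%s): %d/%d species (%.1f%%)", x$season,
              x$n_species_in_sites, x$n_species, 100 * x$frac_species))
  if (!is.na(x$frac_flagged))
    cat(sprintf(", %d/%d flagged (%.1f%%)", x$n_flagged_in_sites,
                x$n_flagged, 100 * x$frac_flagged))
  cat(sprintf(", %.1f%% of total branch length\n",
              100 * x$frac_branch_length))
  invisible(x)
}

#' @export
print.hotspot_mask <- function(x, ...) {
  cat(sprintf("Hotspot mask (%s, %s): top %.0f%%, threshold %.4g, %d cells\n",
              x$metric, x$season, 100 * x$q, x$threshold, x$n_members))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d species on a %d x %d grid (seed %d)\n",
    x$config$n_species, x$config$n_rows, x$config$n_cols, x$config$seed))
  cat(sprintf("  %d flagged taxa, %d focal sites (%s mode)\n",
              sum(x$table$rl_flag), length(x$sites$cell_ids),
              x$config$site_mode))
  invisible(x)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Site-network diversity analysis\n\n")
  print(x$rl_null)
  cat("\n")
  df <- effectiveness_table(x)
  df$mean_effectiveness <- round(df$mean_effectiveness, 4)
  df$ci_lower <- round(df$ci_lower, 4)
  df$ci_upper <- round(df$ci_upper, 4)
  print(df, row.names = FALSE)
  cat("\n")
  for (cv in x$coverage) print(cv)
  invisible(x)
}

#' @export
summary.analysis_report <- function(object, ...) {
  df <- effectiveness_table(object)
  cat(sprintf("%d effectiveness analyses (%d significant, %d skipped), %d season(s)\n",
              nrow(df), sum(df$significant, na.rm = TRUE),
              sum(is.na(df$significant)), length(object$coverage)))
  cat(sprintf("red-list null verdict: observed %s the 95%% interval\n",
              object$rl_null$verdict))
  invisible(df)
}

#' Dot-and-interval plot of effectiveness results
#'
#' One point (mean effectiveness) with a 2.5--97.5% interval line per
#' metric x mode, panelled by season, with a dashed zero line — the standard
#' presentation of resampling-based effectiveness.
#'
#' @param x an `analysis_report`.
#' @param ... passed to [graphics::plot()].
#' @return the effectiveness table, invisibly.
#' @export
plot.analysis_report <- function(x, ...) {
  df <- effectiveness_table(x)
  seasons <- unique(df$season)
  op <- graphics::par(mfrow = c(length(seasons), 1),
                      mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in seasons) {
    d <- df[df$season == s, ]
    lab <- paste(d$metric, d$mode)
    ylim <- range(c(d$ci_lower, d$ci_upper, 0))
    graphics::plot(seq_len(nrow(d)), d$mean_effectiveness, ylim = ylim,
                   xaxt = "n", xlab = "", ylab = "effectiveness",
                   main = paste(s, "season"), pch = 19, ...)
    graphics::axis(1, at = seq_len(nrow(d)), labels = lab, las = 2,
                   cex.axis = 0.7)
    graphics::segments(seq_len(nrow(d)), d$ci_lower,
                       seq_len(nrow(d)), d$ci_upper)
    graphics::abline(h = 0, lty = 2, col = "grey40")
  }
  invisible(df)
}

profile_matrix <- function(values, grid) {
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Image of a per-cell diversity profile
#'
#' @param x a `diversity_profile`.
#' @param ... passed to [graphics::image()].
#' @export
plot.diversity_profile <- function(x, ...) {
  m <- profile_matrix(x$values, x$grid)
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  main = paste(x$metric, "-", x$season),
                  col = grDevices::hcl.colors(32, "viridis"),
                  axes = FALSE, ...)
  invisible(x)
}

#' Image of a hotspot mask
#'
#' @param x a `hotspot_mask`.
#' @param ... passed to [graphics::image()].
#' @export
plot.hotspot_mask <- function(x, ...) {
  m <- profile_matrix(as.numeric(x$member), x$grid)
  graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  main = sprintf("top %.0f%% %s (%s)", 100 * x$q, x$metric,
                                 x$season),
                  col = c("grey90", "firebrick"), axes = FALSE, ...)
  invisible(x)
}
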