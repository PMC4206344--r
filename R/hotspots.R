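# Top-quantile diversity hotspot masks and their spatial overlap.

#' Hotspot mask: the top fraction q of grid cells for a metric
#'
#' The threshold is the (1 - q) percentile (type-7 linear interpolation) of
#' the defined cell values; a cell is a member when its value is >= the
#' threshold. All threshold ties are included, so the member count can exceed
#' q * N; cells where the metric is undefined are excluded from both the
#' percentile computation and membership.
#'
#' @param profile a `diversity_profile`.
#' @param q fraction of cells to highlight, in (0, 1); default 0.10.
#' @return a `hotspot_mask`: logical `$member` per cell, `$threshold`, the
#'   profile's grid/metric/season, and `$n_members`.
#' @export
hotspot_mask <- function(profile, q = 0.10) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  vals <- profile$values
  defined <- !is.na(vals)
  if (!any(defined)) stop("no defined cells to rank", call. = FALSE)
  threshold <- percentile_interval(vals[defined], probs = 1 - q)
  member <- defined & vals >= threshold
  structure(list(grid = profile$grid, metric = profile$metric,
                 season = profile$season, q = q, threshold = threshold,
                 member = member, n_members = sum(member)),
            class = "hotspot_mask")
}

#' Jaccard overlap of two hotspot masks
#'
#' `|a & b| / |a | b|`; 1 for identical masks (including two empty masks),
#' 0 for disjoint ones.
#'
#' @param a,b `hotspot_mask`s on the same grid.
#' @return a fraction in `[0, 1]`.
#' @export
mask_overlap <- function(a, b) {
  if (!same_grid(a$grid, b$grid)) stop("masks are on different grids")
  un <- sum(a$member | b$member)
  if (un == 0L) return(1)
  sum(a$member & b$member) / un
}

#' Write a hotspot mask as a 0/1 text raster
#'
#' Uses the same dialect as the presence layers, so masks can be re-read with
#' [read_presence_raster()].
#'
#' @param mask a `hotspot_mask`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hotspot_raster <- function(mask, path) {
  layer <- presence_layer(paste0("hotspot_", mask$metric), mask$season,
                          which(mask$member) - 1L, mask$grid)
  write_presence_raster(layer, path)
}
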