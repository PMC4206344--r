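# Gridded landscape, presence rasters and community assembly.
#
# Cell indexing is row-major and 0-based everywhere: cell = row * n_cols +
# col, with row 0 at origin_y and rows increasing "downward" (raster order).
# Cell intervals are half-open: a point with coordinate origin + i*cell_size
# <= v < origin + (i+1)*cell_size falls in band i.

#' Define a raster grid
#'
#' @param n_rows,n_cols positive integers.
#' @param origin_x,origin_y coordinates of the grid corner at cell (0, 0)
#'   (degrees or arbitrary units).
#' @param cell_size positive cell edge length (e.g. 0.03 degrees).
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = 0,
                      cell_size = 1) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid must have at least one cell")
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(list(n_rows = n_rows, n_cols = n_cols, origin_x = origin_x,
                 origin_y = origin_y, cell_size = cell_size),
            class = "grid_spec")
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Convert between cell index and (row, col)
#'
#' @param cell 0-based row-major cell indices.
#' @param grid a `grid_spec`.
#' @return `cell_to_rowcol`: a two-column matrix (row, col), 0-based.
#' @export
cell_to_rowcol <- function(cell, grid) {
  cell <- as.integer(cell)
  if (any(cell < 0L | cell >= n_cells(grid))) stop("cell index out of range")
  cbind(row = cell %/% grid$n_cols, col = cell %% grid$n_cols)
}

#' @rdname cell_to_rowcol
#' @param row,col 0-based row and column indices.
#' @return `rowcol_to_cell`: 0-based cell indices.
#' @export
rowcol_to_cell <- function(row, col, grid) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row >= grid$n_rows | col < 0L | col >= grid$n_cols))
    stop("row/col out of range")
  row * grid$n_cols + col
}

presence_layer <- function(taxon, season, cells, grid) {
  cells <- sort(unique(as.integer(cells)))
  if (length(cells) && (min(cells) < 0L || max(cells) >= n_cells(grid)))
    stop("presence cells out of grid range")
  structure(list(taxon = taxon, season = season, cells = cells, grid = grid),
            class = "presence_layer")
}

check_season <- function(season) {
  if (!season %in% c("breeding", "wintering"))
    stop("season must be 'breeding' or 'wintering'", call. = FALSE)
  season
}

#' Read a presence/absence text raster
#'
#' The dialect is a header line `rows cols origin_x origin_y cell_size`
#' followed by `rows` lines of space-separated 0/1 values (row-major).
#'
#' @param path file path (conventionally `<taxon>.<season>.grid`).
#' @param grid the expected `grid_spec`; a mismatch is an error.
#' @param taxon,season labels attached to the layer.
#' @return a `presence_layer` with 0-based occupied-cell indices.
#' @export
read_presence_raster <- function(path, grid, taxon, season) {
  check_season(season)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.numeric(strsplit(trimws(lines[1L]), "\\s+")[[1]])
  if (length(hdr) != 5L || anyNA(hdr))
    stop("bad raster header in ", path)
  if (hdr[1] != grid$n_rows || hdr[2] != grid$n_cols)
    stop("raster dimensions ", hdr[1], "x", hdr[2], " in ", path,
         " do not match grid ", grid$n_rows, "x", grid$n_cols)
  if (abs(hdr[5] - grid$cell_size) > 1e-9 ||
      abs(hdr[3] - grid$origin_x) > 1e-9 || abs(hdr[4] - grid$origin_y) > 1e-9)
    stop("raster georeference in ", path, " does not match grid")
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (length(body) != grid$n_rows)
    stop("expected ", grid$n_rows, " raster rows in ", path, ", got ",
         length(body))
  vals <- unlist(lapply(body, function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])))
  if (length(vals) != n_cells(grid))
    stop("raster body size mismatch in ", path)
  if (anyNA(vals) || !all(vals %in% c(0L, 1L)))
    stop("raster entries must be 0 or 1 in ", path)
  presence_layer(taxon, season, which(vals == 1L) - 1L, grid)
}

#' Write a presence layer in the text-raster dialect
#'
#' @param layer a `presence_layer`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_presence_raster <- function(layer, path) {
  grid <- layer$grid
  vals <- integer(n_cells(grid))
  vals[layer$cells + 1L] <- 1L
  m <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  hdr <- paste(grid$n_rows, grid$n_cols,
               format(grid$origin_x, digits = 10),
               format(grid$origin_y, digits = 10),
               format(grid$cell_size, digits = 10))
  writeLines(c(hdr, apply(m, 1L, paste, collapse = " ")), path)
  invisible(path)
}

#' Read a taxon table
#'
#' CSV with columns `taxon`, `rl_flag` (0/1 red-list membership) and
#' `lump_group` (shared label for taxa whose distributions are merged; empty
#' for stand-alone taxa).
#'
#' @param path CSV file path.
#' @return a data frame with character `taxon`, logical `rl_flag`, character
#'   `lump_group` (`NA` when absent).
#' @export
read_taxon_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  taxon_table(df$taxon, df$rl_flag, df$lump_group)
}

#' Build a taxon table in memory
#'
#' @param taxon character vector of unique taxon labels.
#' @param rl_flag logical/0-1 vector: red-list member (the user decides
#'   whether data-deficient taxa are flagged).
#' @param lump_group optional character: taxa sharing a label are merged by
#'   [lump_taxa()]; `NA`/empty means no lumping.
#' @return a validated `data.frame`.
#' @export
taxon_table <- function(taxon, rl_flag, lump_group = NULL) {
  taxon <- as.character(taxon)
  if (anyDuplicated(taxon))
    stop("duplicate taxa in taxon table: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  if (is.null(lump_group)) lump_group <- rep(NA_character_, length(taxon))
  lump_group <- as.character(lump_group)
  lump_group[!is.na(lump_group) & !nzchar(lump_group)] <- NA_character_
  grp_sizes <- table(lump_group[!is.na(lump_group)])
  if (any(grp_sizes < 2L))
    stop("lump groups must have at least 2 members: ",
         paste(names(grp_sizes)[grp_sizes < 2L], collapse = ", "))
  data.frame(taxon = taxon, rl_flag = as.logical(as.integer(rl_flag)),
             lump_group = lump_group, stringsAsFactors = FALSE)
}

#' Merge the distributions of lumped taxa
#'
#' Taxa sharing a `lump_group` in the table are replaced, per season, by one
#' layer named after the group whose occupied cells are the union of the
#' members' cells; the merged taxon's red-list flag is the logical OR of the
#' members' flags. Ungrouped taxa pass through unchanged. Applying the
#' operation twice equals applying it once.
#'
#' @param layers a list of `presence_layer`s (any mix of seasons).
#' @param table a taxon table (see [taxon_table()]).
#' @return a list with `$layers` (merged layers) and `$table` (the collapsed
#'   taxon table, lump groups cleared).
#' @export
lump_taxa <- function(layers, table) {
  layer_tax <- vapply(layers, function(l) l$taxon, character(1))
  groups <- unique(table$lump_group[!is.na(table$lump_group)])
  for (g in groups) {
    members <- table$taxon[!is.na(table$lump_group) & table$lump_group == g]
    absent <- setdiff(members, layer_tax)
    if (length(absent) && !g %in% layer_tax)
      stop("lump group '", g, "' members with no presence layer: ",
           paste(absent, collapse = ", "))
  }
  out_layers <- list()
  for (season in unique(vapply(layers, function(l) l$season, character(1)))) {
    sl <- layers[vapply(layers, function(l) l$season == season, logical(1))]
    stax <- vapply(sl, function(l) l$taxon, character(1))
    done <- logical(length(sl))
    for (g in groups) {
      members <- table$taxon[!is.na(table$lump_group) & table$lump_group == g]
      idx <- which(stax %in% c(members, g))
      if (!length(idx)) next
      cells <- sort(unique(unlist(lapply(sl[idx], function(l) l$cells))))
      out_layers[[length(out_layers) + 1L]] <-
        presence_layer(g, season, cells, sl[[idx[1L]]]$grid)
      done[idx] <- TRUE
    }
    out_layers <- c(out_layers, sl[!done])
  }
  # collapse the table rows to one per group
  keep <- is.na(table$lump_group)
  tab <- table[keep, , drop = FALSE]
  for (g in groups) {
    members <- !is.na(table$lump_group) & table$lump_group == g
    tab <- rbind(tab, data.frame(taxon = g, rl_flag = any(table$rl_flag[members]),
                                 lump_group = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  # already-lumped group rows (idempotence): drop duplicates by taxon
  tab <- tab[!duplicated(tab$taxon), , drop = FALSE]
  rownames(tab) <- NULL
  list(layers = out_layers, table = tab)
}

#' Assemble a cells-by-taxa community matrix for one season
#'
#' @param layers a list of `presence_layer`s.
#' @param grid the shared `grid_spec`.
#' @param season which season's layers to assemble.
#' @return a `community_matrix`: logical incidence matrix (cells x taxa) plus
#'   grid and season metadata.
#' @export
build_community_matrix <- function(layers, grid, season) {
  check_season(season)
  sl <- layers[vapply(layers, function(l) l$season == season, logical(1))]
  taxa <- vapply(sl, function(l) l$taxon, character(1))
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels in layers: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  inc <- matrix(FALSE, nrow = n_cells(grid), ncol = length(sl),
                dimnames = list(NULL, taxa))
  for (j in seq_along(sl)) {
    if (!same_grid(sl[[j]]$grid, grid))
      stop("layer '", taxa[j], "' is on a different grid")
    inc[sl[[j]]$cells + 1L, j] <- TRUE
  }
  structure(list(grid = grid, season = season, incidence = inc, taxa = taxa),
            class = "community_matrix")
}

#' Map site-center points to grid cells
#'
#' Each point is assigned to the cell whose half-open coordinate intervals
#' contain it. Points sharing a cell are collapsed to one (first occurrence
#' order), matching a comparison of distinct site cells against the same
#' number of distinct random cells.
#'
#' @param points a data frame with columns `x` and `y` (and optionally
#'   `site_id`), or a two-column matrix.
#' @param grid a `grid_spec`.
#' @return a `site_set`: `$cell_ids` (0-based, distinct, in first-occurrence
#'   order), `$source = "focal"`, `$n_points` (points supplied).
#' @export
map_points_to_cells <- function(points, grid) {
  points <- as.data.frame(points)
  if (is.null(points$x)) { names(points)[1:2] <- c("x", "y") }
  col <- floor((points$x - grid$origin_x) / grid$cell_size)
  row <- floor((points$y - grid$origin_y) / grid$cell_size)
  bad <- which(col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows)
  if (length(bad))
    stop("point(s) outside grid extent: ",
         paste(sprintf("(%g, %g)", points$x[bad], points$y[bad]),
               collapse = ", "), call. = FALSE)
  cells <- as.integer(row) * grid$n_cols + as.integer(col)
  site_set(unique(cells), source = "focal", n_points = nrow(points))
}

site_set <- function(cell_ids, source = c("focal", "random"), n_points = NA) {
  source <- match.arg(source)
  cell_ids <- as.integer(cell_ids)
  if (anyDuplicated(cell_ids)) stop("site cells must be distinct")
  structure(list(cell_ids = cell_ids, source = source,
                 n_points = n_points), class = "site_set")
}

#' Read site centers from CSV
#'
#' @param path CSV with columns `site_id`, `x`, `y`.
#' @return a data frame.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "x", "y") %in% names(df)))
    stop("sites file must have columns site_id, x, y")
  df
}
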