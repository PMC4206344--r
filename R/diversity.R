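# Per-cell diversity measures on a community matrix and a rooted phylogeny.
#
# Phylogenetic richness is Faith's PD in its root-inclusive form: the summed
# branch length of the UNION of root-to-tip paths of the taxa present.  This
# single convention is used everywhere branch length of a taxon subset is
# needed (per-cell PD, the red-list null, coverage fractions), so the per-cell
# and whole-network numbers are directly comparable.

#' Faith's phylogenetic diversity (root-inclusive)
#'
#' Sum of branch lengths over the union of root-to-tip paths of `taxa`.
#' With all tips supplied it equals [tree_total_length()]; with a single tip
#' it is that tip's root-to-tip depth; an empty set returns 0 by convention.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param taxa character vector of tip labels (a set; duplicates ignored).
#' @return a non-negative number.
#' @export
faith_pd <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) return(0)
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip label(s): ", paste(taxa[is.na(idx)], collapse = ", "),
         call. = FALSE)
  pt <- parent_table(tree)
  marked <- logical(max(tree$edge))
  total <- 0
  for (v in idx) {
    while (!marked[v] && !is.na(pt$parent[v])) {
      marked[v] <- TRUE
      total <- total + pt$elen[v]
      v <- pt$parent[v]
    }
  }
  total
}

#' Mean pairwise phylogenetic distance
#'
#' Mean patristic distance over all unordered pairs of distinct taxa; the
#' community-level "phylogenetic distinctiveness". Undefined (`NA`) for
#' fewer than two taxa.
#'
#' @inheritParams faith_pd
#' @return a number, or `NA_real_` when `length(taxa) < 2`.
#' @export
mean_pairwise_distance <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("unknown tip label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(taxa) < 2L) return(NA_real_)
  d <- patristic_matrix(tree)[taxa, taxa]
  sum(d) / (length(taxa) * (length(taxa) - 1L))
}

# Edge-by-tip descendant incidence: row e is TRUE for tips below edge e's
# child node.  Lets PD of many subsets be computed as one matrix product:
# PD(x) = sum(len[e] : desc[e, ] & x intersect).
pd_edge_matrix <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- matrix(FALSE, nrow = nt + nn, ncol = nt)
  desc[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  child <- tree$edge[, 2L]
  list(desc = desc[child, , drop = FALSE] * 1,  # numeric for fast %*%
       len = tree$edge.length, tips = tree$tip.label)
}

# Vectorised PD for a 0/1 subset matrix (subsets x tips, columns in
# em$tips order): one edge is counted when any of its descendant tips is in
# the subset.
pd_batch <- function(em, subsets) {
  hits <- em$desc %*% t(subsets)      # edges x subsets intersection counts
  as.numeric(crossprod(hits > 0, em$len))
}

# Vectorised MPD for a 0/1 subset matrix given a patristic matrix D (ordered
# as the subset columns): x'Dx / (k(k-1)).
mpd_batch <- function(D, subsets) {
  k <- rowSums(subsets)
  q <- rowSums((subsets %*% D) * subsets)
  out <- ifelse(k >= 2, q / (k * (k - 1)), NA_real_)
  as.numeric(out)
}

diversity_profile <- function(grid, season, metric, values) {
  structure(list(grid = grid, season = season, metric = metric,
                 values = as.numeric(values)),
            class = "diversity_profile")
}

PC_METRICS <- c("richness", "rl_richness", "phylo_richness",
                "phylo_distinctiveness")

#' Per-cell diversity profiles
#'
#' Computes, for every grid cell of a seasonal community matrix, the four
#' diversity measures: species richness, red-list richness, phylogenetic
#' richness (root-inclusive Faith's PD; 0 for empty cells) and phylogenetic
#' distinctiveness (mean pairwise patristic distance; undefined, `NA`, where
#' fewer than two taxa are present).
#'
#' @param community a `community_matrix` (see [build_community_matrix()]).
#' @param tree a rooted `phylo`; tips must coincide with the community taxa.
#' @param table a taxon table supplying the red-list flags.
#' @return a named list of four `diversity_profile`s.
#' @export
cell_profiles <- function(community, tree, table) {
  validate_phylogeny(tree)
  reconcile_taxa(community$taxa, tree$tip.label, table$taxon)
  inc <- community$incidence[, tree$tip.label, drop = FALSE] * 1
  flags <- table$rl_flag[match(tree$tip.label, table$taxon)]

  richness <- rowSums(inc)
  rl_rich <- as.numeric(inc %*% flags)
  em <- pd_edge_matrix(tree)
  pd <- pd_batch(em, inc)
  D <- patristic_matrix(tree)[tree$tip.label, tree$tip.label]
  mpd <- mpd_batch(D, inc)

  grid <- community$grid; season <- community$season
  list(richness = diversity_profile(grid, season, "richness", richness),
       rl_richness = diversity_profile(grid, season, "rl_richness", rl_rich),
       phylo_richness = diversity_profile(grid, season, "phylo_richness", pd),
       phylo_distinctiveness =
         diversity_profile(grid, season, "phylo_distinctiveness", mpd))
}

# Taxon-set reconciliation: community taxa, tree tips and table taxa must
# coincide exactly; mismatches are reported, never silently dropped.
reconcile_taxa <- function(community_taxa, tree_tips, table_taxa) {
  report <- character(0)
  chk <- function(a, b, la, lb) {
    extra <- setdiff(a, b)
    if (length(extra))
      report <<- c(report, paste0("in ", la, " but not ", lb, ": ",
                                  paste(extra, collapse = ", ")))
  }
  chk(community_taxa, tree_tips, "community", "tree")
  chk(tree_tips, community_taxa, "tree", "community")
  chk(table_taxa, tree_tips, "taxon table", "tree")
  chk(tree_tips, table_taxa, "tree", "taxon table")
  if (length(report))
    stop("taxon sets do not match:\n  ", paste(report, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a diversity profile as TSV
#'
#' Columns: `cell_id`, `row`, `col`, `metric`, `season`, `value` (empty field
#' where the metric is undefined).
#'
#' @param profile a `diversity_profile`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  grid <- profile$grid
  ids <- seq_len(n_cells(grid)) - 1L
  rc <- cell_to_rowcol(ids, grid)
  df <- data.frame(cell_id = ids, row = rc[, "row"], col = rc[, "col"],
                   metric = profile$metric, season = profile$season,
                   value = profile$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
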