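# Brute-force oracles kept deliberately independent of the package's
# implementations: they enumerate node paths with ape::nodepath and sum edge
# lengths by matching rows of tree$edge, instead of the package's
# parent-walk edge marking / matrix algebra.

edge_length_of <- function(tree, parent, child) {
  tree$edge.length[tree$edge[, 1] == parent & tree$edge[, 2] == child]
}

# root-to-tip path-union PD: mark every edge on every root-to-tip path
pd_oracle <- function(tree, taxa) {
  if (length(taxa) == 0) return(0)
  root <- length(tree$tip.label) + 1L
  edges <- character(0)
  for (tip in match(taxa, tree$tip.label)) {
    path <- ape::nodepath(tree, root, tip)
    edges <- union(edges, paste(path[-length(path)], path[-1]))
  }
  sum(vapply(strsplit(edges, " "), function(p)
    edge_length_of(tree, as.integer(p[1]), as.integer(p[2])), numeric(1)))
}

# pairwise patristic distance by summing edges on the a-b node path
patristic_oracle <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  if (ia == ib) return(0)
  path <- ape::nodepath(tree, ia, ib)
  tot <- 0
  for (i in seq_len(length(path) - 1)) {
    p <- path[i]; q <- path[i + 1]
    len <- edge_length_of(tree, p, q)
    if (!length(len)) len <- edge_length_of(tree, q, p)
    tot <- tot + len
  }
  tot
}

# all-pairs mean of the patristic oracle
mpd_oracle <- function(tree, taxa) {
  if (length(taxa) < 2) return(NA_real_)
  pairs <- utils::combn(taxa, 2)
  mean(apply(pairs, 2, function(p) patristic_oracle(tree, p[1], p[2])))
}

# random rooted tree with branch lengths (ape's default runif lengths)
random_tree <- function(n) ape::rtree(n)

# compact synthetic scenario for fast pipeline tests
small_config <- function(seed, ...) {
  args <- list(n_species = 12, n_rows = 10, n_cols = 10, range_size = 8,
               richness_gradient = 2, wintering_shift = 2,
               rl_fraction = 0.2, n_sites = 5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(scenario_config, args)
}

write_raster_text <- function(path, lines) writeLines(lines, path)
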