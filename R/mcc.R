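# Maximum clade credibility consensus from a tree sample.
#
# The MCC tree is chosen FROM the sample: each tree is scored by the sum over
# its internal clades of log(clade frequency in the sample) — equivalent to
# the product of clade credibilities — and the best-scoring tree wins (ties
# go to the lowest sample index).  Node heights on the winner are then
# replaced by the mean height of the matching clade across the sample trees
# that contain it (clade-match convention).  A node's height is measured from
# the tips: height = (tree's maximum root-to-tip depth) - (root-to-node
# depth), so for ultrametric trees it is the usual time-before-present.

clade_tipsets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nt + nn)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply((nt + 1L):(nt + nn),
         function(i) paste(sort(desc[[i]]), collapse = "\r"),
         character(1))
}

# per-node heights measured from the tips (see above); indexed by node id
node_heights <- function(tree) {
  depth <- node_depths(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

#' Maximum clade credibility tree with mean node heights
#'
#' Selects, from a sample of rooted trees on a shared tip set, the tree whose
#' internal clades are jointly most frequent in the sample (maximum product
#' of clade frequencies; ties broken by lowest sample index), then replaces
#' each internal node's height by the mean height of the matching clade over
#' the sample trees containing that clade. Branch lengths are recomputed from
#' the adjusted heights; tips keep their original heights. If conflicting
#' clade means would imply a negative branch it is clamped to zero with a
#' warning, as consensus height averaging can produce.
#'
#' @param sample a list of validated `phylo` trees on one tip set (e.g. from
#'   [read_tree_sample()]).
#' @return a `phylo` tree with attributes `mcc_index` (which sample tree was
#'   selected) and `mcc_score` (its summed log clade frequency).
#' @export
mcc_tree <- function(sample) {
  if (inherits(sample, "phylo")) sample <- list(sample)
  if (length(sample) == 0L) stop("empty tree sample", call. = FALSE)
  for (t in sample) validate_phylogeny(t)
  tips <- sort(sample[[1L]]$tip.label)
  for (i in seq_along(sample))
    if (!identical(sort(sample[[i]]$tip.label), tips))
      stop("tree ", i, " does not share the common tip set", call. = FALSE)

  n <- length(sample)
  keysets <- lapply(sample, clade_tipsets)
  freq <- table(unlist(lapply(keysets, unique)))
  scores <- vapply(keysets, function(k) sum(log(as.numeric(freq[k]) / n)),
                   numeric(1))
  best <- which.max(scores)  # first max = lowest index on ties

  # pool clade heights across the sample
  height_pool <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    h <- node_heights(sample[[i]])
    nt <- length(sample[[i]]$tip.label)
    keys <- keysets[[i]]
    for (j in seq_along(keys)) {
      prev <- if (exists(keys[j], envir = height_pool)) get(keys[j], envir = height_pool) else numeric(0)
      assign(keys[j], c(prev, h[nt + j]), envir = height_pool)
    }
  }

  winner <- sample[[best]]
  nt <- length(winner$tip.label)
  h <- node_heights(winner)
  wkeys <- keysets[[best]]
  for (j in seq_along(wkeys))
    h[nt + j] <- mean(get(wkeys[j], envir = height_pool))
  new_len <- h[winner$edge[, 1L]] - h[winner$edge[, 2L]]
  if (any(new_len < 0)) {
    warning("conflicting clade heights implied ", sum(new_len < 0),
            " negative branch length(s); clamped to 0")
    new_len <- pmax(new_len, 0)
  }
  out <- winner
  out$edge.length <- new_len
  attr(out, "mcc_index") <- best
  attr(out, "mcc_score") <- scores[best]
  out
}

#' Clade-score of each tree in a sample
#'
#' The summed log clade frequency used by [mcc_tree()] to rank sample trees;
#' exposed so the selection can be audited.
#'
#' @param sample a list of `phylo` trees on one tip set.
#' @return numeric vector of scores, one per tree.
#' @export
mcc_scores <- function(sample) {
  if (inherits(sample, "phylo")) sample <- list(sample)
  keysets <- lapply(sample, clade_tipsets)
  freq <- table(unlist(lapply(keysets, unique)))
  n <- length(sample)
  vapply(keysets, function(k) sum(log(as.numeric(freq[k]) / n)), numeric(1))
}
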