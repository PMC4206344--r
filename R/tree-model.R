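#' @importFrom stats quantile setNames
#' @importFrom utils read.csv write.csv
NULL

# Trees are ape "phylo" objects throughout; these helpers enforce the
# invariants the rest of the package relies on: rooted, branch lengths on
# every edge, non-negative lengths, unique tip labels.

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("not a phylogeny ('phylo') object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("phylogeny has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and non-missing", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  # Newick is read as rooted at its outermost node (polytomies allowed);
  # nothing is ever midpoint-rooted, as all metrics here are root-dependent.
  invisible(tree)
}

# Cheap structural pre-scan so malformed Newick gets an error that names a
# character offset (ape's parser aborts without one).
scan_newick <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character offset ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick: missing ';' terminator at character offset ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Parse a rooted phylogeny from a Newick string or file
#'
#' Reads a single rooted tree with branch lengths. The returned object is an
#' ape `phylo` tree validated for the package's invariants: exactly one root,
#' branch lengths present and non-negative on every edge, unique tip labels.
#' Unrooted trees are rejected because every diversity measure in this
#' package (root-to-tip path sums in particular) is root-dependent.
#'
#' @param text a Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @param file alternatively, path to a file holding one Newick tree.
#' @return a validated `phylo` object.
#' @examples
#' tr <- read_phylogeny("((A:1,B:1):1,C:2);")
#' tree_total_length(tr)
#' @export
read_phylogeny <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  scan_newick(text)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree",
                          call. = FALSE)
  if (inherits(tree, "multiPhylo"))
    stop("expected a single tree, got ", length(tree), call. = FALSE)
  validate_phylogeny(tree)
  tree
}

#' Read a sample of trees (one Newick per line) on a shared tip set
#'
#' @param file path to a multi-tree Newick file, one tree per line.
#' @param text alternatively, a character vector or single string of trees.
#' @return a list of validated `phylo` objects, all on the same tip set.
#' @export
read_tree_sample <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  text <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0L) stop("empty tree sample")
  trees <- lapply(text, function(s) read_phylogeny(text = s))
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stop("tree ", i, " does not share the tip set of tree 1")
  trees
}

#' Serialize a phylogeny (or list of them) to Newick
#'
#' Branch lengths are written with 10 significant digits, enough for exact
#' round-trips at the package's 1e-9 comparison tolerance.
#'
#' @param tree a `phylo` object or list of them.
#' @param file optional path; if omitted the Newick string(s) are returned.
#' @return the Newick string(s), invisibly when written to file.
#' @export
write_phylogeny <- function(tree, file = NULL) {
  trees <- if (inherits(tree, "phylo")) list(tree) else tree
  out <- vapply(trees, function(t)
    ape::write.tree(t, digits = 10), character(1))
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  if (inherits(tree, "phylo")) out[[1L]] else out
}

#' Total branch length of a phylogeny
#'
#' @param tree a `phylo` object.
#' @return the sum of all branch lengths.
#' @export
tree_total_length <- function(tree) {
  validate_phylogeny(tree)
  sum(tree$edge.length)
}

#' Prune a phylogeny to a subset of tips
#'
#' Keeps exactly the requested tips, collapsing internal nodes left with a
#' single child and summing their branch lengths, so that patristic distances
#' among the kept tips are preserved.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least one).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) == 0L) stop("'keep' must contain at least one tip")
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    # degenerate single-tip tree: one edge of length = root-to-tip depth
    depth <- node_depths(tree)[match(keep, tree$tip.label)]
    return(read_phylogeny(sprintf("(%s:%.10g);", keep, depth)))
  }
  ape::keep.tip(tree, keep)
}

# root-to-node path lengths for every node (tips first, ape numbering)
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# parent and edge-length lookup indexed by child node id; root entries are NA
parent_table <- function(tree) {
  n_node <- max(tree$edge)
  parent <- rep(NA_integer_, n_node)
  elen <- rep(NA_real_, n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  list(parent = parent, elen = elen)
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the unique path connecting tips `a` and `b`.
#'
#' @param tree a `phylo` object.
#' @param a,b tip labels.
#' @return a non-negative number; 0 iff `a == b`.
#' @export
patristic_distance <- function(tree, a, b) {
  validate_phylogeny(tree)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown tip label: ", a, call. = FALSE)
  if (is.na(ib)) stop("unknown tip label: ", b, call. = FALSE)
  if (ia == ib) return(0)
  pt <- parent_table(tree)
  depth <- node_depths(tree)
  anc <- integer(0)
  v <- ia
  while (!is.na(v)) { anc <- c(anc, v); v <- pt$parent[v] }
  v <- ib
  while (!(v %in% anc)) v <- pt$parent[v]
  depth[ia] + depth[ib] - 2 * depth[v]
}

#' All pairwise patristic distances among tips
#'
#' @param tree a `phylo` object.
#' @return a symmetric matrix with row/column names in tip-label order.
#' @export
patristic_matrix <- function(tree) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) == 1L) {
    m <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(m)
  }
  ape::cophenetic.phylo(tree)
}
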