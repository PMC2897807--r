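#' BIONJ tree from a pairwise distance matrix
#'
#' Builds an unrooted phylogeny from map distances with the variance-weighted
#' neighbor joining of BIONJ (via \pkg{ape}).  Branch lengths are clamped to
#' be non-negative: a negative branch is set to zero and its deficit
#' transferred to the sibling branch(es), the usual neighbor-joining
#' convention.  With exactly two labels the tree is the single split with the
#' distance shared equally.
#'
#' @param dm symmetric non-negative matrix with zero diagonal and unique
#'   dimnames (as produced by [all_pairwise()]), or a [stats::dist].
#' @return an \pkg{ape} `phylo` object (unrooted, non-negative branch
#'   lengths).
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' write_newick(bionj_tree(d))
#' @export
bionj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  labels <- rownames(dm)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique row/column labels")
  if (nrow(dm) < 2) stop("need at least 2 labels")
  if (any(dm < 0)) stop("negative distances are not allowed")
  if (any(abs(dm - t(dm)) > 1e-9)) stop("distance matrix must be symmetric")
  if (nrow(dm) == 2) {
    tr <- structure(
      list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
           edge.length = rep(dm[1, 2] / 2, 2),
           tip.label = labels, Nnode = 1L),
      class = "phylo", order = "cladewise")
    return(tr)
  }
  tr <- ape::bionj(as.dist(dm))
  clamp_negative_branches(tr)
}

# Set negative branch lengths to zero, moving the deficit onto the sibling
# branch(es) under the same parent; any residual negativity is finally
# clamped at zero.
clamp_negative_branches <- function(tr, tol = 1e-12) {
  el <- tr$edge.length
  parent <- tr$edge[, 1]
  for (e in order(el)) {
    if (el[e] >= -tol) next
    sib <- setdiff(which(parent == parent[e]), e)
    if (length(sib)) el[sib] <- el[sib] + el[e] / length(sib)
    el[e] <- 0
  }
  tr$edge.length <- pmax(el, 0)
  tr
}

#' Serialize a tree as Newick text
#'
#' Standard Newick with branch lengths, terminated by `";"`.  Labels
#' containing Newick-reserved characters (whitespace, parentheses, commas,
#' colons, semicolons, brackets or quotes) are single-quoted, with embedded
#' quotes doubled.
#'
#' @param tree an \pkg{ape} `phylo` object.
#' @param file optional path; when given the text is also written there.
#' @param digits significant digits for branch lengths.
#' @return the Newick string.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- function(x) {
    if (grepl("[][()':;,[:space:]]", x))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  blen <- function(e) {
    if (is.null(tree$edge.length)) return("")
    paste0(":", format(tree$edge.length[e], digits = digits, trim = TRUE,
                       scientific = FALSE))
  }
  rec <- function(node, edge_in) {
    sub <- if (node <= ntip) {
      lab(tree$tip.label[node])
    } else {
      es <- kids[[as.character(node)]]
      paste0("(", paste(vapply(es, function(e) rec(tree$edge[e, 2], e),
                               character(1)), collapse = ","), ")")
    }
    paste0(sub, if (!is.null(edge_in)) blen(edge_in) else "")
  }
  txt <- paste0(rec(root, NULL), ";")
  if (!is.null(file)) writeLines(txt, file)
  txt
}
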