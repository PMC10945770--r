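#' Read a rooted or unrooted tree from Newick text or a file
#'
#' Thin validating wrapper around [ape::read.tree()]. Every non-root edge
#' must carry a branch length (interpreted throughout the package as
#' substitutions per aligned site). Quoted labels, internal support labels
#' and scientific notation are accepted.
#'
#' @param x Newick string (must contain a parenthesis) or path to a file.
#' @param clamp_negative If `TRUE`, negative branch lengths are clamped to
#'   zero with a warning instead of raising an error. Maximum-likelihood
#'   trees are non-negative, so silent clamping is off by default: a
#'   negative length usually flags corrupt input.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:2):0.5,C:1.5);")
#' tree_total_length(tr)
#' @export
read_newick <- function(x, clamp_negative = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- tryCatch(
    if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x) else ape::read.tree(x),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr, clamp_negative = clamp_negative)
}

validate_tree <- function(tr, clamp_negative = FALSE) {
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  n_edge <- nrow(tr$edge)
  if (is.null(tr$edge.length) || length(tr$edge.length) != n_edge ||
      anyNA(tr$edge.length)) {
    bad <- if (is.null(tr$edge.length)) seq_len(n_edge) else which(is.na(tr$edge.length))
    lab <- vapply(tr$edge[bad, 2L], function(v) node_name(tr, v), character(1))
    stop("missing branch length above node(s): ", paste(lab, collapse = ", "))
  }
  if (any(tr$edge.length < 0)) {
    if (clamp_negative) {
      warning("clamping ", sum(tr$edge.length < 0), " negative branch length(s) to zero")
      tr$edge.length[tr$edge.length < 0] <- 0
    } else {
      bad <- which(tr$edge.length < 0)[1L]
      stop("negative branch length above node ", node_name(tr, tr$edge[bad, 2L]),
           " (use clamp_negative = TRUE to clamp to zero)")
    }
  }
  tr
}

node_name <- function(tr, v) {
  n <- length(tr$tip.label)
  if (v <= n) tr$tip.label[v] else paste0("node#", v)
}

#' Write a tree to Newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if empty, the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = "", digits = 10) {
  out <- ape::write.tree(tree, file = file, digits = digits)
  if (nzchar(file)) invisible(out) else out
}

#' Root a tree on an outgroup
#'
#' Replaces manual rooting: the tree is (re)rooted so that the root separates
#' the outgroup leaves from all remaining leaves. Total branch length and all
#' pairwise leaf-to-leaf patristic distances are preserved.
#'
#' @param tree A `"phylo"` object (rooted or unrooted).
#' @param outgroup Character vector of leaf labels forming the outgroup. Must
#'   be a clade in the unrooted sense.
#' @return A rooted `"phylo"` object.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  outgroup <- unique(as.character(outgroup))
  unknown <- setdiff(outgroup, tree$tip.label)
  if (length(unknown) > 0) {
    stop("outgroup leaves not in tree: ", paste(unknown, collapse = ", "))
  }
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(ingroup) == 0L) stop("outgroup cannot contain every leaf")
  utr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (length(outgroup) > 1L && length(utr$tip.label) > 2L) {
    # monophyly in the unrooted sense: root provisionally on an ingroup leaf
    probe <- ape::root(utr, outgroup = ingroup[1L], resolve.root = TRUE)
    if (!ape::is.monophyletic(probe, outgroup)) {
      stop("outgroup is not monophyletic: ", paste(outgroup, collapse = ", "))
    }
  }
  # rooting on the ingroup side places the root on the same edge; ape needs
  # this fallback when the outgroup's MRCA coincides with the basal node
  res <- tryCatch(ape::root(utr, outgroup = outgroup, resolve.root = TRUE),
                  error = function(e) ape::root(utr, outgroup = ingroup,
                                                resolve.root = TRUE))
  stopifnot(abs(sum(res$edge.length) - sum(tree$edge.length)) < 1e-9)
  res
}
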