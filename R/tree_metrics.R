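#' Total tree length
#'
#' The extent of molecular evolution of a gene over a set of species: the sum
#' of all branch lengths (substitutions per aligned site) in its phylogeny.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Numeric scalar.
#' @examples
#' tree_total_length(read_newick("((A:1,B:2):0.5,C:1.5);")) # 5
#' @export
tree_total_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

# depth of every node (tips + internals) below the root, by preorder sweep
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  d <- numeric(n + tr$Nnode)
  e <- tr$edge
  len <- tr$edge.length
  for (i in seq_len(nrow(e))) d[e[i, 2L]] <- d[e[i, 1L]] + len[i]
  d
}

#' Root-to-tip distances
#'
#' Summed branch length from the last common ancestor at the root to each
#' leaf, in substitutions per site: the per-species extent of molecular
#' evolution used in trait regressions.
#'
#' @param tree A rooted `"phylo"` object.
#' @return Named numeric vector, one entry per leaf.
#' @export
root_to_tip <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("root_to_tip requires a rooted tree")
  n <- length(tree$tip.label)
  d <- node_depths(tree)[seq_len(n)]
  names(d) <- tree$tip.label
  d
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the tree path separating two leaves (through
#' their most recent common ancestor).
#'
#' @param tree A `"phylo"` object.
#' @param leaf_a,leaf_b Leaf labels.
#' @return Numeric scalar; symmetric in its leaf arguments.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  ia <- match(leaf_a, tree$tip.label)
  ib <- match(leaf_b, tree$tip.label)
  if (is.na(ia)) stop("unknown leaf: ", leaf_a)
  if (is.na(ib)) stop("unknown leaf: ", leaf_b)
  if (ia == ib) return(0)
  d <- node_depths(tree)
  m <- ape::getMRCA(tree, c(ia, ib))
  d[ia] + d[ib] - 2 * d[m]
}

#' All pairwise patristic distances
#'
#' @param tree A `"phylo"` object.
#' @return Symmetric numeric matrix with leaf labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  n <- length(tree$tip.label)
  d <- node_depths(tree)
  anc <- ape::mrca(tree)
  D <- outer(d[seq_len(n)], d[seq_len(n)], `+`) - 2 * matrix(d[anc], n, n)
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

#' Prune a tree to a leaf subset, preserving path lengths
#'
#' Drops all leaves outside `keep`; internal nodes left with a single child
#' are collapsed by summing the incident branch lengths, so every pairwise
#' patristic distance among the kept leaves is unchanged. The original root
#' is always retained (as a degree-one root when necessary), so root-to-tip
#' distances are preserved as well.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of leaf labels to retain.
#' @return A `"phylo"` object on exactly the `keep` leaves.
#' @export
prune_preserving_lengths <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  tips <- tree$tip.label
  unknown <- setdiff(keep, tips)
  if (length(unknown) > 0) stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  if (length(keep) == 0L) stop("must keep at least one leaf")
  if (length(keep) == length(tips)) return(tree)

  n <- length(tips)
  nn <- n + tree$Nnode
  root <- n + 1L
  parent <- integer(nn)
  elen <- numeric(nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length

  needed <- logical(nn)
  for (v in match(keep, tips)) {
    while (v != root && !needed[v]) {
      needed[v] <- TRUE
      v <- parent[v]
    }
  }
  needed[root] <- TRUE

  nch <- integer(nn)
  for (v in which(needed)) if (v != root) nch[parent[v]] <- nch[parent[v]] + 1L

  keep_tip_old <- sort(match(keep, tips))
  keep_node <- logical(nn)
  keep_node[keep_tip_old] <- TRUE
  keep_node[root] <- TRUE
  internals <- which(needed)
  internals <- internals[internals > n & internals != root]
  keep_node[internals[nch[internals] >= 2L]] <- TRUE

  n_new <- length(keep_tip_old)
  old_internal <- c(root, setdiff(which(keep_node & seq_len(nn) > n), root))
  new_id <- integer(nn)
  new_id[keep_tip_old] <- seq_len(n_new)
  new_id[old_internal] <- n_new + seq_along(old_internal)

  kept <- setdiff(which(keep_node), root)
  edge <- matrix(0L, length(kept), 2L)
  edge_len <- numeric(length(kept))
  for (i in seq_along(kept)) {
    v <- kept[i]
    len <- elen[v]
    u <- parent[v]
    while (!keep_node[u]) {
      len <- len + elen[u]
      u <- parent[u]
    }
    edge[i, ] <- c(new_id[u], new_id[v])
    edge_len[i] <- len
  }

  res <- structure(list(edge = edge, edge.length = edge_len,
                        tip.label = tips[keep_tip_old],
                        Nnode = length(old_internal)),
                   class = "phylo")
  ape::reorder.phylo(res, "cladewise")
}

#' Stratified bootstrap of total tree length over gene copies
#'
#' For gene families with several copies per species, resamples exactly one
#' leaf per species per replicate, prunes the fixed input tree to the sample
#' (preserving path lengths) and records the total tree length, summarising
#' the replicates by their mean and standard deviation. With all-single-copy
#' species the procedure is degenerate: every replicate equals the full tree
#' length and the SD is zero.
#'
#' @param tree A `"phylo"` object.
#' @param species_map Named character vector (leaf label -> species) or a
#'   data frame with columns `label`, `species`. Every leaf must be mapped.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; required, so summaries are reproducible.
#' @return A list of class `"bootstrap_summary"` with elements `mean`, `sd`,
#'   `n_reps`, `seed` and the replicate `lengths`.
#' @export
stratified_bootstrap_tree_length <- function(tree, species_map, n_reps = 1000, seed) {
  stopifnot(inherits(tree, "phylo"), n_reps >= 1)
  if (missing(seed)) stop("a seed is required for reproducible bootstrapping")
  map <- as_species_map(species_map)
  unmapped <- setdiff(tree$tip.label, names(map))
  if (length(unmapped) > 0) {
    stop("leaves missing from species map: ", paste(unmapped, collapse = ", "))
  }
  by_species <- split(tree$tip.label, map[tree$tip.label])
  if (any(lengths(by_species) == 0L)) stop("species with zero leaves in map")
  set.seed(seed)
  single <- all(lengths(by_species) == 1L)
  lens <- if (single) {
    rep(tree_total_length(tree), n_reps)
  } else {
    vapply(seq_len(n_reps), function(r) {
      pick <- vapply(by_species, function(v) {
        if (length(v) == 1L) v else sample(v, 1L)
      }, character(1))
      tree_total_length(prune_preserving_lengths(tree, pick))
    }, numeric(1))
  }
  structure(list(mean = mean(lens), sd = stats::sd(lens),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 lengths = lens),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("stratified bootstrap: mean total length %.6g ± %.6g SD (%d reps, seed %d)\n",
              x$mean, x$sd, x$n_reps, x$seed))
  invisible(x)
}

#' Percentage ratio between two extents of evolution
#'
#' `100 * length_a / length_b`, e.g. the extent of evolution of one subunit
#' relative to another.
#'
#' @param length_a,length_b Non-negative tree lengths; `length_b` must be
#'   positive.
#' @return Percentage (numeric scalar).
#' @export
subunit_ratio <- function(length_a, length_b) {
  if (!is.finite(length_b) || length_b <= 0) stop("length_b must be positive")
  100 * length_a / length_b
}

#' Protein-per-nucleotide (or inverse) evolution ratio
#'
#' Ratio of total protein tree length (substitutions per amino-acid site) to
#' total nucleotide tree length (substitutions per nucleotide site), as a
#' percentage. Because a codon spans three nucleotide sites, the neutral
#' expectation of the protein-per-nucleotide ratio is `3 * f_N`, where `f_N`
#' is the nonsynonymous fraction of single-nucleotide changes (see
#' [neutral_expected_ratio()]); values well below it indicate purifying
#' selection on the protein.
#'
#' @param nuc_tree Nucleotide gene tree (`"phylo"`).
#' @param prot_tree Protein gene tree (`"phylo"`) over the same sequences.
#' @param direction `"protein_per_nucleotide"` (default) or
#'   `"nucleotide_per_protein"`.
#' @return Percentage (numeric scalar) with the chosen convention recorded in
#'   the `"direction"` attribute.
#' @export
protein_per_nucleotide_ratio <- function(nuc_tree, prot_tree,
                                         direction = c("protein_per_nucleotide",
                                                       "nucleotide_per_protein")) {
  direction <- match.arg(direction)
  ln <- tree_total_length(nuc_tree)
  lp <- tree_total_length(prot_tree)
  out <- if (direction == "protein_per_nucleotide") {
    subunit_ratio(lp, ln)
  } else {
    subunit_ratio(ln, lp)
  }
  attr(out, "direction") <- direction
  out
}
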