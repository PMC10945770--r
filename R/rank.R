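#' Background ortholog distances for a species pair
#'
#' Collects, across a cohort of orthogroup gene trees, the patristic distance
#' separating genes of two species — the genome-wide background against which
#' a focal gene's extent of evolution is ranked. By default every
#' cross-species leaf pair within an orthogroup is used (which over-counts
#' pairs involving paralogs); an explicit ortholog-pair list, e.g. exported
#' from an orthology tool, overrides the default.
#'
#' @param orthogroup_trees Named list of `"phylo"` objects (names are
#'   orthogroup ids) or an object returned by [simulate_orthogroup_cohort()].
#' @param species_map Named character vector (leaf label -> species) or a
#'   `label`/`species` data frame covering the trees' leaves.
#' @param species_a,species_b Species identifiers.
#' @param ortholog_pairs Optional data frame with columns `gene_a`, `gene_b`
#'   restricting which leaf pairs count as orthologs.
#' @return Data frame of class `"background_cohort"` with columns
#'   `orthogroup`, `gene_a`, `gene_b`, `distance`, and the species pair
#'   stored in attributes `species_a`/`species_b`. Empty (with a warning) if
#'   either species is absent from all trees.
#' @export
background_pair_distances <- function(orthogroup_trees, species_map,
                                      species_a, species_b,
                                      ortholog_pairs = NULL) {
  if (inherits(orthogroup_trees, "orthogroup_cohort")) {
    if (missing(species_map) || is.null(species_map)) {
      species_map <- orthogroup_trees$species_map
    }
    orthogroup_trees <- orthogroup_trees$trees
  }
  map <- as_species_map(species_map)
  if (is.null(names(orthogroup_trees))) {
    names(orthogroup_trees) <- sprintf("OG%04d", seq_along(orthogroup_trees))
  }
  rows <- vector("list", length(orthogroup_trees))
  for (og in names(orthogroup_trees)) {
    tr <- orthogroup_trees[[og]]
    sp <- map[tr$tip.label]
    genes_a <- tr$tip.label[!is.na(sp) & sp == species_a]
    genes_b <- tr$tip.label[!is.na(sp) & sp == species_b]
    if (length(genes_a) == 0L || length(genes_b) == 0L) next
    pairs <- expand.grid(gene_a = genes_a, gene_b = genes_b,
                         stringsAsFactors = FALSE)
    if (!is.null(ortholog_pairs)) {
      key <- paste(pairs$gene_a, pairs$gene_b)
      ok <- key %in% c(paste(ortholog_pairs$gene_a, ortholog_pairs$gene_b),
                       paste(ortholog_pairs$gene_b, ortholog_pairs$gene_a))
      pairs <- pairs[ok, , drop = FALSE]
    }
    if (nrow(pairs) == 0L) next
    D <- patristic_matrix(tr)
    pairs$distance <- D[cbind(pairs$gene_a, pairs$gene_b)]
    pairs$orthogroup <- og
    rows[[og]] <- pairs[, c("orthogroup", "gene_a", "gene_b", "distance")]
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("species pair (", species_a, ", ", species_b,
            ") absent from all orthogroup trees; empty cohort")
    out <- data.frame(orthogroup = character(0), gene_a = character(0),
                      gene_b = character(0), distance = numeric(0))
  }
  rownames(out) <- NULL
  structure(out, species_a = species_a, species_b = species_b,
            class = c("background_cohort", "data.frame"))
}

cohort_distances <- function(cohort) {
  if (is.data.frame(cohort)) cohort$distance else as.numeric(cohort)
}

#' Percentile rank of a focal distance against a background cohort
#'
#' Fraction (as a percentage) of the background ortholog distances that
#' exceed the focal gene's distance — "percent of the genome evolving
#' faster". Ties receive midrank weight 0.5. Species pairs whose cohort is
#' smaller than `min_n` are flagged rather than dropped, and are excluded
#' from downstream summaries.
#'
#' @param focal Focal patristic distance (substitutions per site).
#' @param cohort A [background_pair_distances()] result or numeric vector of
#'   background distances.
#' @param min_n Minimum cohort size for the result to count (default 100).
#' @return One-row data frame of class `"percentile_result"` with columns
#'   `species_a`, `species_b`, `focal_distance`, `percent_faster`,
#'   `percent_slower`, `n_background`, `passed_threshold`. `percent_faster`
#'   is `NA` for an empty cohort.
#' @export
percentile_faster <- function(focal, cohort, min_n = 100) {
  stopifnot(is.finite(focal))
  d <- cohort_distances(cohort)
  if (anyNA(d)) stop("cohort contains non-finite distances")
  n <- length(d)
  pf <- if (n == 0L) NA_real_ else 100 * (sum(d > focal) + 0.5 * sum(d == focal)) / n
  data.frame(species_a = attr(cohort, "species_a") %||% NA_character_,
             species_b = attr(cohort, "species_b") %||% NA_character_,
             focal_distance = focal,
             percent_faster = pf,
             percent_slower = if (is.na(pf)) NA_real_ else 100 - pf,
             n_background = n,
             passed_threshold = n >= min_n,
             stringsAsFactors = FALSE) |>
    structure(class = c("percentile_result", "data.frame"))
}

#' Average duplicate percentile results for one species pair
#'
#' When a species pair yields several percentiles (gene duplicates, or one
#' assembly matching several sub-species), the mean percentile is taken; the
#' reported cohort size is the smallest across members, so the threshold
#' flag stays conservative.
#'
#' @param results Data frame of [percentile_faster()] rows sharing one
#'   species pair.
#' @param min_n Threshold used to recompute `passed_threshold`.
#' @return One-row `"percentile_result"` data frame.
#' @export
aggregate_duplicate_percentiles <- function(results, min_n = 100) {
  if (is.null(results) || nrow(results) == 0L) stop("empty result group")
  pair <- unique(results[, c("species_a", "species_b")])
  if (nrow(pair) > 1L) stop("results span more than one species pair")
  n_min <- min(results$n_background)
  data.frame(species_a = pair$species_a, species_b = pair$species_b,
             focal_distance = mean(results$focal_distance),
             percent_faster = mean(results$percent_faster),
             percent_slower = 100 - mean(results$percent_faster),
             n_background = n_min,
             passed_threshold = n_min >= min_n,
             stringsAsFactors = FALSE) |>
    structure(class = c("percentile_result", "data.frame"))
}

#' Summarise percentile results over species pairs
#'
#' Five-number summary (plus mean and count) of `percent_faster` across the
#' species pairs passing the cohort-size threshold, optionally per group
#' label (e.g. taxonomic group).
#'
#' @param results Data frame of [percentile_faster()] rows, optionally with a
#'   `group` column.
#' @return Data frame with one row per group (column `group` only when the
#'   input has one) and columns `n_pairs`, `mean`, `min`, `q25`, `median`,
#'   `q75`, `max`. Zero rows (with a warning) when nothing passes the
#'   threshold.
#' @export
summarize_percentiles <- function(results) {
  ok <- results[results$passed_threshold & !is.na(results$percent_faster), ,
                drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("no species pair passes the cohort-size threshold")
    return(data.frame(n_pairs = integer(0), mean = numeric(0), min = numeric(0),
                      q25 = numeric(0), median = numeric(0), q75 = numeric(0),
                      max = numeric(0)))
  }
  groups <- if ("group" %in% names(ok)) split(ok, ok$group) else list(ok)
  out <- do.call(rbind, lapply(groups, function(g) {
    q <- stats::quantile(g$percent_faster, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n_pairs = nrow(g), mean = mean(g$percent_faster),
               min = min(g$percent_faster), q25 = q[1], median = q[2],
               q75 = q[3], max = max(g$percent_faster))
  }))
  if ("group" %in% names(ok)) out <- cbind(group = names(groups), out)
  rownames(out) <- NULL
  out
}
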