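# shared manifest for pipeline results: config snapshot + row counts,
# deterministic (no timestamps), so identical inputs give identical bundles
run_manifest <- function(stage, config, counts) {
  list(stage = stage,
       package_version = as.character(utils::packageVersion("evoextent")),
       config = config,
       counts = counts)
}

#' End-to-end kinetic/trait analysis of one gene tree
#'
#' Computes root-to-tip distances from a rooted gene tree (or takes them
#' precomputed), regresses every requested trait on distance, reads the
#' ancestral trait values off the intercepts (with the extant means for
#' comparison), and converts slopes into per-substitution and per-My
#' improvement rates.
#'
#' @param tree_or_distances Rooted `"phylo"` gene tree, or a named numeric
#'   vector / `species`-`distance` data frame of precomputed root-to-tip
#'   distances.
#' @param traits Trait table (data frame with `species` column).
#' @param config Optional list: `species_map` (leaf label -> species; default
#'   labels are species ids), `trait_names`, `n_sites` (default 476),
#'   `clade_age` (default 160 My).
#' @return List of class `"kinetics_result"`: `distances` (data frame),
#'   `regressions`, `ancestral` (intercept ± SE and extant mean ± SE per
#'   trait), `improvements`, `manifest`.
#' @export
pipeline_kinetics <- function(tree_or_distances, traits, config = list()) {
  n_sites <- config$n_sites %||% 476L
  clade_age <- config$clade_age %||% 160

  if (inherits(tree_or_distances, "phylo")) {
    rtt <- root_to_tip(tree_or_distances)
    if (!is.null(config$species_map)) {
      map <- as_species_map(config$species_map)
      names(rtt) <- unname(map[names(rtt)])
    }
  } else if (is.data.frame(tree_or_distances)) {
    rtt <- tree_or_distances$distance
    names(rtt) <- as.character(tree_or_distances$species)
  } else {
    rtt <- tree_or_distances
  }
  traits <- derive_trait_columns(traits)
  common <- intersect(names(rtt), as.character(traits$species))
  if (length(common) < 3L) {
    stop("species join between distances and traits has fewer than 3 species (",
         length(common), ")")
  }
  rtt <- rtt[common]
  traits <- traits[match(common, traits$species), , drop = FALSE]

  regs <- run_trait_regressions(rtt, traits, config$trait_names)

  extant <- vapply(regs$trait, function(tn) {
    v <- traits[[tn]]
    v <- v[is.finite(v)]
    c(mean(v), stats::sd(v) / sqrt(length(v)))
  }, numeric(2))
  ancestral <- data.frame(trait = regs$trait,
                          ancestral_value = regs$intercept,
                          ancestral_se = regs$se_intercept,
                          extant_mean = extant[1, ],
                          extant_se = extant[2, ])
  rownames(ancestral) <- NULL

  mean_rtt <- mean(rtt)
  improvements <- do.call(rbind, lapply(seq_len(nrow(regs)), function(i) {
    cbind(trait = regs$trait[i],
          improvement_rates(regs$slope[i], regs$intercept[i], mean_rtt,
                            n_sites, clade_age))
  }))
  rownames(improvements) <- NULL

  manifest <- run_manifest("kinetics",
                           list(n_sites = n_sites, clade_age = clade_age,
                                trait_names = regs$trait),
                           list(n_species = length(common),
                                n_traits = nrow(regs)))
  structure(list(distances = data.frame(species = names(rtt), distance = unname(rtt)),
                 regressions = regs, ancestral = ancestral,
                 improvements = improvements, manifest = manifest),
            class = "kinetics_result")
}

#' Percentile-rank a focal gene against an orthogroup cohort
#'
#' For every pair of species on the focal gene tree, measures the focal
#' patristic distance, collects the background ortholog distances from the
#' orthogroup trees, and computes the percent of the background evolving
#' faster, with the minimum-cohort-size rule applied before summarising.
#'
#' @param focal_tree `"phylo"` tree of the focal gene; tip labels are species
#'   ids (or supply `config$focal_species_map`).
#' @param orthogroup_trees Named list of `"phylo"` trees or an
#'   [simulate_orthogroup_cohort()] result.
#' @param species_map Species map covering the orthogroup trees' leaves.
#' @param config Optional list: `min_n` (default 100), `ortholog_pairs`.
#' @return List of class `"rank_result"`: `results` (one row per species
#'   pair), `summary`, `manifest`.
#' @export
pipeline_rank <- function(focal_tree, orthogroup_trees, species_map,
                          config = list()) {
  min_n <- config$min_n %||% 100L
  if (!is.null(config$focal_species_map)) {
    map <- as_species_map(config$focal_species_map)
    focal_tree$tip.label <- unname(map[focal_tree$tip.label])
  }
  species <- focal_tree$tip.label
  if (length(species) < 2L) stop("focal tree needs at least two species")
  D <- patristic_matrix(focal_tree)
  pairs <- utils::combn(sort(species), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]
    b <- pairs[2L, j]
    cohort <- suppressWarnings(
      background_pair_distances(orthogroup_trees, species_map, a, b,
                                config$ortholog_pairs))
    percentile_faster(D[a, b], cohort, min_n = min_n)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- withCallingHandlers(
    summarize_percentiles(results),
    warning = function(w) {
      warning(conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  manifest <- run_manifest("rank",
                           list(min_n = min_n,
                                explicit_ortholog_pairs = !is.null(config$ortholog_pairs)),
                           list(n_species = length(species),
                                n_pairs = nrow(results),
                                n_passed = sum(results$passed_threshold)))
  structure(list(results = results, summary = summary, manifest = manifest),
            class = "rank_result")
}

#' Compare the extent of evolution of two genes (e.g. two subunits)
#'
#' Reports total tree lengths and their percentage ratio; when a species map
#' for the second (multi-copy) gene is supplied, adds the stratified
#' bootstrap summary of its tree length; when a codon sequence is supplied,
#' adds the neutral expectation for the protein-per-nucleotide ratio.
#'
#' @param tree_a,tree_b `"phylo"` gene trees (e.g. single-copy subunit and
#'   multi-copy subunit).
#' @param species_map_b Optional species map for `tree_b`'s leaves.
#' @param config Optional list: `n_reps` (default 1000), `seed` (default 1),
#'   `codon_seq`.
#' @return List of class `"subunit_result"`: `length_a`, `length_b`,
#'   `ratio_percent` (a relative to b), `bootstrap_b` (or `NULL`),
#'   `neutral` (or `NULL`), `manifest`.
#' @export
pipeline_subunit_compare <- function(tree_a, tree_b, species_map_b = NULL,
                                     config = list()) {
  n_reps <- config$n_reps %||% 1000L
  seed <- config$seed %||% 1L
  len_a <- tree_total_length(tree_a)
  len_b <- tree_total_length(tree_b)
  boot <- if (!is.null(species_map_b)) {
    stratified_bootstrap_tree_length(tree_b, species_map_b, n_reps, seed)
  }
  neutral <- if (!is.null(config$codon_seq)) {
    list(nonsyn_fraction = neutral_expected_fraction(config$codon_seq),
         expected_protein_per_nucleotide =
           as.numeric(neutral_expected_ratio(config$codon_seq)))
  }
  manifest <- run_manifest("subunit_compare",
                           list(n_reps = n_reps, seed = seed,
                                has_codon_seq = !is.null(config$codon_seq)),
                           list(n_leaves_a = length(tree_a$tip.label),
                                n_leaves_b = length(tree_b$tip.label)))
  structure(list(length_a = len_a, length_b = len_b,
                 ratio_percent = subunit_ratio(len_a, len_b),
                 bootstrap_b = boot, neutral = neutral, manifest = manifest),
            class = "subunit_result")
}
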