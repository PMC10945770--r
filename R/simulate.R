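#' Simulate a pure-birth (Yule) species tree
#'
#' Grows a rooted binary ultrametric tree: starting from the root's two
#' lineages, each next split waits an exponential time with rate
#' `k * birth_rate` (k = current lineage count) and splits a uniformly chosen
#' lineage, until `n_taxa` lineages exist; a final exponential segment with
#' rate `n_taxa * birth_rate` is then appended. The expected root-to-tip
#' depth is `sum(1 / (k * birth_rate))` for `k = 2 .. n_taxa`. Branch lengths
#' are in arbitrary rate units, interpretable as substitutions per site after
#' rescaling.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed (required).
#' @return A rooted ultrametric `"phylo"` with tips `s001`, `s002`, ...
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed) {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n_taxa <- as.integer(n_taxa)
  # internal nodes in creation order (1 = root); lineages hang off them
  node_parent <- integer(n_taxa - 1L)
  node_time <- numeric(n_taxa - 1L)
  node_parent[1L] <- 0L
  node_time[1L] <- 0
  par_node <- c(1L, 1L)  # parent internal node of each active lineage
  t_now <- 0
  k <- 2L
  n_int <- 1L
  while (k < n_taxa) {
    t_now <- t_now + stats::rexp(1L, rate = k * birth_rate)
    i <- sample.int(k, 1L)
    n_int <- n_int + 1L
    node_parent[n_int] <- par_node[i]
    node_time[n_int] <- t_now
    par_node[i] <- n_int
    par_node <- c(par_node, n_int)
    k <- k + 1L
  }
  t_end <- t_now + stats::rexp(1L, rate = n_taxa * birth_rate)
  n_edge <- n_taxa + n_int - 1L
  edge <- matrix(0L, n_edge, 2L)
  elen <- numeric(n_edge)
  r <- 0L
  if (n_int > 1L) {
    for (j in 2:n_int) {
      r <- r + 1L
      edge[r, ] <- c(n_taxa + node_parent[j], n_taxa + j)
      elen[r] <- node_time[j] - node_time[node_parent[j]]
    }
  }
  for (i in seq_len(n_taxa)) {
    r <- r + 1L
    edge[r, ] <- c(n_taxa + par_node[i], i)
    elen[r] <- t_end - node_time[par_node[i]]
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = sprintf("s%03d", seq_len(n_taxa)),
                       Nnode = n_int),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Rescale all branch lengths by a constant
#'
#' @param tree A `"phylo"` object.
#' @param factor Positive multiplier.
#' @return The rescaled tree.
#' @export
rescale_tree <- function(tree, factor) {
  stopifnot(inherits(tree, "phylo"), is.finite(factor), factor > 0)
  tree$edge.length <- tree$edge.length * factor
  tree
}

#' Multiplicative per-branch rate jitter
#'
#' Multiplies every branch by an independent LogNormal factor with mean 1 and
#' the given coefficient of variation, emulating among-lineage rate variation
#' (and, on an ultrametric species tree, creating the root-to-tip spread that
#' gene trees show).
#'
#' @param tree A `"phylo"` object.
#' @param cv Coefficient of variation of the jitter (0 = no change).
#' @param seed Integer seed (required when `cv > 0`).
#' @return The jittered tree.
#' @export
perturb_branch_lengths <- function(tree, cv, seed) {
  stopifnot(inherits(tree, "phylo"), cv >= 0)
  if (cv == 0) return(tree)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  sdl <- sqrt(log1p(cv^2))
  tree$edge.length <- tree$edge.length *
    stats::rlnorm(length(tree$edge.length), meanlog = -sdl^2 / 2, sdlog = sdl)
  tree
}

#' Simulate a cohort of orthogroup gene trees
#'
#' Each orthogroup tree is the species tree with every branch multiplied by a
#' gene-specific rate `r_g ~ LogNormal(rate_meanlog, rate_sdlog)` (the
#' heavy-tailed among-gene rate variation the percentile analysis assumes)
#' plus optional per-branch multiplicative jitter. Gene leaf labels carry
#' their species id (`<species>|<orthogroup>`).
#'
#' @param species_tree A `"phylo"` species tree.
#' @param n_orthogroups Number of orthogroup trees.
#' @param rate_meanlog,rate_sdlog Parameters of the LogNormal gene-rate
#'   distribution (defaults 0 and 1).
#' @param branch_jitter_cv Coefficient of variation of optional per-branch
#'   jitter (default 0).
#' @param seed Integer seed (required).
#' @return List of class `"orthogroup_cohort"`: `trees` (named list of
#'   `"phylo"`), `species_map` (data frame `label`/`species`), `rates`
#'   (the drawn gene rates).
#' @export
simulate_orthogroup_cohort <- function(species_tree, n_orthogroups,
                                       rate_meanlog = 0, rate_sdlog = 1,
                                       branch_jitter_cv = 0, seed) {
  stopifnot(inherits(species_tree, "phylo"), n_orthogroups >= 1)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  rates <- stats::rlnorm(n_orthogroups, rate_meanlog, rate_sdlog)
  ids <- sprintf("OG%04d", seq_len(n_orthogroups))
  sdl <- if (branch_jitter_cv > 0) sqrt(log1p(branch_jitter_cv^2)) else 0
  n_edge <- length(species_tree$edge.length)
  trees <- vector("list", n_orthogroups)
  maps <- vector("list", n_orthogroups)
  for (g in seq_len(n_orthogroups)) {
    tr <- species_tree
    mult <- rates[g]
    if (sdl > 0) {
      mult <- mult * stats::rlnorm(n_edge, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    tr$edge.length <- tr$edge.length * mult
    tr$tip.label <- paste0(species_tree$tip.label, "|", ids[g])
    trees[[g]] <- tr
    maps[[g]] <- data.frame(label = tr$tip.label,
                            species = species_tree$tip.label,
                            stringsAsFactors = FALSE)
  }
  names(trees) <- ids
  names(rates) <- ids
  structure(list(trees = trees,
                 species_map = do.call(rbind, maps),
                 rates = rates),
            class = "orthogroup_cohort")
}

#' Simulate a multi-copy gene family on a species tree
#'
#' Replaces each species tip carrying more than one gene copy by a star of
#' its copies (each copy on a branch of `within_species_divergence / 2`, so
#' copies of one species are separated by the stated divergence). Emulates
#' gene families that are multi-copy in some genomes, the situation the
#' stratified bootstrap corrects for.
#'
#' @param species_tree A `"phylo"` species tree.
#' @param copy_numbers Integer copy count per species: a scalar (recycled) or
#'   a vector named by species. Ignored when `lambda` is given.
#' @param within_species_divergence Patristic distance between copies of the
#'   same species (default 0).
#' @param lambda Optional Poisson rate: copy counts drawn as
#'   `1 + rpois(lambda)`.
#' @param seed Integer seed (required when `lambda` is used).
#' @return List of class `"multicopy_family"`: `tree` (gene tree) and
#'   `species_map` (data frame `label`/`species`). Single-copy species keep
#'   their original tip label; copies are labelled `<species>_1`, ...
#' @export
simulate_multicopy_family <- function(species_tree, copy_numbers = 1,
                                      within_species_divergence = 0,
                                      lambda = NULL, seed) {
  stopifnot(inherits(species_tree, "phylo"), within_species_divergence >= 0)
  sp <- species_tree$tip.label
  if (!is.null(lambda)) {
    if (missing(seed)) stop("a seed is required when drawing copy numbers")
    set.seed(seed)
    copies <- 1L + stats::rpois(length(sp), lambda)
    names(copies) <- sp
  } else if (length(copy_numbers) == 1L && is.null(names(copy_numbers))) {
    copies <- rep(as.integer(copy_numbers), length(sp))
    names(copies) <- sp
  } else {
    copies <- as.integer(copy_numbers[sp])
    names(copies) <- sp
    if (anyNA(copies)) stop("copy_numbers must name every species")
  }
  if (any(copies < 1L)) stop("copy numbers must be >= 1")

  tr <- species_tree
  map <- data.frame(label = sp, species = sp, stringsAsFactors = FALSE)
  half <- within_species_divergence / 2
  for (s in sp[copies > 1L]) {
    k <- copies[[s]]
    labs <- paste0(s, "_", seq_len(k))
    star <- ape::read.tree(text = paste0(
      "(", paste0(labs, ":", format(half, scientific = FALSE), collapse = ","), "):0;"))
    tr <- ape::bind.tree(tr, star, where = which(tr$tip.label == s))
    map <- rbind(map[map$label != s, , drop = FALSE],
                 data.frame(label = labs, species = s, stringsAsFactors = FALSE))
  }
  rownames(map) <- NULL
  structure(list(tree = tr, species_map = map), class = "multicopy_family")
}

#' Simulate traits under directional selection along root-to-tip distance
#'
#' Generates one trait value per tip as
#' `trait = intercept + slope * root_to_tip + Normal(0, noise_sd)`, the same
#' functional form the trait regressions assume (independent noise, no
#' phylogenetic residual correlation).
#'
#' @param tree Rooted `"phylo"` gene tree with branch lengths.
#' @param intercept Ancestral trait value (trait units).
#' @param slope Trait units per (substitutions per site).
#' @param noise_sd Standard deviation of the independent Gaussian noise.
#' @param seed Integer seed (required).
#' @param trait_name Name of the trait column (default `"trait"`).
#' @return Data frame with columns `species` (tip labels) and the trait.
#' @export
simulate_directional_traits <- function(tree, intercept, slope, noise_sd,
                                        seed, trait_name = "trait") {
  stopifnot(noise_sd >= 0)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  rtt <- root_to_tip(tree)
  out <- data.frame(species = names(rtt),
                    value = intercept + slope * rtt +
                      stats::rnorm(length(rtt), 0, noise_sd),
                    stringsAsFactors = FALSE)
  names(out)[2L] <- trait_name
  out
}

#' Default configuration for the fixture generator
#'
#' The defaults emulate the study conditions of an angiosperm rubisco-style
#' analysis: 93 species with kinetic traits, a 500-orthogroup background
#' cohort with LogNormal(0, 1) gene rates and 10% per-branch jitter, a focal
#' gene at a mean root-to-tip depth of 0.05 substitutions per site across 476
#' aligned sites, traits generated around an ancestral value of 81.1 with a
#' slope of 128 trait units per substitutions-per-site, noise calibrated to
#' an expected variance explained of about 10%, and a 160-My-old clade.
#'
#' @param seed Integer seed (required; all other randomness derives from it).
#' @return Named list of generator parameters.
#' @export
default_sim_config <- function(seed) {
  if (missing(seed)) stop("a seed is required")
  list(seed = as.integer(seed), n_taxa = 93L, birth_rate = 1,
       n_orthogroups = 500L, rate_meanlog = 0, rate_sdlog = 1,
       branch_jitter_cv = 0.1, mean_rtt = 0.05,
       intercept = 81.1, slope = 128, target_r2 = 0.10, noise_sd = NULL,
       n_sites = 476L, clade_age = 160)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes a species tree, a jittered and depth-scaled focal
#' gene tree, an orthogroup cohort with its species map, a directional trait
#' table and a JSON manifest recording every generating parameter (including
#' the noise SD realised from `target_r2` when `noise_sd` is `NULL`:
#' `noise_sd = |slope| * sd(rtt) * sqrt(1 / target_r2 - 1)`). The same seed
#' reproduces a byte-identical bundle.
#'
#' @param config List from [default_sim_config()] (entries may be
#'   overridden).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
make_fixture_bundle <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_dir <- file.path(out_dir, "cohort")
  dir.create(cohort_dir, showWarnings = FALSE)
  seed <- config$seed

  species_tree <- simulate_yule_tree(config$n_taxa, config$birth_rate, seed = seed)
  focal <- perturb_branch_lengths(species_tree, config$branch_jitter_cv,
                                  seed = seed + 1L)
  focal <- rescale_tree(focal, config$mean_rtt / mean(root_to_tip(focal)))
  cohort <- simulate_orthogroup_cohort(species_tree, config$n_orthogroups,
                                       config$rate_meanlog, config$rate_sdlog,
                                       config$branch_jitter_cv, seed = seed + 2L)
  rtt <- root_to_tip(focal)
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- abs(config$slope) * stats::sd(rtt) * sqrt(1 / config$target_r2 - 1)
  }
  traits <- simulate_directional_traits(focal, config$intercept, config$slope,
                                        noise_sd, seed = seed + 3L,
                                        trait_name = "S_CO")

  write_newick(species_tree, file.path(out_dir, "species_tree.nwk"))
  write_newick(focal, file.path(out_dir, "focal_tree.nwk"))
  for (og in names(cohort$trees)) {
    write_newick(cohort$trees[[og]], file.path(cohort_dir, paste0(og, ".nwk")))
  }
  write_tsv_table(cohort$species_map, file.path(out_dir, "species_map.tsv"))
  write_tsv_table(traits, file.path(out_dir, "traits.tsv"))

  manifest <- list(seed = seed, n_taxa = config$n_taxa,
                   birth_rate = config$birth_rate,
                   n_orthogroups = config$n_orthogroups,
                   rate_meanlog = config$rate_meanlog,
                   rate_sdlog = config$rate_sdlog,
                   branch_jitter_cv = config$branch_jitter_cv,
                   mean_rtt = config$mean_rtt, intercept = config$intercept,
                   slope = config$slope, target_r2 = config$target_r2,
                   noise_sd = noise_sd, n_sites = config$n_sites,
                   clade_age = config$clade_age,
                   n_cohort_trees = length(cohort$trees),
                   n_trait_rows = nrow(traits))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
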