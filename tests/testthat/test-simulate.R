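test_that("Yule simulation yields rooted ultrametric trees, deterministically", {
  t2 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_true(ape::is.rooted(t2))

  t20 <- simulate_yule_tree(20, 1, seed = 3)
  expect_true(ape::is.rooted(t20))
  expect_true(ape::is.binary(t20))
  expect_equal(diff(range(root_to_tip(t20))), 0, tolerance = 1e-12)
  expect_identical(write_newick(simulate_yule_tree(20, 1, seed = 3)),
                   write_newick(t20))
  expect_false(identical(write_newick(simulate_yule_tree(20, 1, seed = 4)),
                         write_newick(t20)))
})

test_that("Yule root-to-tip depth matches its closed-form expectation", {
  n <- 8
  lambda <- 1
  depths <- vapply(1:300, function(i) {
    root_to_tip(simulate_yule_tree(n, lambda, seed = 5000 + i))[[1]]
  }, numeric(1))
  expectation <- sum(1 / (2:n * lambda))
  se <- sqrt(sum(1 / (2:n * lambda)^2) / 300)
  expect_lt(abs(mean(depths) - expectation), 4 * se)
})

test_that("orthogroup cohorts scale the species tree by gene rates", {
  sp <- read_newick("((A:1,B:3):0.5,C:1.5);")
  # rate fixed at 1, no jitter: every tree identical to the species tree
  co1 <- simulate_orthogroup_cohort(sp, 3, rate_meanlog = 0, rate_sdlog = 0,
                                    seed = 6)
  for (tr in co1$trees) {
    expect_equal(tr$edge.length, sp$edge.length)
    expect_equal(sub("\\|OG\\d+$", "", tr$tip.label), sp$tip.label)
  }
  # rate fixed at 2: all patristic distances exactly doubled
  co2 <- simulate_orthogroup_cohort(sp, 2, rate_meanlog = log(2),
                                    rate_sdlog = 0, seed = 6)
  expect_equal(unname(patristic_matrix(co2$trees[[1]])),
               unname(2 * patristic_matrix(sp)))
  # species map covers every gene leaf
  co3 <- simulate_orthogroup_cohort(sp, 5, seed = 7)
  expect_setequal(co3$species_map$label,
                  unlist(lapply(co3$trees, `[[`, "tip.label")))
  expect_length(co3$rates, 5)
})

test_that("multi-copy families replace tips by stars of the stated divergence", {
  sp <- read_newick("((A:1,B:3):0.5,C:1.5);")
  fam1 <- simulate_multicopy_family(sp, 1)
  expect_identical(write_newick(fam1$tree), write_newick(sp))
  expect_equal(fam1$species_map$species, fam1$species_map$label)

  fam <- simulate_multicopy_family(sp, c(A = 1, B = 3, C = 1),
                                   within_species_divergence = 0.4)
  expect_equal(sum(fam$species_map$species == "B"), 3)
  expect_equal(patristic_distance(fam$tree, "B_1", "B_2"), 0.4)
  expect_equal(patristic_distance(fam$tree, "B_1", "B_3"), 0.4)
  # distance from a copy to another species = original + half the divergence
  expect_equal(patristic_distance(fam$tree, "B_1", "A"),
               patristic_distance(sp, "B", "A") + 0.2)

  # two copies with zero divergence: bootstrap over copies is degenerate
  fam0 <- simulate_multicopy_family(sp, c(A = 2, B = 2, C = 1),
                                    within_species_divergence = 0)
  bs <- stratified_bootstrap_tree_length(fam0$tree, fam0$species_map,
                                         n_reps = 100, seed = 8)
  expect_equal(bs$sd, 0)

  # Poisson-drawn copy numbers are reproducible
  famp <- simulate_multicopy_family(sp, lambda = 1.5, seed = 9)
  famp2 <- simulate_multicopy_family(sp, lambda = 1.5, seed = 9)
  expect_identical(write_newick(famp$tree), write_newick(famp2$tree))
})

test_that("directional traits follow intercept + slope * distance + noise", {
  tr <- perturb_branch_lengths(simulate_yule_tree(60, 1, seed = 12), 0.5,
                               seed = 13)
  noiseless <- simulate_directional_traits(tr, 81.1, 20, 0, seed = 14)
  f <- fit_ols(root_to_tip(tr)[noiseless$species], noiseless$trait)
  expect_equal(f$intercept, 81.1, tolerance = 1e-8)
  expect_equal(f$slope, 20, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)

  # null slope: estimates centred on zero relative to their SE
  zs <- vapply(1:100, function(i) {
    tt <- simulate_directional_traits(tr, 5, 0, 1, seed = 2000 + i)
    ff <- fit_ols(root_to_tip(tr)[tt$species], tt$trait)
    ff$slope / ff$se_slope
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 / sqrt(100))

  expect_identical(simulate_directional_traits(tr, 1, 2, 0.5, seed = 15),
                   simulate_directional_traits(tr, 1, 2, 0.5, seed = 15))
})

test_that("tree rescaling propagates linearly through every metric", {
  tr <- random_tree(12, seed = 16)
  sc <- rescale_tree(tr, 3.5)
  expect_equal(tree_total_length(sc), 3.5 * tree_total_length(tr))
  expect_equal(patristic_matrix(sc), 3.5 * patristic_matrix(tr))
  expect_equal(root_to_tip(sc), 3.5 * root_to_tip(tr))
})

test_that("fixture bundles are complete, loadable and seed-reproducible", {
  cfg <- default_sim_config(seed = 99)
  cfg$n_taxa <- 40L
  cfg$n_orthogroups <- 4L
  dir1 <- file.path(tempdir(), "bundle1")
  dir2 <- file.path(tempdir(), "bundle2")
  m1 <- make_fixture_bundle(cfg, dir1)
  m2 <- make_fixture_bundle(cfg, dir2)

  files <- c("species_tree.nwk", "focal_tree.nwk", "species_map.tsv",
             "traits.tsv", "manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(dir1, f)), info = f)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  expect_length(list.files(file.path(dir1, "cohort"), pattern = "\\.nwk$"), 4)

  focal <- read_newick(file.path(dir1, "focal_tree.nwk"))
  expect_equal(mean(root_to_tip(focal)), cfg$mean_rtt, tolerance = 1e-9)
  traits <- read_trait_table(file.path(dir1, "traits.tsv"))
  expect_equal(nrow(traits), 40)
  map <- read_species_map(file.path(dir1, "species_map.tsv"))
  expect_equal(nrow(map), 4 * 40)
  manifest <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_equal(manifest$seed, 99)
  expect_equal(manifest$noise_sd, m1$noise_sd)

  # generating parameters round-trip through the pipeline
  res <- pipeline_kinetics(focal, traits,
                           list(n_sites = cfg$n_sites,
                                clade_age = cfg$clade_age))
  expect_equal(res$regressions$trait, "S_CO")
  expect_lt(abs(res$regressions$slope - cfg$slope),
            4 * res$regressions$se_slope)
})
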