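test_that("background cohort collects cross-species pairs per orthogroup", {
  sp <- read_newick("((A:1,B:3):0.5,C:1.5);")
  co <- simulate_orthogroup_cohort(sp, 2, rate_meanlog = 0, rate_sdlog = 0,
                                   seed = 5)
  bg <- background_pair_distances(co, NULL, "A", "B")
  expect_equal(nrow(bg), 2)
  expect_equal(bg$distance, c(4, 4))

  # paralogs: two A copies against one B gene give two distances
  fam <- simulate_multicopy_family(sp, c(A = 2, B = 1, C = 1),
                                   within_species_divergence = 0.2)
  bg2 <- background_pair_distances(list(OGx = fam$tree), fam$species_map,
                                   "A", "B")
  expect_equal(nrow(bg2), 2)
  expect_equal(bg2$distance, c(4.1, 4.1))

  # explicit ortholog pairs override the all-pairs default
  bg3 <- background_pair_distances(list(OGx = fam$tree), fam$species_map,
                                   "A", "B",
                                   ortholog_pairs = data.frame(gene_a = "A_1",
                                                               gene_b = "B"))
  expect_equal(nrow(bg3), 1)
  expect_equal(bg3$gene_a, "A_1")

  expect_warning(empty <- background_pair_distances(co, NULL, "A", "Z"),
                 "absent from all orthogroup trees")
  expect_equal(nrow(empty), 0)
})

test_that("cohort distances equal the per-tree patristic oracle", {
  sp <- random_tree(6, seed = 61)
  co <- simulate_orthogroup_cohort(sp, 50, rate_meanlog = 0, rate_sdlog = 1,
                                   branch_jitter_cv = 0.2, seed = 62)
  bg <- background_pair_distances(co, NULL, "t1", "t2")
  expect_equal(nrow(bg), 50)
  for (i in sample(nrow(bg), 10)) {
    tr <- co$trees[[bg$orthogroup[i]]]
    expect_equal(bg$distance[i],
                 graph_distance_oracle(tr, bg$gene_a[i], bg$gene_b[i]),
                 tolerance = 1e-9)
  }
})

test_that("percentile rank counts the background evolving faster, with midrank ties", {
  expect_equal(percentile_faster(0.1, seq(0.2, 15, length.out = 150))$percent_faster,
               100)
  expect_equal(percentile_faster(99, 1:50)$percent_faster, 0)
  # focal equal to the median of 101 distinct values -> exactly 50
  expect_equal(percentile_faster(51, 1:101)$percent_faster, 50)

  set.seed(91)
  for (i in 1:200) {
    d <- sample(0:30, sample(5:60, 1), replace = TRUE)  # integer grid forces ties
    focal <- sample(0:30, 1)
    got <- percentile_faster(focal, d)$percent_faster
    faster <- 0
    for (v in d) {                       # brute-force counting oracle
      if (v > focal) faster <- faster + 1
      else if (v == focal) faster <- faster + 0.5
    }
    expect_equal(got, 100 * faster / length(d))
  }
})

test_that("percentile rank is monotone in the focal distance", {
  set.seed(92)
  d <- rlnorm(300)
  focals <- sort(runif(50, 0, max(d) * 1.1))
  pf <- vapply(focals, function(f) percentile_faster(f, d)$percent_faster,
               numeric(1))
  expect_true(all(diff(pf) <= 0))
})

test_that("cohort-size threshold flags at exactly min_n", {
  r99 <- percentile_faster(1, seq_len(99) + 1)
  r100 <- percentile_faster(1, seq_len(100) + 1)
  expect_false(r99$passed_threshold)
  expect_true(r100$passed_threshold)
  # empty cohort: undefined percentile, flagged
  r0 <- percentile_faster(1, numeric(0))
  expect_true(is.na(r0$percent_faster))
  expect_equal(r0$n_background, 0)
  # below-threshold results are excluded from summaries
  r99$species_a <- "A"; r99$species_b <- "B"
  expect_warning(s <- summarize_percentiles(r99), "threshold")
  expect_equal(nrow(s), 0)
  expect_equal(summarize_percentiles(rbind(r99, r100))$n_pairs, 1)
})

test_that("duplicate percentiles for one species pair average to the mean", {
  mk <- function(pf, n) {
    data.frame(species_a = "A", species_b = "B", focal_distance = 1,
               percent_faster = pf, percent_slower = 100 - pf,
               n_background = n, passed_threshold = n >= 100)
  }
  agg <- aggregate_duplicate_percentiles(rbind(mk(40, 150), mk(60, 120)))
  expect_equal(agg$percent_faster, 50)
  expect_equal(agg$n_background, 120)
  expect_true(agg$passed_threshold)

  one <- mk(73.5, 200)
  expect_equal(aggregate_duplicate_percentiles(one)$percent_faster, 73.5)

  set.seed(93)
  for (i in 1:20) {
    pfs <- runif(sample(2:6, 1), 0, 100)
    grp <- do.call(rbind, lapply(pfs, mk, n = 150))
    expect_equal(aggregate_duplicate_percentiles(grp)$percent_faster, mean(pfs))
  }
  expect_error(aggregate_duplicate_percentiles(mk(1, 1)[0, ]), "empty")
  expect_error(aggregate_duplicate_percentiles(rbind(mk(1, 150),
    within(mk(2, 150), species_b <- "C"))), "more than one species pair")
})

test_that("percentile summaries report quartiles over species pairs", {
  mk <- function(pf) data.frame(species_a = "A", species_b = paste0("B", pf),
                                focal_distance = 1, percent_faster = pf,
                                percent_slower = 100 - pf, n_background = 150,
                                passed_threshold = TRUE)
  allsame <- do.call(rbind, lapply(rep(100, 4), mk))
  s1 <- summarize_percentiles(allsame)
  expect_equal(unlist(s1[c("mean", "min", "q25", "median", "q75", "max")]),
               c(mean = 100, min = 100, q25 = 100, median = 100, q75 = 100,
                 max = 100))
  spread <- do.call(rbind, lapply(c(0, 25, 50, 75, 100), mk))
  s2 <- summarize_percentiles(spread)
  expect_equal(s2$median, 50)
  expect_equal(s2$q25, 25)
  expect_equal(s2$q75, 75)
})

test_that("a focal gene at a known rate quantile recovers its percentile", {
  # focal rate fixed at the q-quantile of the gene-rate distribution:
  # percent_faster should concentrate near 100 * (1 - q)
  sp <- simulate_yule_tree(6, 1, seed = 71)
  q <- 0.25
  co <- simulate_orthogroup_cohort(sp, 400, rate_meanlog = 0, rate_sdlog = 1,
                                   seed = 72)
  focal <- rescale_tree(sp, qlnorm(q, 0, 1))
  rk <- pipeline_rank(focal, co, NULL, list(min_n = 100))
  expect_lt(abs(mean(rk$results$percent_faster) - 100 * (1 - q)), 5)
})
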