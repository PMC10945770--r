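# evoextent

Tools for measuring **how much molecular evolution a gene has accumulated**
and for testing whether that evolution is **directional** with respect to a
continuous trait.

The package is aimed at molecular evolutionists asking questions of the form
"is this gene unusually slow- or fast-evolving relative to the rest of the
genome?" and "have the sequence changes it did accumulate been improving a
measurable phenotype?" — the kind of analysis applied, for example, to the
CO₂-fixing enzyme rubisco in plants, where the chloroplast-encoded large
subunit is among the slowest-evolving genes known yet shows trait
improvement with accumulating substitutions.

## What it computes

Trees are ordinary `ape` `"phylo"` objects with branch lengths in
substitutions per aligned site.

**Extent of molecular evolution** (`tree_total_length`, `root_to_tip`,
`patristic_distance`, `prune_preserving_lengths`,
`stratified_bootstrap_tree_length`): the total tree length of a gene
phylogeny measures all evolution since the clade's last common ancestor; the
root-to-tip distance `d_i` measures the evolution of species *i*'s ortholog;
the patristic distance `d_{ij}` measures the evolution separating two
orthologs. For multi-copy gene families, a stratified bootstrap resamples
exactly one copy per species per replicate (pruning the tree without
altering any retained path length) and reports mean ± SD of the total
length, so copy-number differences cannot inflate the comparison.

**Genome-wide percentile rank** (`background_pair_distances`,
`percentile_faster`, `pipeline_rank`): for each species pair, the focal
gene's patristic distance is ranked against the cohort of ortholog distances
measured across all orthogroup trees containing that pair,

    percent_faster = 100 · (#{d > d_focal} + ½·#{d = d_focal}) / n ,

with a minimum cohort size (default 100) per species pair and averaging of
duplicate percentiles.

**Directional selection on traits** (`fit_ols`, `run_trait_regressions`,
`ancestral_trait`, `improvement_rates`, `pipeline_kinetics`): each trait *y*
is regressed on root-to-tip distance *x* by ordinary least squares,
`y = a + b·x + ε`. A significant slope indicates sustained directional
change; the intercept `a` estimates the trait value of the clade's ancestor
(reported mean ± 1 SE). Slopes convert to interpretable rates:
change per single substitution `b / n_sites`, relative improvement per
substitution `100 · (b / n_sites) / a` (%), substitution interval
`clade_age / (mean(x) · n_sites)` (My), and relative improvement per My.

**Neutral expectation** (`neutral_expected_fraction`,
`simulate_neutral_codon_substitutions`): the fraction of single-nucleotide
changes that alter the protein under the standard genetic code (stop-creating
changes excluded), used as the no-selection reference line when comparing
protein to nucleotide tree lengths.

**Alignment preprocessing** (`thread_codon_alignment`, `trim_ungapped`,
`length_filter`, `min_columns_gate`): codon-alignment threading from a
protein alignment plus its CDS set, removal of all gapped columns (whole
codons at a time), leave-one-out median length filtering, and the
">50 ubiquitously aligned positions" gate.

**Synthetic data** (`simulate_yule_tree`, `simulate_orthogroup_cohort`,
`simulate_multicopy_family`, `simulate_directional_traits`,
`make_fixture_bundle`): generators with the statistical structure the
analysis assumes, so every stage is testable end to end without external
data.

## Worked example

```r
library(evoextent)

# a focal gene tree with rate variation, and a trait improving with distance
species <- simulate_yule_tree(93, birth_rate = 1, seed = 1)
gene    <- perturb_branch_lengths(species, cv = 0.5, seed = 2)
gene    <- rescale_tree(gene, 0.05 / mean(root_to_tip(gene)))
traits  <- simulate_directional_traits(gene, intercept = 81.1, slope = 128,
                                       noise_sd = 1.9, seed = 3,
                                       trait_name = "S_CO")

res <- pipeline_kinetics(gene, traits, list(n_sites = 476, clade_age = 160))
res$regressions
#>   trait  n    slope se_slope intercept se_intercept r2_percent      p_slope
#> 1  S_CO 93 136.0455 24.00217   80.6918     1.212449   26.09244 1.682471e-07
res$improvements[, c("trait", "per_substitution_change",
                     "relative_per_substitution", "my_per_substitution",
                     "relative_per_my")]
#>   trait per_substitution_change relative_per_substitution my_per_substitution
#> 1  S_CO               0.2858099                 0.3541995            6.722689
#>   relative_per_my
#> 1      0.05268717
```

The slope and intercept recover the generating parameters (128 ± SE, 81.1 ±
SE); the chain converts them to a 0.29 trait-unit gain per substitution, a
0.35% relative improvement per substitution, one substitution per 6.7 My at
this tree depth, and 0.05% improvement per My.

Ranking a slow focal gene against a background cohort:

```r
cohort <- simulate_orthogroup_cohort(simulate_yule_tree(6, 1, seed = 4),
                                     n_orthogroups = 500, seed = 5)
focal  <- rescale_tree(simulate_yule_tree(6, 1, seed = 4), qlnorm(0.01, 0, 1))
rank   <- pipeline_rank(focal, cohort, NULL, list(min_n = 100))
rank$summary
#>   n_pairs mean  min  q25 median  q75  max
#> 1      15 98.8 98.8 98.8   98.8 98.8 98.8
```

A gene whose rate sits at the 1st percentile of the gene-rate distribution
is ranked slower than ~99% of the background, as expected.

## Scope

Alignment inference, tree inference, model selection and orthology inference
are upstream of this package: it consumes their outputs (Newick, FASTA,
TSV). Regressions are ordinary least squares, matching the analysis it
implements; phylogenetically corrected regression is out of scope. See
`vignettes/evoextent-methods.Rmd` for the model, assumptions, parameter
choices and limitations.
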