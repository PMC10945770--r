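---
title: "Measuring the extent and direction of molecular evolution with evoextent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the extent and direction of molecular evolution with evoextent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoextent)
```

## The problem

Branch lengths of a maximum-likelihood gene tree estimate substitutions per
aligned site, so a gene's phylogeny is itself a record of how much molecular
evolution the gene has experienced. Three summaries of that record carry the
analysis:

* **total tree length** — all evolution accumulated in the gene across a
  clade since its last common ancestor;
* **root-to-tip distance** `d_i` — the evolution experienced by species
  *i*'s ortholog since that ancestor;
* **patristic distance** `d_ij` — the evolution separating two species'
  orthologs since their divergence.

Two scientific questions are built on these summaries. First, *is the focal
gene unusually slow (or fast)?* — answered by ranking its patristic distance,
species pair by species pair, against the distances of all other orthologous
gene pairs measured across orthogroup trees. Second, *has its evolution been
directional with respect to a phenotype?* — answered by regressing trait
values on root-to-tip distance: under directional selection, lineages whose
ortholog has evolved further should show systematically better trait values,
and the regression intercept (zero distance) estimates the trait of the
clade's common ancestor.

## Assumptions

All analyses take the trees as given; uncertainty in tree inference is not
propagated. Branch lengths must be comparable across the trees being
compared, which in practice means alignments trimmed to ubiquitously aligned
positions and a substitution model held constant across genes — the
preprocessing utilities (`thread_codon_alignment`, `trim_ungapped`,
`length_filter`, `min_columns_gate`) implement the corresponding alignment
hygiene, while alignment, tree and orthology inference themselves are
upstream tools whose outputs this package consumes.

The trait regression is **ordinary least squares**, treating species as
independent observations. Shared phylogenetic history induces residual
correlation that OLS ignores; this is a deliberate scope decision (the
method being implemented is the least-squares analysis itself) and the main
caveat when interpreting p-values — see *Limitations*.

## Key operations and their conventions

**Rooting and pruning.** `root_at_outgroup` reroots on the edge separating a
(unrooted-sense monophyletic) outgroup from the rest; total length and all
patristic distances are invariant. `prune_preserving_lengths` removes
leaves and collapses the resulting unary nodes by summing branch lengths, so
every retained pairwise distance is exactly preserved; the original root is
always retained (as a degree-one root if needed) so root-to-tip distances
are preserved too — this matters because the bootstrap and the trait
analysis both measure evolution *from the original common ancestor*.

**Stratified bootstrap** (`stratified_bootstrap_tree_length`). Gene families
that are multi-copy in some genomes would otherwise contribute more branches
than single-copy families. Each replicate samples exactly one copy per
species (uniformly), prunes the fixed input tree and records its total
length; the summary is mean ± SD over replicates. Replicates reuse the fixed
tree rather than re-inferring one per sample: branch lengths are per-site
estimates on the full data, resampling them is deterministic and
desk-scale, and the sampling distribution over copies is the quantity of
interest. A seed is a required argument, never defaulted.

**Percentile rank** (`percentile_faster`). The rank is reported in the
direction "percent of the background evolving faster than the focal gene",
with midrank (weight 0.5) tie handling — the standard percentile-rank
convention; ties are real because distances come from finite-precision
files. Cohorts below `min_n = 100` ortholog measurements per species pair
are retained in output but flagged and excluded from summaries, so sparse
pairs cannot quietly bias a boxplot. When one species pair yields several
percentiles (gene duplicates; one assembly matching several sub-species),
`aggregate_duplicate_percentiles` takes the mean percentile and the
*minimum* cohort size, keeping the threshold flag conservative. By default
every cross-species leaf pair in an orthogroup counts as an ortholog pair —
an over-count when paralogs are present — and an explicit ortholog-pair list
from an orthology tool overrides it.

**Neutral expectation** (`neutral_expected_fraction`). The reference for
"how much protein change per nucleotide change would no selection produce"
is computed by exhaustive enumeration: per codon, the nine single-nucleotide
changes under the standard genetic code, excluding changes creating stops,
and the nonsynonymous fraction of the remainder, averaged over codons. The
mutation model is uniform (no transition/transversion bias, no codon usage
weighting): a documented simplification, adequate for a reference line.
Because protein lengths are per amino-acid site (3× fewer sites), the
neutral protein-per-nucleotide length ratio is `3 · f_N`.
`simulate_neutral_codon_substitutions` provides the independent long-run
check of the enumeration.

**The improvement chain.** With slope `b` (trait units per
substitutions-per-site), intercept `a`, alignment length `n_sites`, mean
root-to-tip distance `mean_rtt` and clade age `clade_age` (My):

| quantity | formula | units |
|---|---|---|
| change per substitution | `b / n_sites` | trait units |
| relative improvement per substitution | `100 · (b / n_sites) / a` | % |
| substitution interval | `clade_age / (mean_rtt · n_sites)` | My |
| relative improvement per My | per-substitution % ÷ interval | %/My |

The per-My figure is always computed from the *unrounded* per-substitution
figure; rounding (one decimal for percentages) is display-only.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_n` | 100 | minimum ortholog measurements per species pair |
| `min_fraction` | 0.5 | leave-one-out median length filter |
| `min_cols` | 50 | strict gate: > 50 ubiquitously aligned positions |
| `clade_age` | 160 My | age of the clade radiation (angiosperm default) |
| `n_sites` | 476 | aligned sites of the focal gene (trimmed RbcL-scale) |
| `n_reps` | 1000 | bootstrap replicates |

The `min_cols` gate is read strictly ("more than 50"): 51 columns pass, 50
fail. Negative branch lengths are rejected at parse time unless
`clamp_negative = TRUE` is set, since ML trees are non-negative and silent
clamping hides corrupt input. Terminal stop codons are silently dropped
during threading (the common CDS convention); internal stops are errors.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
estimators assume, so recovery failures localise bugs rather than model
mismatch:

* `simulate_yule_tree` — pure-birth species tree; waiting time to the next
  split is exponential with rate `k · birth_rate`, giving expected depth
  `Σ_{k=2}^{n} 1/(kλ)` (the closed form the tests check).
* `simulate_orthogroup_cohort` — each orthogroup tree is the species tree
  scaled by a gene rate `r_g ~ LogNormal(0, 1)` plus optional per-branch
  LogNormal jitter (mean 1, given CV). The LogNormal gives the heavy-tailed
  among-gene rate variation the percentile analysis assumes; a focal gene
  fixed at quantile `q` of the rate distribution should recover
  `percent_faster ≈ 100(1 − q)`.
* `simulate_multicopy_family` — species tips replaced by stars of copies at
  a stated within-species divergence, the structure the stratified bootstrap
  corrects for.
* `simulate_directional_traits` — `trait = a + b·d_i + ε`, ε i.i.d.
  Gaussian: the same functional form the regression fits, chosen over
  Brownian-motion trait evolution deliberately, because the validation
  surface is recovery of the regression model itself and phylogenetic
  residual correlation is a known, documented omission.

Default generator settings mirror a plausible study: 93 species with traits,
500 orthogroups in the background cohort, branch jitter CV 0.1, focal-gene
depth 0.05 substitutions/site over 476 sites, ancestral trait 81.1 with
slope 128 (≈ 0.27 trait units per substitution), clade age 160 My. When no
noise SD is supplied, `make_fixture_bundle` calibrates it to an expected
variance explained of 10% via `noise_sd = |b|·sd(d)·sqrt(1/r² − 1)`, a
realistic signal strength for a single kinetic trait.

What passing tests on these data do **not** show: robustness to
phylogenetically correlated residuals, to tree-inference error, to
misalignment, or to non-LogNormal rate distributions. They validate the
estimators under their own assumptions.

## Numerical choices

* Distance computations use one preorder sweep for node depths and the
  identity `d_ij = d_i + d_j − 2·d_mrca`; tests compare against independent
  graph-shortest-path and cophenetic oracles at 1e-9.
* Pruning is exact arithmetic on summed branch lengths (tolerance 1e-9 in
  invariant tests).
* OLS is delegated to `stats::lm`; r² is computed as `1 − SSE/SST` and the
  slope p-value as a two-sided t test with `n − 2` df. A constant response
  is special-cased to slope 0, r² 0, p `NA` (the 0/0 case). Fits require
  `n ≥ 3` and nonzero variance in the distances; missing trait values are
  dropped pairwise per trait, so each trait keeps its own n.
* All simulators require a seed argument; identical seeds give bit-identical
  outputs, including byte-identical fixture bundles.

## Problem sizes used in validation

The shipped tests run the full loop at desk scale: 100-tree invariant
checks, a 500-orthogroup cohort for percentile recovery, 500 replicates for
regression bias/coverage, and 2000 null simulations for the type-I error of
the slope test — sizes at which Monte-Carlo error is small relative to the
tolerances being asserted while the whole suite stays fast.

## Limitations

* OLS p-values treat species as exchangeable; with strong phylogenetic
  signal in residuals they are anti-conservative. Conclusions about
  *direction* (sign and magnitude of slopes) are more robust than exact
  significance levels.
* The default all-cross-pairs orthology designation inflates cohort sizes
  when paralogs are present; supply an explicit ortholog-pair list when one
  exists.
* The neutral expectation uses a uniform mutation model; mutation bias can
  shift the reference line by a few percentage points.
* Percentile results depend on the background cohort actually being
  comparable (same species pair, same time depth); the package enforces the
  species-pair structure but cannot verify upstream model constancy.
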