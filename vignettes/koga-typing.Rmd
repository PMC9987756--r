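---
title: "Oral–gut microbiome typing, networks and panel scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oral–gut microbiome typing, networks and panel scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kogatyper)
```

This vignette is the package's own account of the statistics it
implements: the assumptions behind each step, the parameters that matter,
the numerical conventions, and what the validation on synthetic cohorts
does and does not establish.

## The typing model

The pipeline treats each sample's genus-level relative-abundance vector as
a point on the probability simplex and asks whether the cohort decomposes
into a few dominant-genus configurations.

**Preprocessing.** Lineage labels ending in the empty-rank marker `;__`
denote reads not classified at the working rank; they are removed
(`drop_unnamed_taxa`) and relative tables renormalised. Counts are
converted to relative abundances per sample (`to_relative`). Rare genera
are then removed by `prevalence_filter`: a genus is kept only when its
*unweighted mean* relative abundance across the samples of the input table
strictly exceeds `min_mean_frac` (default `1e-4`, i.e. 0.01%). Strict
inequality means a genus sitting exactly at the cutoff is dropped. The
filtered table is deliberately *not* renormalised — the retained
high-abundance genera are compared as-is, so clustering distances are not
distorted by how much rare mass each sample happened to carry. Whether the
filter is applied once globally or per subgroup during nested typing is
the caller's choice; `run_typing_pipeline` filters once per body site
(the default), while `assign_koga_types(min_mean_frac = )` re-filters
within each oral-type subgroup.

**Distances.** Dissimilarity between samples is the root Jensen–Shannon
divergence with natural logarithms. Zeros are replaced by an additive
pseudocount (`pseudocount = 1e-9`, well below any abundance surviving the
prevalence filter) followed by renormalisation, which leaves the distance
between disjoint-support profiles within `1e-4` of its theoretical bound
\(\sqrt{\ln 2} \approx 0.8326\). The square root makes the dissimilarity a
metric; cluster labels are unaffected by whether the root is taken, only
the geometry of ordinations changes, and the package uses the metric form
everywhere (including PCoA) for consistency.

**Clustering.** `pam_cluster` is a deterministic k-medoids solver.
Instances with `choose(n, k) <= exact_threshold` (default 1000) are solved
by exact enumeration of medoid sets, ties broken towards the
lexicographically smallest set. Larger instances use greedy BUILD followed
by steepest-descent SWAP with lowest-index tie-breaks and no random
restarts, so results are a pure function of the distance matrix. The exact
path exists because single-swap descent has genuine local optima even at
n = 7 (we found a 7-point instance where BUILD+SWAP — ours and the
reference `cluster::pam` alike — terminates 2.5% above the optimum);
solving small instances exactly costs microseconds and removes that
failure mode, while both paths optimise the same objective
\(\sum_x d(x, \mathrm{medoid}(x))\).

**Choosing k.** `select_k` fits k = 2..`k_max` (default 10) and picks the
k maximising a medoid-based Calinski–Harabasz index: within-dispersion
\(W=\sum_x d(x,\mathrm{medoid}(x))^2\), between-dispersion
\(B=\sum_c n_c\, d(\mathrm{medoid}_c, g)^2\) with \(g\) the global medoid,
\(CH = (B/(k-1))/(W/(n-k))\). Using medoids rather than Euclidean
centroids keeps the index well-defined on an arbitrary distance matrix and
deterministic; \(W = 0\) (all points coincident with their medoids)
returns an `Inf` sentinel. Mean silhouette widths are reported alongside
as a robustness check, with members of singleton clusters contributing 0
by convention. Ties in CH resolve to the smallest k.

**Labelling and nesting.** Each cluster is named after the genus
maximising (mean abundance inside − mean abundance outside) the cluster,
ties resolved alphabetically. The contrast rule (rather than the raw
inside mean) matters when one genus — *Streptococcus* in saliva — is
globally abundant: the *Haemophilus*-led cluster would otherwise also be
labelled *Streptococcus*. The raw-inside-mean rule remains available via
`dominant_taxon_labels(rule = "inside_mean")`. Oral type letters (S/H)
come from the dominant genus initials; the nested step re-runs the whole
pipeline on the gut samples *within* each oral-type subgroup (subgroups
below four samples are refused) and concatenates the letters into SB, SP,
HB, HP. Percentages in `type_frequencies` are rounded half-up to one
decimal, matching how such tables are conventionally printed.

## Significance tests

`permanova` implements one-way distance-based PERMANOVA with
\(SS_{total} = \sum_{i<j} d_{ij}^2/n\), per-group within-sums analogously,
and p-values \((\#\{F_{perm} \ge F_{obs}\}+1)/(n_{perm}+1)\) over seeded
label permutations (default `n_perm = 999`). The pseudo-F agrees with
`vegan::adonis2` to machine precision; the permutation scheme is
re-implemented so that seeding is explicit. `rank_sum_differential` runs a
per-taxon two-sided Mann–Whitney U with the normal approximation and tie
correction, no continuity correction, and no multiplicity adjustment —
it is a screening table with star flags, not a confirmatory analysis. A
taxon constant across both groups is reported with `U = nm/2`, `p = 1`.

## SparCC networks

`sparcc` estimates basis correlations from compositional counts under the
sparsity assumption: per inner iteration, fractions are drawn from
Dirichlet(counts + 1) per sample; the log-ratio variance matrix
\(T_{ij} = \mathrm{Var}\log(f_i/f_j)\) (n−1 denominator) feeds the linear
system with \(D-1\) on the diagonal and 1 off it, whose solution
\(\omega\) gives \(\rho_{ij} = (\omega_i+\omega_j-T_{ij}) /
(2\sqrt{\omega_i\omega_j})\), clipped to \([-1,1]\). The strongest pair
with \(|\rho|\) above `exclusion_threshold` (default 0.1) is iteratively
removed from the system, up to `max_exclusions` (default 10) rounds or
until the reduced system would become singular, whichever comes first;
negative basis variances are clamped at `1e-12` before the square root.
The reported matrix is the element-wise median over `n_inner` (default 20)
iterations. Estimation needs at least four taxa and refuses all-zero taxa
rather than dropping them silently. Counts are the expected input — the
estimator's whole point is to undo the compositional closure itself.

Permutation p-values (`permutation_pvalues`) shuffle each taxon's counts
independently across samples — destroying all between-taxon association
while preserving marginals — and re-estimate with a reduced
`n_inner_perm = 5` for tractability; with the default `n_perm = 100` the
smallest attainable p is 1/101, just resolving the conventional 0.05
cutoff. Network extraction (`seeded_two_level_network`) is a deterministic
pure function of (R, p, cutoffs): level 1 collects partners of the seed
genus at strictly `|R| > 0.3` and `p < 0.05`, level 2 collects each
level-1 partner's own significant partners excluding *only* the seed —
other level-1 members may legitimately re-appear in second networks, as
published two-level tables show.

## The synthetic cohort generator

`simulate_paired_cohort` is the package's test bed. Per subject it draws
an oral cluster from `mixture_weights`, a gut cluster from the oral
cluster's row of the 2×2 `coupling` matrix, a genus composition from a
Dirichlet whose cluster-dominant genus concentration is multiplied by
`dominance_boost`, and counts from a multinomial at `depth`. The defaults
are the study conditions the pipeline is validated under: 112 subjects,
oral weights (0.554, 0.446), coupling rows (0.694, 0.306) and
(0.720, 0.280) — which put the four composite types near 38/17/32/13% —
boost 50, depth 20 000, and 20 genera per site with unit base
concentration. Boost 50 over unit concentrations gives the dominant genus
an expected share near 70% within its cluster, a deliberately
well-separated regime; boost 1 is the null with no planted structure.
Within-type dispersion is not something the real cohort reports, so these
defaults are tuned for testability: unimodal Dirichlet noise, no
overdispersion beyond the compositional draw, no taxon correlations, no
batch effects, and sequencing depth fixed rather than variable. Passing
recovery tests on this generator therefore shows the pipeline's operations
are correct and well-composed — not that real saliva/stool cohorts
separate this cleanly.

`simulate_correlated_counts` generates the matching test bed for SparCC —
lognormal basis abundances with a prescribed log-scale covariance,
closed to fractions, multinomial counts — and stashes the true basis logs
in an attribute so tests can compare against the Pearson oracle on the
unobserved basis. `prevalence_fixture_table` builds a relative table whose
taxon means straddle the 0.01% cutoff by construction (75 of 215 genera
passing, mirroring the scale of a real genus table).

All generators take a single seed, restore the caller's RNG state, and are
bit-reproducible given the spec.

## The panel-scoring statistic

For a panel of beneficial/harmful species, `type_means` averages relative
abundance over the samples of each composite type; `z_across_types`
standardises each species row across the types using the *sample* (n−1)
standard deviation; `reverse_harmful` negates harmful rows so scarcity of
pathogens raises the score; `percentile_from_z` maps
\(z \mapsto \mathrm{round}(100\,\Phi(z))\) with half-away-from-zero
rounding; `quartile_score` bins percentiles at 25/50/75 with lower-closed
bins (`[25,50) -> 2`) and the endpoints clamped into the outer bins; and
`score_panel` sums the quartile scores per body site and type.

Three conventions deserve emphasis, because they decide boundary species
and hence the totals. First, the percentile is the *population* normal CDF
of the z value, not the empirical rank of the type among the four types —
with four values per row, ranks could only yield four distinct
percentiles, which is inconsistent with the published totals the package
reproduces. Second, percentiles are rounded to the nearest integer
*before* binning: \(\Phi(-0.6902) = 0.24506\) becomes 25 and scores 2, not
1 — on the shipped worked-example panel this single convention moves one
oral type's total by one point. Third, the n−1 standard deviation is
confirmed by the fixture's own rows, which have sample sd exactly 1
(e.g. the ±0.5/∓1.5 pattern of a species abundant in a single type).
A species with identical means in every type is degenerate: it scores
z = 0, percentile 50, quartile 3 everywhere, and triggers a warning.

`scoring_panel_fixture` ships the published 29-row worked example (14 oral
species — 9 beneficial, 5 harmful; 15 gut — 10 + 5) with harmful rows
stored post-reversal exactly as printed, and `network_fixture` ships the
published S- and H-type two-level edge lists; both exist so the scoring
and tallying machinery can be validated against printed results without
any sequence data.

## Validation scales and limitations

The test suite exercises: planted-cohort recovery over 50 cohorts at the
default study conditions (optimal-k hit rate, adjusted Rand index of oral
and composite labels); exact PAM-vs-enumeration equivalence on 200 random
instances with n ≤ 7; SparCC bias, planted-signal recovery (D = 50,
n = 200, depth 10 000) and compositional scale invariance; PERMANOVA
type-I error over 500 null simulations at 99 permutations each; and exact
reproduction of the worked-example scoring totals and network tallies.
These sizes keep the default suite around a minute on one core.

Known limitations:

* The pipeline clusters *tables*; it does not model uncertainty in the
  cluster assignments, and k selection by CH is a point decision.
* SparCC point estimates at n = 200 carry sampling noise of roughly
  \(1/\sqrt{n} \approx 0.07\) per pair; the *mean absolute* off-diagonal
  correlation under independence therefore sits near
  \(\sqrt{2/(\pi n)} \approx 0.056\) — that is the attainable floor for
  any consistent estimator at this sample size (the Pearson oracle on the
  true basis logs sits at the same level), so calibration is asserted on
  the signed-mean bias, which the estimator keeps well under 0.05.
* Permutation p-values for SparCC use reduced inner iterations; they are
  screening p-values, slightly noisier than the point estimates.
* The scoring statistic standardises across exactly the types present; it
  is a relative comparison among those types, not an absolute health
  index, and the package takes the species panel as user input rather
  than deriving it.
* The generator's independence and unimodality assumptions (above) bound
  what synthetic recovery can claim about real cohorts.
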