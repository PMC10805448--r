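---
title: "Methods: FA-weighted white-matter network analysis and its synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FA-weighted white-matter network analysis and its synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanet)
```

## The analysis in one paragraph

`fanet` implements a graph-theoretic case-control analysis of white-matter
structural brain networks of the kind used to study temporal lobe epilepsy
(TLE). Each subject's brain is represented as a 90-node network over the AAL
parcellation: an edge connects two regions when deterministic tractography
found streamlines between them with mean fractional anisotropy (FA) strictly
above 0.2, and the edge carries that mean FA as its weight (`FA_wei`) or a 1
(`FA_bin`). Per subject the package computes global efficiency
$E_g = \frac{1}{n(n-1)}\sum_{i \ne j} d_{ij}^{-1}$, characteristic path
length $L_p$ (mean shortest-path length over reachable pairs), clustering
coefficient $C_p = \frac{1}{n}\sum_i 2t_i/(k_i(k_i-1))$, local efficiency
$E_{loc}$ (mean efficiency of each node's neighbour-induced subgraph), nodal
efficiency $E_{nodal}(i) = \frac{1}{n-1}\sum_{j \ne i} d_{ij}^{-1}$, degree
$k_i$, and the small-world coefficient $\sigma = \gamma/\lambda$ with
$\gamma = C_p/C_{rand}$ and $\lambda = L_p/L_{rand}$ against degree-matched
rewired null networks. A covariate-adjusted statistical layer compares every
property between groups (linear model with age and gender, Benjamini-
Hochberg FDR within families) and correlates nodal efficiency with clinical
characteristics (partial correlation; age and gender controlled, plus age at
seizure onset for the epilepsy-duration analysis). Because no imaging data
ship with the package, a first-class synthetic-cohort generator produces
subject tables and region-pair streamline summaries with known planted
structure, so every stage is testable end to end.

## Numerical conventions of the metric engine

* **Weight-to-length mapping.** Shortest paths on weighted networks run
  over edge lengths $1/w$ (the usual convention for FA-weighted networks,
  where high FA means good communication). `one_minus` ($1-w$) is available
  via `weight_conversion` for sensitivity analyses.
* **Weighted clustering.** The binary triangle formula is printed above;
  for weighted networks we use the Onnela generalisation (geometric mean of
  max-normalised triangle weights), the default of the standard brain-
  connectivity toolboxes. `FA_bin` networks always use the binary formula.
* **Disconnected graphs.** Efficiency-type metrics give unreachable pairs
  zero contribution (the harmonic convention), so they are defined for any
  graph; $L_p$ averages reachable pairs only and the unreachable count is
  reported alongside (`n_unreachable_pairs`). An edgeless network returns
  zero efficiencies and `Lp = NA` rather than an error.
* **Null ensembles.** Maslov-Sneppen double-edge swaps preserve each node's
  degree exactly; weights travel with their edges, so the weight multiset is
  preserved too. Defaults: 100 nulls, 10 accepted swaps per edge. A graph
  with no eligible swap (e.g. complete) raises an explicit error, or passes
  unrewired copies when `on_degenerate = "identity"`.
* **Hub criterion.** A region is a hub when its group-mean degree exceeds
  the grand mean over regions by more than `sd_multiplier` (default 1)
  across-region standard deviations. The criterion is stored with the table
  so flags are reproducible from the reported means.

## The synthetic cohort: what it emulates

The generator reproduces the study conditions of a two-group TLE design:
18 patients (10 male, age 30.4 ± 8.16 y) and 29 controls (17 male,
27.8 ± 5.78 y); epilepsy duration 13.90 ± 7.15 y and age at seizure onset
16.28 ± 10.69 y with correlation −0.632; verbal IQ 90.00 ± 11.57 vs
109.45 ± 11.91 and performance IQ 95.06 ± 10.90 vs 109.00 ± 10.51. Gender
counts are matched exactly; ages are truncated at 18 (adult cohort) by
resampling; IQ scores are rounded to integers as psychometric scales
deliver them.

**Clinical copula.** Duration and onset are drawn from a bivariate Gaussian
truncated to the positive quadrant by rejection (resampling, so no point
mass at zero). Because the configured moments describe the *observed*
(nonnegative) data, the latent Gaussian parameters are moment-matched
numerically (two-dimensional Gauss-Legendre quadrature inside a Nelder-Mead
solve, cached per parameter set) so that the delivered truncated sample has
exactly the configured means, SDs and correlation. Naive truncation of the
configured parameters would attenuate the correlation from −0.632 to about
−0.55 and shift the means. Degenerate SDs (set to 0) bypass the solve and
return the means exactly. Duration and onset are not constrained to sum to
the subject's age; the three are consistent only in expectation.

**Connectome template.** One weighted template per cohort is drawn from a
distance-dependent, modular random geometric model: connection propensity
decays exponentially with Euclidean distance between region centroids
(30 mm e-folding), is boosted within a hemisphere (×1.25) and within a lobe
(×1.9), and is scaled by region-class propensities. A planted hub backbone
(bilateral precuneus, putamen, middle temporal gyrus; right dorsolateral
superior frontal, superior parietal and inferior temporal gyri; left
calcarine and middle occipital gyrus — the association-cortex hub layout of
measured adult connectomes) receives a ×2.1 propensity boost, and the
propensity kernel is raised to the power 3 (`kernel_sharpness`), which
makes edge probabilities near-deterministic. Both choices exist for one
reason: with a flat propensity continuum, the mean-plus-SD hub criterion
cuts through a dense part of the degree distribution and hub identity
becomes sampling noise; the backbone plus sharpened kernel create an
expected-degree gap so the hub set is a reproducible property of the
generator (mean Jaccard overlap across independent cohorts ≈ 0.87 in our
tests) rather than an artifact. The propensity matrix is rescaled by a
monotone root solve so the expected binary mean degree equals
`density_calibration`; a single uniform draw per pair makes the realised
edge set monotone in that parameter. Edge weights are 0.2 plus an
exponential excess (mean 0.12, capped below 1), placing substantial mass
just above the FA > 0.2 detection threshold, as weak long-range tracts in
real tractography do — this mass is what lets attenuation remove edges.

**Planted effects.** For patients, every edge incident to
`affected_regions` (by default the temporal/limbic regions implicated in
the emulated study: bilateral posterior cingulate and parahippocampal gyri,
right anterior cingulate, left middle cingulate, left amygdala, left
superior/middle/inferior temporal gyri, left temporal poles) is multiplied
by `fa_attenuation` × (1 − `duration_slope` × duration). Edges incident to
`iq_regions` are multiplied by 1 + `iq_coupling` × (performance IQ − 100)/15
for every subject — a brain-behaviour coupling, not a disease effect.
Per-subject Gaussian FA jitter (`edge_noise_sd` = 0.015) and negative-
binomial streamline counts complete the streamline summaries. Attenuated
edges whose FA falls to 0.2 or below are still emitted and are dropped by
the construction threshold — that is the mechanism by which the patient
group loses binary degree.

**Calibration.** `density_calibration = 10.17` and `fa_attenuation = 0.775`
are frozen defaults chosen once so that 10-seed averages of the grand-mean
binary degree reproduce the emulated study's printed values (9.782 controls,
9.088 patients); held-out seeds reproduce them to within 0.08. The implied
mean FA reduction on affected-region edges (≈ 24% at the mean duration) is
at the strong end of what diffusion studies report; it is the magnitude the
printed degree gap requires under this weight distribution, and it makes
planted-effect recovery unambiguous.

**Seeds.** A single cohort seed draws the subject table and the template;
per-subject streamline seeds derive deterministically from it
(`seed × 1000 + ordinal`), so any subject can be regenerated alone.

## Statistical layer

"Two-sample t test with age and gender controlled" is operationalised as
the group term of the additive linear model `y ~ group + age + gender`
(gender as a 0/1 indicator, no interactions); adjusted group means are
evaluated at grand-mean covariates. When covariates carry no information
the statistic reduces exactly to the classical pooled two-sample t. FDR
families: the 90 nodal-efficiency tests form one family per network kind,
the global metrics one family per network kind, and each clinical variable's
90 correlations one family; every result row records its family. Partial
correlations residualise both variables on the covariates (with intercept)
and use $t = r\sqrt{df/(1-r^2)}$ with $df = n - 2 - k$. Normality screening
uses the Lilliefors-corrected Kolmogorov-Smirnov test (plain KS would be
anti-conservative with sample-estimated parameters); it is advisory and
gates nothing. Clinical correlations are computed for patients and the
FA-weighted network only, since binarisation discards the FA information
the correlation targets.

## What passing tests show — and what they do not

The simulation's between-subject variability comes from edge jitter and the
duration/IQ couplings only; real cohorts add registration error,
tractography failures, and biological heterogeneity that this generator
does not model. Two consequences follow. First, planted effects are
recovered with very large t statistics, and significance spreads beyond the
directly attenuated regions because shortest paths through attenuated edges
lengthen everywhere — so the default simulation demonstrates pipeline
correctness (directions, FDR behaviour, sign recovery), not realistic
power. Second, FDR calibration under the null is exact here
(exchangeable groups) but says nothing about violations such as
heteroscedastic or non-Gaussian metric distributions in real data. The
oracle suite (brute-force Floyd-Warshall and exhaustive triangle
enumeration on hundreds of random graphs) is what establishes that the
metric engine itself is correct independently of the generator.

Problem sizes used by the shipped checks: 200 random oracle graphs at
n ≤ 12; one 47-subject cohort with 100 nulls per subject and network kind
for the small-world survey; 10-seed averages for the degree calibration;
1000 replicates for the type-I calibration; 8 effect-free cohorts for the
FDR null; n = 5000 for the clinical copula and n = 10⁵ for the
partial-correlation oracle.

## Known limitations

* The AAL centroid coordinates shipped with the package are synthetic
  stand-ins placed from gross anatomy (mirrored in x); they support the
  distance kernel and `.node` export but are not measured centroids.
* The generator plants its hub backbone; hub *recovery* by the pipeline is
  therefore a consistency check, not evidence about real hub topology.
* Streamline counts are carried through construction but unused by the
  default edge rule beyond `min_count`; count-weighted networks are out of
  scope.
* No probabilistic tractography variant, no lateralisation subgroup
  analysis, and no voxelwise processing — inputs begin at region-pair
  streamline summaries.

## A minimal run

```{r example, eval = FALSE}
cfg <- read_config()                  # shipped default study conditions
res <- run_pipeline(cfg, seed = 1, out_dir = "fanet_out")
subset(res$comparison, family_id == "global_FA_wei")
head(subset(res$correlation, significant))
res$hubs$control[res$hubs$control$hub, ]
```
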