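---
title: "Occupancy-based decontamination and spatial analysis of replicated eDNA surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy-based decontamination and spatial analysis of replicated eDNA surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaport)
```

## The problem

eDNA metabarcoding of replicated water samples produces species lists that
mix true signal with contamination (field, lab, index-hopping) and
stochastic PCR/sequencing artefacts. The hierarchical survey design this
package targets — stations, several sampling locations per station,
replicate bottles per location, plus field blanks — exists precisely so
that the *pattern of co-occurrence across replicates* can adjudicate
between the two: true eDNA signal tends to recur across bottles at a
location, while artefactual detections scatter as isolated single-bottle
hits.

## The occupancy model with false positives

For one species, let site $j$ (by default a location, with $K_j$ bottle
replicates) be occupied by the species' DNA with probability $\psi$. Given
occupancy, each replicate yields a detection with probability $p_{11}$;
given non-occupancy, a false detection occurs with probability $p_{10}$.
With $d_j$ of $K_j$ replicates positive, the likelihood marginalised over
the latent occupancy state $z_j$ is

$$L = \prod_j \left[ \psi\, p_{11}^{d_j} (1-p_{11})^{K_j - d_j}
  + (1-\psi)\, p_{10}^{d_j} (1-p_{10})^{K_j - d_j} \right],$$

with binomial coefficients omitted (they cancel in the posterior and add a
data-only constant, so log-likelihood values are comparable only within
this package). `marginal_log_likelihood()` implements this directly; the
test suite verifies it against exhaustive enumeration of all $2^J$ latent
configurations to $10^{-12}$.

Retention decisions use the posterior occupancy
$$P(z_j = 1 \mid d_j) = \frac{\psi\, p_{11}^{d_j}(1-p_{11})^{K_j-d_j}}
  {\psi\, p_{11}^{d_j}(1-p_{11})^{K_j-d_j} + (1-\psi)\, p_{10}^{d_j}(1-p_{10})^{K_j-d_j}},$$
which is strictly increasing in $d_j$ whenever $p_{11} > p_{10}$.

### Estimation: penalised likelihood, not pure MLE

`fit_occupancy()` maximises the log-likelihood plus weak Beta penalties,
on an unconstrained scale with $p_{11} = p_{10} + (1-p_{10})\,
\mathrm{logit}^{-1}(\theta_3)$ so that $p_{11} \ge p_{10}$ holds by
construction (the standard identifiability fix against label switching).

The penalties deserve explanation, because the obvious symmetric choice
fails. $\psi$ and $p_{11}$ carry Beta(2, 2) penalties that keep estimates
off the 0/1 boundaries for sparse species. A Beta(2, 2) on $p_{10}$,
however, has its mode at 0.5: for histories that carry *no information*
about $p_{10}$ — a species detected in every replicate of every occupied
site, for instance — the penalty rather than the data decides, and the fit
drifts onto the non-identifiable $p_{11} = p_{10}$ ridge where the
posterior collapses to $\psi$. We therefore place an asymmetric
Beta(2, 20) penalty on $p_{10}$ (mode $\approx 0.05$), the usual weakly
informative encoding of the biological fact that per-replicate false
positives are rare — the assumption that makes this model class usable for
decontamination at all. Both shapes are exposed (`penalty`, `fp_shape2`).

Optimisation is BFGS from a fixed grid of six starting points, so fits are
bit-reproducible. Degenerate histories (no detections; fewer than two
sites; fewer than three total replicates) are flagged non-identifiable;
species whose optimiser fails on every start are routed to an
`unresolved` list and dropped with a report, never silently.

### The retention rule

`occupancy_filter()` keeps a (species, site) detection when its posterior
occupancy reaches `tau`, and keeps a species in the study when it survives
at one or more sites. The default `tau = 0.8` asks for fourfold posterior
odds in favour of occupancy; a `min_detections` fallback (a minimum
replicate count per site) is available as an alternative rule, since
thresholding could also plausibly be done on replicate counts directly. In
the default case-study scenario, single-bottle single-location species
fall well below `tau = 0.8` (posterior $\approx$ 0.35–0.55) while species
with two or more positive bottles at a site sit above 0.98 — exactly the
qualitative behaviour that motivates replicate-based decontamination.

### Siting and replicate units

Sites are locations and replicates are bottles by default
(`site_level = "location"`, so $K = 3$ under the default design, $J = 28$
sites). Station-level siting is a switch. PCR replicates are recorded in
the design metadata but reads are simulated and analysed per bottle: the
bottle is the replicate unit at which results are reported, and modelling
a third level would require a multi-scale likelihood that is deliberately
out of scope (a documented extension point).

## What the simulator emulates — and what it does not

`simulate_community()`, `simulate_reads()` and `simulate_trawl()` generate
surveys with the statistical structure the analysis assumes:

* latent occupancy $z \sim \mathrm{Bern}(\psi)$ per species × site;
* per-bottle detections with $p_{11}$ / $p_{10}$, every false positive
  logged with its provenance;
* per-sample sequencing depth $\sim$ negative binomial (mean 20 000,
  dispersion 5 by default — overdispersion typical of amplicon
  libraries), allocated to the bottle's detected species by a multinomial
  weighted by log-normal station-level abundance (SD `station_effect_sd`,
  the knob that creates between-station compositional divergence);
* blank contamination as per-species Bernoulli events (rate 0.02) with
  geometric read counts (mean 10);
* trawl catches $\sim$ Poisson(catchability × effort × station
  abundance × occupied fraction).

The default assemblage (`case_study_species()`) mixes 60 resident species
($\psi = 0.5$, $p_{11} = 0.75$, $p_{10} = 0.03$, catchability 0.4) with a
40-species sporadic tail ($\psi = 0.06$, $p_{11} = 0.35$, $p_{10} = 0.01$,
tenth the abundance, catchability 0.05) — the long tail of transients and
trace signal whose adjudication is the point of the method. Those values
were chosen once as a realistic harbour fish community under this design;
they are arguments, not constants.

A single seed drives everything, split deterministically into per-stage
substreams so each stage is independently reproducible; identical seeds
give byte-identical outputs, which the test suite checks end-to-end.

Deliberately *not* modelled: sequence-level artefacts (chimeras,
misassignment — the package consumes assigned tables), eDNA transport and
decay, tag jumping between samples, and PCR-replicate-level variation.
Passing recovery tests on these simulations therefore demonstrates
correctness of the estimators under the stated model, not robustness to
taxonomic misassignment or transport.

## Completeness and spatial structure

Sampling completeness uses the incidence framework, since survey claims
are about detection saturation across bottles/locations/stations, not
abundances: sample coverage
$\hat C = 1 - (Q_1/U)\,[(T-1)Q_1 / ((T-1)Q_1 + 2Q_2)]$, bias-corrected
Chao2, and combinatorial rarefaction
$S(t) = S_{obs} - \sum_i \binom{T-Y_i}{t}/\binom{T}{t}$ with Chao2-based
extrapolation. Combinatorial terms are computed in log space
(`lchoose`), exact for $T$ into the hundreds. "Units needed to saturate"
is not uniquely defined, so `units_to_saturation()` reports two
operationalisations side by side — smallest $t$ with $\hat C(t) \ge 0.95$,
and smallest $t$ with $S(t) \ge 0.95 \times$ Chao2 — without claiming they
coincide.

Community structure uses the eDNA index (column proportions, then each
taxon scaled to its own maximum — comparable across samples within a
taxon, meaningless across taxa), Jaccard on presence/absence by default
(post-filter results are detection-based; Bray–Curtis on the index by
flag), PCoA via Gower double-centering with negative eigenvalues dropped
and their mass reported (no Lingoes/Cailliez correction — simpler and
auditable), and a nested PERMANOVA: sequential (Type-I) sums of squares
via hat-matrix traces on the Gower-centred matrix, station entered before
location-within-station to match the hierarchy. On Euclidean distances
this partition reproduces classical ANOVA exactly (the McArdle–Anderson
identity, tested to $10^{-10}$, and cross-checked against
`vegan::adonis2`). Permutation p-values use free permutation for the
station term and within-station permutation for the nested term, with
$p = (b+1)/(B+1)$ and a seeded generator.

## Numerical and interface choices

* Read tables are integer matrices with unique taxon/sample labels;
  readers reject negatives, non-integers and duplicate columns with the
  offending label, and all writers round-trip exactly.
* Unbalanced designs (a lost bottle) are kept as per-site $K_j$, never
  imputed; `validate_metadata()` reports irregularities rather than
  failing.
* Decontamination filters never create reads, conserve removed-read
  totals in their audit report, and never renormalise — downstream stages
  decide about proportions.
* Blank handling defaults to max-blank subtraction (each taxon's maximum
  blank count subtracted from every field sample, floored at zero), the
  conservative and auditable choice; blank-prevalence removal is the
  alternative.
* The detection threshold after decontamination defaults to
  `min_reads = 1` and is exposed, since reasonable pipelines differ here.
* Report numbers are rounded only at serialisation (one decimal for
  percentages), never internally.

## Problem sizes

The test suite validates at the scale the design targets: likelihood
enumeration up to 12 sites; parameter recovery on 200 species × 28 sites
× 3 replicates (median absolute errors ≈ 0.06 / 0.05 / 0.015 for $\psi$ /
$p_{11}$ / $p_{10}$, against a 0.1 criterion); rarefaction against 10 000
Monte-Carlo subsamples; PERMANOVA size under the null over 1 000 simulated
datasets at $n = 8$; and byte-identical end-to-end reruns of the full
84-sample pipeline.

## Known limitations

* Per-species independent fits: no pooling of $p_{10}$ across species,
  although contamination processes are plausibly shared. Hierarchical
  pooling is the natural extension.
* Single-level occupancy: bottle-within-location-within-station is
  collapsed to one site level per analysis.
* No abundance-based (Hill number) diversity profiles and no dispersion
  test alongside PERMANOVA; significant terms can reflect location or
  spread.
* Species matching between gears is exact-string (plus a user synonym
  table); no fuzzy nomenclature resolution.
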