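# ednaport

Analysis tools for hierarchically replicated environmental DNA (eDNA)
metabarcoding surveys paired with conventional trawl sampling, built around
the survey design used in port and harbour biomonitoring: a set of trawl
stations, several water-sampling locations per station, replicate 1 L
bottles per location, and one field blank per station.

The package is aimed at researchers and monitoring programs who have a
taxa-by-sample read table, sample metadata describing the replicate
hierarchy, and (optionally) paired trawl catches, and who want to

* separate true eDNA detections from contamination and PCR/sequencing
  noise using the co-occurrence of detections across replicates,
* quantify how complete their sampling was at each level of the hierarchy,
* characterise spatial structure of the eDNA community, and
* compare eDNA species inventories against paired conventional gear.

A fully seeded simulator generates surveys with known ground truth (latent
occupancy, imperfect detection, false positives, read-depth noise, blank
contamination, paired trawl catchability), so every estimator in the
package can be validated by parameter recovery.

## The model at the core

The decontamination statistic is a two-state site-occupancy model with
false positives, fitted per species to its replicate detection history.
Site *j* (a sampling location with *K_j* replicate bottles) is occupied
with probability ψ. Each replicate detects the species with probability
p11 if the site is occupied and with false-positive probability p10 if it
is not. With d_j detections at site j, the marginal likelihood is

    L(ψ, p11, p10) = Π_j [ ψ p11^{d_j} (1−p11)^{K_j−d_j}
                         + (1−ψ) p10^{d_j} (1−p10)^{K_j−d_j} ]

(binomial coefficients omitted; they cancel in the posterior). Parameters
are estimated by penalised maximum likelihood with p11 ≥ p10 enforced by
the parameterisation, and each (species, site) detection is retained only
when the posterior probability of occupancy,

    P(z_j = 1 | d_j) = ψ p11^{d_j}(1−p11)^{K_j−d_j} / L_j,

reaches a threshold τ (default 0.8). In practice this removes species
whose detections are confined to a single bottle while keeping species
detected in several replicates or at several sites.

Around this core the package provides blank-based decontamination
(max-blank subtraction, blank prevalence), incidence-based sample coverage,
Chao2 richness and rarefaction/extrapolation at bottle, location and
station level, the eDNA index (within-sample proportions scaled per taxon
to its maximum), Jaccard and Bray–Curtis distances, principal coordinates
analysis, nested PERMANOVA (stations, then locations within stations, with
restricted permutations), and eDNA-vs-trawl overlap/Venn/heat-table
reporting plus reference-database audit tables.

## Worked example

```r
library(ednaport)

## The case-study design: 7 stations x 4 locations x 3 bottles + 7 blanks
d <- build_design(7, 4, 3, 1)
d
#> Survey design: 7 stations x 4 locations x 3 bottles (84 field samples, 7 blanks)

## Fit the occupancy model to one species' detection history:
## detections in 2, 3 and 1 of 3 bottles at three locations, absent at 25
f <- fit_occupancy(c(2L, 3L, 1L, rep(0L, 25)), K = 3)
f
#> Occupancy fit (28 sites): psi=0.115 p11=0.674 p10=0.017 logL=-15.42
round(posterior_occupancy(f$psi, f$p11, f$p10, d = 1:3, K = 3), 4)
#> [1] 0.3581 0.9850 0.9999
```

The species is estimated to occupy ~11% of locations with a high
per-bottle detection rate and a small false-positive rate; a single-bottle
detection (d = 1) is ambiguous (posterior 0.36, removed at τ = 0.8) while
two or three detections are near-certain and retained.

The full pipeline on a simulated survey at the same scale:

```r
out <- run_pipeline(seed = 1, n_perm = 199)
out$report$occupancy_impact
#> $species_total_before   91
#> $species_total_after    73
#> $species_removed        18
out$venn$percent_trawl_recovered
#> [1] 100
out$permanova
#>       term df        SS        R2        F     p
#> 1  station  6  4.807126 0.1866071 13.67007 0.005
#> 2 location 21 17.671456 0.6859856 14.35785 0.005
#> 3 Residual 56  3.282098 0.1274073       NA    NA
#> 4    Total 83 25.760680 1.0000000       NA    NA
```

Of 91 species with at least one post-blank-filter detection, the occupancy
filter removes 18 (the simulated sporadic tail), eDNA recovers every
trawl-caught species, and station plus location-within-station structure
explains ~87% of community variation, with the residual being
between-bottle noise.

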