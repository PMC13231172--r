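# decodex

Post-simulation analysis of hydrogen bonding and π-stacking in the ribosome
decoding-center neighborhood: the A-site codon:anticodon duplex, the CAR
interaction surface (C1054 and A1196 of the small-subunit rRNA plus R146 of
ribosomal protein Rps3), and the mRNA +1 codon.

The package is for structural bioinformaticians who have (or simulate)
trajectory frames of this neighborhood and want the full analysis chain the
field applies to it, as tested, reusable R functions rather than one-off
scripts: geometric interaction calling per frame, per-simulation
interaction fingerprints over a labeled contact catalogue, nonparametric
factorial statistics, φ-coefficient covariation, and correlation-distance
embeddings.  A synthetic-data module generates every input with known
ground truth, so the pipeline runs and is testable without any
molecular-dynamics output or download.

## What it computes

**Geometric observables, per trajectory frame**

- *Stacking*: the center-of-geometry (COG) distance between ring systems,
  with the purine minimum-ring rule
  d(A, B) = min over ring pairs of ‖COG(ringᵢᴬ) − COG(ringⱼᴮ)‖; frames with
  d ≤ 4.5 Å are stacked.  The A:R contact uses the arginine guanidinium
  group (π–cation stacking).
- *Hydrogen bonds*: present iff the heavy donor–acceptor distance ≤ 3.5 Å
  and the donor–hydrogen–acceptor angle ≥ 135°, over candidate triples
  enumerated from an editable donor/acceptor edge catalogue.

**Reductions**: a 26-contact catalogue (a–z: 10 stacks + 16 H-bond
families) is evaluated per simulation and reduced, after equilibration
trimming, to mean-interaction fingerprints (a `SummarizedExperiment`,
contacts × simulations) and to site-level H-bond strengths (mean H-bond
frequency of each site's mRNA nucleotides with their nearest
complementary-surface residues).

**Inference**

- Aligned rank transform (ART) factorial ANOVA — align per effect, midrank,
  full-factorial ANOVA on ranks, read off the target effect — with
  Bonferroni correction over the 3 main effects (A-site N1N2, wobble
  decoding geometry, +1 codon) and 3 two-way interactions; Shapiro–Wilk
  screening of classical residuals motivates the rank-based route.
- φ coefficients between binarized frame events,
  φ = (n₁₁n₀₀ − n₁₀n₀₁)/√(n₁·n₀·n·₁n·₀) ≡ Pearson r on 0/1 data, assembled
  into the 26 × 26 covariation matrix.
- Stratified Pearson correlation between A-site and CAR-site strengths
  (per A-site codon × +1 codon stratum, Bonferroni across strata).
- Correlation distance 1 − r between interaction vectors, embedded in 2-D
  by UMAP (precomputed metric, n_neighbors = 15, min_dist = 0.1, seeded)
  and classical MDS, plus hierarchical clustering.

## Worked example

Generate one synthetic simulation of the neighborhood (A-site codon UGU
decoded with G:U wobble geometry, +1 codon GCU; CAR contacts `t`, `u` given
elevated occupancy 0.8, everything else 0.5), then evaluate it:

```r
library(decodex)

cat26 <- defaultCatalogue()
cond  <- list(a_site_n1n2 = "UG", wobble = "GU_wobble", plus1_codon = "GCU")
occ   <- setNames(rep(0.5, 26), letters[1:26]); occ[c("t", "u")] <- 0.8
traj  <- genNeighborhoodTrajectory(cond, occ, nFrames = 2000, seed = 42)

s <- trimEquilibration(evaluateContact(traj, cat26[["g"]]),
                       dropFirstN = 200)
meanInteraction(s)                     # mean COG of stack g (aN2:aN3), Å
#> 4.471
meanInteraction(binarizeSeries(s))     # stacked-fraction of frames
#> 0.49
siteHbondStrength(traj, "CAR_site", trim = list(keepFinalFraction = 2/3))
#> 0.56
siteHbondStrength(traj, "A_site",  trim = list(keepFinalFraction = 2/3))
#> 0.501
```

The stack `g` was planned at occupancy 0.5 and measures 0.49; its mean COG
(4.47 Å) sits between the stacked (3.4 Å) and unstacked (5.5 Å) generator
geometries.  The CAR-site strength (0.56) exceeds the A-site strength
(0.50) because two of its contacts were boosted to 0.8.  The coupling
generator round-trips through the φ estimator the same way:

```r
X <- genCoupledBinaries(20000, c(g = 0.5, t = 0.5),
                        data.frame(a = "g", b = "t", phi = 0.5), seed = 1)
phiCoefficient(X[, "g"], X[, "t"])
#> 0.495
```

The config-driven pipeline runs all stages in order and writes CSV tables
plus a run log (`?runPipeline`); `inst/scripts/decodex.R` wraps it for the
shell (`Rscript decodex.R run -c config.yaml`).

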