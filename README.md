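# jaykin

Deconstructing fine-scale isolation-by-distance in pedigreed,
continuously monitored populations.

Isolation-by-distance — genetic relatedness declining with the
geographic distance between individuals — is ubiquitous, but few systems
allow it to be *explained*: derived quantitatively from directly
measured dispersal, pedigree structure and immigration. `jaykin`
implements that deconstruction for territorial bird populations with
female-biased natal dispersal (males ZZ, females ZW and hemizygous for
the Z), and ships a spatially explicit synthetic-population generator so
the entire pipeline is testable offline.

## What it computes

- **Genomic identity-by-descent.** The genome-wide method-of-moments
  estimator (IBS counts + allele frequencies → P(IBD=0/1/2),
  π̂ = P(IBD=1)/2 + P(IBD=2)), in bounded and unbiased variants, plus a
  hemizygosity-aware Z-linked estimator
  θ̂ = Σ(yᵢ−p)(yⱼ−p) / Σ pq on dosage fractions, scaled to the ZW
  coefficient-of-relationship convention and deliberately unbounded.
- **Pedigree relatedness.** Recursive kinship for autosomal and ZW
  inheritance (written natively for ZW: males carry two Z copies,
  females one paternal Z), coefficients of relationship, and closest
  relationship classification up to fourth cousins (PO, FS, HS, G1, N1,
  DC1, C1, … C4) by minimal path length with expected-r tie-breaks.
- **Decay statistics.** Loess IBD-by-distance curves; the half-decay
  distance δ (distance at which the fitted curve drops halfway from its
  short-range maximum to the overall mean) with BCa bootstrap intervals;
  Mantel correlograms in fixed 500 m bins with permutation p-values and
  progressive Holm correction; quantile-binned means; PC-vs-northing
  Spearman correlations.
- **Dispersal simulations.** Forward simulation of the distance between
  relatives (full-sibs up to second cousins) from sex-specific dispersal
  curves alone, including the fixed-ancestor-sex first-cousin design,
  with KS/Wilcoxon comparisons against observed distributions.
- **Spatial pedigree coalescent.** Backward-in-time prediction of
  expected IBD at distance d,
  Ẑ = Σ_g [Π_{k<g} (1−M)² (1 − Pp(d_k) − Pf(d_k) − Ph(d_k))] ×
  [Pp(d_g)E(Zp) + Pf(d_g)E(Zf) + Ph(d_g)E(Zh) + 2M(1−M)E(Zr) + M²E(Zm)],
  with a model ladder M0–M4 (sex-specific dispersal, coalescence,
  immigration, and isolation-by-distance in immigrants), R² scoring and
  k-fold cross-validation.

## Worked example

A fully synthetic study at the emulated system's scale (14 generations,
100 breeding pairs per generation, immigration 0.197/0.345, female
median dispersal ≈ 2.35× male), genotyping the last three generations:

```r
library(jaykin)

cfg <- study_config(n_generations = 14,
                    n_breeding_pairs_per_generation = 100,
                    n_autosomal_loci = 3000, n_z_loci = 250,
                    rng_seed = 42)
study <- simulate_study(cfg)

med <- tapply(study$dispersal$distance_m, study$dispersal$sex, median)
ids <- study$pedigree$id[study$pedigree$generation >= 11]
pairs <- build_pair_table(study, ids = ids)

co  <- paste0(pmin(pairs$sex_a, pairs$sex_b), pmax(pairs$sex_a, pairs$sex_b))
dmm <- bootstrap_delta(pairs[co == "MM", ], "ibd_auto", B = 200, seed = 1)
dff <- bootstrap_delta(pairs[co == "FF", ], "ibd_auto", B = 200, seed = 1)

curves <- dispersal_curves(study$dispersal$distance_m[study$dispersal$sex == "M"],
                           study$dispersal$distance_m[study$dispersal$sex == "F"])
fit <- fit_coalescent_model(pairs, NULL, curves, "M4",
                            n_sims_per_bin = 400, n_bins = 15, seed = 2)
```

Output on this seed (a few minutes on one CPU):

```
male median dispersal:   427 m
female median dispersal: 858 m
pairs: 179700   mean autosomal IBD (unbiased): 0.0033
delta (MM): 678 m   95% CI [649, 694]
delta (FF): 840 m  95% CI [794, 925]
M4 R^2:  MM 0.81   MF 0.77   FF 0.77
```

Read: realized dispersal medians are habitat-truncated versions of the
configured kernels (female ≈ 2× male); relatedness decays faster with
distance among males (δ_MM < δ_FF, non-overlapping CIs) because males
settle nearer their natal territory; and the M4 coalescent —
parameterized only by the pedigree's pair-class probabilities, the
dispersal curves, immigration rates and immigrant relatedness —
reproduces ~80% of the variance in the male-male IBD-by-distance curve.

## Command line

```sh
Rscript -e 'jaykin::jaykin_cli()' simulate    --seed 7 --out study/
Rscript -e 'jaykin::jaykin_cli()' relatedness --study study/ --out pairs.tsv
Rscript -e 'jaykin::jaykin_cli()' ibd-decay   --pairs pairs.tsv --sexes MM \
    --ibd ibd_auto --bootstrap 1000 --seed 7 --out delta.json
Rscript -e 'jaykin::jaykin_cli()' dispersal-sim --dispersal study/dispersal.tsv \
    --relationship C1 --focal MM --ancestors MM --reps 10000 --seed 7 --out sim.tsv
Rscript -e 'jaykin::jaykin_cli()' coalescent  --pairs pairs.tsv \
    --dispersal study/dispersal.tsv --model M4 --bins 15 --sims 1000 \
    --seed 7 --out fit.json
Rscript -e 'jaykin::jaykin_cli()' report      --pairs pairs.tsv --out report.json
```

Every run logs its seed and version; outputs are deterministic given the
seed.

## Layout

- `R/` — implementation (pedigree/kinship, synthetic generator,
  relatedness, decay statistics, dispersal sim, coalescent, IO + CLI)
- `tests/testthat/` — unit, property and acceptance suites
  (`test-acceptance.R` holds the property-based acceptance criteria)
- `vignettes/methods.Rmd` — the models, assumptions, numerical choices
  and limitations
- `scripts/acceptance.R` — the acceptance report
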