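---
title: "Deconstructing fine-scale isolation-by-distance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconstructing fine-scale isolation-by-distance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Isolation-by-distance — the decline of genetic relatedness between
individuals with the geographic distance separating them — is among the
most widely observed patterns in population genetics, yet it is rarely
*deconstructed*: shown to follow quantitatively from directly measured
dispersal, pedigree structure and immigration. `jaykin` implements that
deconstruction as a tested pipeline for continuously monitored, pedigreed
bird populations (the motivating system is a non-migratory, cooperatively
breeding scrub-jay population on a roughly 10 km habitat with strongly
female-biased natal dispersal: median natal dispersal near 488 m in males
and 1,149 m in females, and per-generation immigrant fractions of about
0.20 for males and 0.35 for females). All stages run end-to-end on a
synthetic population generator, so nothing requires external data.

The pipeline has five parts:

1. **Synthetic population generator** — a spatially explicit,
   multi-generation pedigree with sex-specific dispersal and immigration,
   plus genotypes gene-dropped through the pedigree (autosomal and
   Z-linked).
2. **Relatedness estimation** — genomic identity-by-descent (IBD)
   estimators for autosomes and the Z, and recursive pedigree kinship for
   autosomal and ZW inheritance, joined into a per-pair record table.
3. **Decay statistics** — loess IBD-by-distance curves, the half-decay
   distance δ with BCa bootstrap intervals, Mantel correlograms in fixed
   distance bins, quantile-binned means, and PC-versus-northing
   correlations.
4. **Dispersal simulations** — forward simulation of the geographic
   distance between relatives using only the sex-specific dispersal
   curves.
5. **Spatial pedigree coalescent** — a backward-in-time model predicting
   expected IBD as a function of present-day pair distance, with a model
   ladder M0–M4 of increasing sex-specificity, evaluated by R².

# Models and estimators

## Autosomal genomic IBD

For a pair of individuals, counts of loci identical-in-state for 0, 1 or
2 alleles are combined with population allele frequencies through the
classic genome-wide method of moments: the IBS-class expectations
conditional on sharing 0, 1 or 2 alleles identical-by-descent are summed
over loci, and P(IBD=0), P(IBD=1), P(IBD=2) are solved in sequence
(opposite homozygotes can only arise under IBD 0, and the three
probabilities sum to one by construction). The IBD proportion is
π̂ = P(IBD=1)/2 + P(IBD=2). The *bounded* variant clips the triple to the
probability simplex and renormalizes (the convention of the standard
`--genome` implementation); the *unbiased* variant reports the raw
solution, which is negative for about half of truly unrelated pairs.

Two numerical points matter. First, frequencies are treated as known;
they default to the full-sample frequencies but an external table (for
example founder frequencies in simulations) can be supplied. Small-sample
bias-correction factors are deliberately omitted. Second, the simplex
truncation is *not* innocuous on small panels: because P(IBD=1) centres
on zero for unrelated pairs, clipping shifts bounded estimates upward on
average by an amount that grows as the panel shrinks (about 0.02 at
5,000–8,000 loci in our tests, several-fold larger at 300 loci). This is
exactly why the Z chromosome, with its much smaller panel, is analysed
with the **unbounded** estimator throughout. A second, smaller caveat:
the IBS-class expectations assume Hardy–Weinberg proportions given the
frequency reference. In a closed, drifted population referenced to its
founder frequencies, autozygosity inflates homozygote (hence
opposite-homozygote) counts and depresses π̂ by a few thousandths — so
the estimator-correctness oracle runs on replicated non-inbred families,
while whole-population checks allow for this bias.

## Z-linked genomic IBD with hemizygous females

In birds females are ZW and carry a single Z. Genotypes are stored as
alt-allele counts with per-individual ploidy (males 0/1/2, females 0/1).
Writing the dosage fraction \(y_i = x_i / n_i\) (with \(n_i\) the copy
number), \(\mathrm{E}[(y_i - p)(y_j - p)] = \phi_{ij}\, p q\), where
\(\phi_{ij}\) is the Z kinship coefficient — the probability that one
allele drawn from each individual is IBD. The estimator

\[\hat\theta_{ij} = \frac{\sum_l (y_{il} - p_l)(y_{jl} - p_l)}{\sum_l p_l q_l}\]

is therefore unbiased for \(\phi_{ij}\) under known frequencies. To
report a *proportion of the genome shared*, \(\hat\theta\) is scaled by 2
for any pair containing a male and by 1 for female–female pairs. This
scaling makes the estimator's expectation equal the ZW coefficient of
relationship convention used throughout the package: a father and son
share half the son's Z (0.5); a father–daughter or mother–son pair shares
the hemizygous individual's entire Z (1); a mother–daughter pair shares
nothing (the daughter's Z is paternal); two females with identical Z
haplotypes score 1. Estimates are left unbounded — clipping to [0, 1]
would bias the small Z panel upward.

No published closed form was available to copy for the hemizygous case,
so this derivation is validated by an independent oracle instead: exact enumeration of allele-transmission
paths on canonical pedigrees, and gene-dropped populations where the
truth is the pedigree.

## Pedigree kinship, autosomal and ZW

Autosomal kinship uses the standard recursive tabular method over a
generation-ordered pedigree. The ZW recursion is written natively rather
than through the X-linked sex-swap trick: males carry two Z copies (one
from each parent), females carry a single paternal Z, so for a female
\(i\), \(\phi(i, j) = \phi(\mathrm{father}_i, j)\) and
\(\phi(i, i) = 1\); for a male, the autosomal-style average applies and
founder self-kinship is 1/2. The coefficient of relationship is twice the
kinship in both systems. Expected IBD values for the coalescent
(`expected_relationship_ibd()`) are computed from this recursion on
canonical pedigrees, with two averaging conventions: mixed-sex
parent–offspring averages father–daughter and mother–son, and
half-siblings average the paternal and maternal variants.

## Closest relationship classification

The closest relationship of a pair is the configuration minimizing the
total path length (meioses) to a common ancestor, ties broken in favour
of the larger expected coefficient of relationship; classes range from
parent–offspring to fourth cousins, including half- and once-removed
variants and double first cousins (detected as four distinct common
ancestors at grandparental depth). Pairs whose minimal configuration has
no enumerated code (for example deep half-relationships) are reported as
unknown; only parent–offspring, full-sibling and half-sibling classes
feed the coalescent. The classifier is implemented as a depth-limited
ancestor-table self-join and validated against hand-enumerated classes on
a four-generation pedigree, including a pair that is simultaneously a
first and a second cousin.

## δ, the half-decay distance

A loess curve (span 0.75, degree 2 by default — the source analysis does
not state its smoothing parameters) is fitted to IBD against pairwise
distance and evaluated on a fine grid. The curve's "maximum" is
operationalized as the fitted value at the smallest observed distance,
which is robust to mid-range wiggles. If that value does not exceed the
overall pair mean there is no isolation-by-distance signal and δ is
undefined (a distinguished result, not an error). Otherwise δ is the
smallest grid distance at which the fit drops to or below the midpoint
between the curve maximum and the mean, linearly interpolated. δ is
invariant to affine rescaling of the IBD axis.

Uncertainty comes from resampling *pairs* with replacement (accepting the
induced dependence between pairs sharing an individual, as in the source
design), refitting, and recomputing δ; intervals are bias-corrected and
accelerated. The acceleration constant is estimated by a delete-group
jackknife (50 groups by default) because a leave-one-pair-out jackknife
is infeasible at 10^5 pairs. Replicates with undefined δ are dropped; if
they exceed 20% the interval is flagged unstable.

## Mantel correlograms

For fixed distance bins (default 250–750 m through 4,750–5,250 m) the
statistic is the correlation, over retained pairs, between the similarity
matrix entries and the bin-membership indicator. Pairs closer than 250 m
(same-territory and self pairs) are excluded entirely. P-values come from
joint row/column permutation of individuals, and multiplicity correction
is progressive Holm from the shortest bin — the ecosystem default behind
the routine the source analysis cites, which states only "corrected
p-values". Bins with fewer than 30 pairs are dropped with a warning. The
implementation is validated against `vegan::mantel.correlog` on a shared
configuration (one sign convention note: vegan reports its statistic so
that positive values mean positive spatial autocorrelation).

## Dispersal simulations between relatives

A relationship's lineage plan fixes the number of dispersal events
(full-siblings 2, aunt/uncle–nibling 3, first cousins 4, second cousins
6). The shared ancestral nest sits at the origin of an *unbounded* plane;
each event displaces its lineage by a distance drawn from the event-sex
curve and a uniform angle. Focal sexes are fixed; ancestor sexes are
randomized by fair coin unless the fixed-ancestor first-cousin design
pins them. Empirical curves are resampled uniformly with replacement — no
kernel smoothing, no heritability of dispersal. The unbounded-plane
assumption weakens for distant relatives; distributions for plans with
six or more events carry a caveat flag. Simulated and observed
distributions are compared by two-sample Kolmogorov–Smirnov and Wilcoxon
rank-sum tests with Bonferroni thresholds.

## The pedigree-parameterized spatial coalescent

For a pair at present-day distance \(d\), two lineages step backward in
time. Each generation both lineages are displaced by a sex-appropriate
dispersal draw and a uniform angle, giving the trajectory
\(d_1, d_2, \dots\) (with \(d_1\) the distance *after* the first backward
step — the formula's indexing is ambiguous on this point and that reading
matches the stated procedure). The expected IBD is

\[\hat Z = \sum_{g=1}^{G} \Big[\prod_{k=1}^{g-1} (1-M)^2
\big(1 - P_p(d_k) - P_f(d_k) - P_h(d_k)\big)\Big] \times
\big[P_p(d_g) E(Z_p) + P_f(d_g) E(Z_f) + P_h(d_g) E(Z_h) +
2M(1-M) E(Z_r) + M^2 E(Z_m)\big]\]

where \(P_p, P_f, P_h\) are the distance-binned probabilities that a pair
is parent–offspring, full-siblings or half-siblings (estimated from the
pedigree as class counts over pair counts per bin; step-function lookup,
clamped beyond the last bin), \(E(Z_\cdot)\) are expected IBD values for
those classes, \(M\) is the immigration probability, and
\(E(Z_r), E(Z_m)\) are mean IBD for immigrant–resident and
immigrant–immigrant pairs. The model ladder: **M0** sex-averages
everything; **M1** adds sex-specific dispersal; **M2** sex-specific
pair-class tables; **M3** sex-specific immigration, replacing \((1-M)^2\)
with \((1-M_{s_1})(1-M_{s_2})\) and \(2M(1-M)\) with
\(M_{s_1}(1-M_{s_2}) + M_{s_2}(1-M_{s_1})\) for the current generation's
lineage sexes (the printed formula is sex-averaged; this is its natural
generalization); **M4** makes the immigrant IBD terms distance-
conditional, capturing isolation-by-distance among immigrants.

Design points made deliberately: the printed additive bracket is
evaluated *as printed* even though class probabilities and immigration
terms can jointly exceed 1 when \(M\) is large (a diagnostic warns);
ancestor sexes are re-randomized every generation after the first
backward step; the generation cap defaults to \(G = 10\) and the test
suite verifies that doubling it changes \(\hat Z\) by less than 10^-4 at
realistic parameter magnitudes. Predictions bin observed distances into
15 quantiles, run replicate simulations per bin seeded from the observed
within-bin distances, and are scored by
\(R^2 = 1 - \sum_i (y_i - \hat Z_i)^2 / \sum_i (y_i - \bar y)^2\) over
bin means — which can be negative when the model underperforms the mean.
Two-fold cross-validation re-estimates every table on the training fold.

# The synthetic world

The generator's defaults state the emulated system: a 4 × 10 km habitat,
14 non-overlapping generations of 150 breeding pairs, immigration 0.197
(males) and 0.345 (females) per recruit with uniform placement, 8,000
autosomal and 277 Z loci with founder frequencies Uniform(0.05, 0.95).
Dispersal uses a leptokurtic stand-in for the empirical curves — a
mixture of a half-normal body (weight 0.7, σ = 540 m) and a log-normal
tail (meanlog = log 1200, sdlog = 1), which has median ≈ 488 m; the
female kernel is the male kernel scaled by 1149/488, pinning the median
ratio at ≈ 2.35. Recruits disperse from the natal nest with a uniform
angle, rejection-resampled to stay inside the habitat (the empirical
curves likewise contain only within-population events). Mates pair by
spatial proximity (each male takes the nearest unpaired female, with a
full-sibling veto whenever a non-sibling candidate remains). Local
pairing is not optional realism: breeders share a territory, and both
the dispersal simulations and the backward coalescent assume that one
generation corresponds to one natal-dispersal step from a single
parental nest. Random habitat-wide pairing would place each offspring's
natal nest at the midpoint of two territories kilometres apart, injecting
spatial diffusion that neither model represents. One departure from
strict monogamy is deliberate: with probability 0.1 an
offspring's sire is a male other than its dam's social mate
(`extra_pair_rate`). Without it, a strictly monogamous
non-overlapping-generation design would contain *no half-siblings*,
leaving \(P_h\) and the HS oracles untestable; 10% stands in for the
re-pairing and extra-pair paternity of real long-term study populations.

What the generator does **not** emulate: overlapping generations and
cooperative breeding groups, territory geometry (coordinates are points),
heritable dispersal, linkage (loci are independent, so no LD pruning is
needed and IBD-segment methods are out of reach), and temporal variation
in immigration. A green test therefore establishes that the estimators
and models are internally consistent on a population satisfying their
assumptions — not that any particular wild population does.

Scale-downs in the test and acceptance suites (stated once, not tuned):
the gene-drop oracle uses the specified 8,000 loci on a 6-generation,
40-pair population; the sex-contrast replicates use 10 generations × 90
pairs × 2,500 loci; the end-to-end coalescent check uses the full
14-generation depth (the backward model integrates over 10 generations,
so the pedigree must be at least that deep) with 100 pairs per
generation, 4,000 loci and 400 simulations per bin; bootstrap coverage
checks run at reduced replicate counts.

One negative result is worth stating: in this synthetic world the model
ladder's advantage shows clearly for male-male comparisons (sex-averaged
dispersal is most wrong for the philopatric sex) but not for
female-female comparisons, where the sex-averaged model's dispersal and
immigration errors nearly cancel and M0 already fits well. The test
suite therefore asserts the ladder direction for MM only.

# Known limitations

- The bounded autosomal estimator inherits the upward truncation bias of
  simplex clipping for near-unrelated pairs; comparisons across panels of
  different sizes should use the unbiased variant (as the Z analysis
  does).
- Mantel correlogram p-values use 999 permutations by default (the source
  used 10,000); raise `n_perm` for publication-grade tails.
- The coalescent treats the printed bracket as exhaustive and mutually
  compatible; orderings of same-generation immigration and coalescence
  are not resolved beyond it.
- δ depends on the loess span near the short-distance boundary; the
  default span 0.75 is a convention, and sensitivity to it is exercised
  (not resolved) in the test suite.
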