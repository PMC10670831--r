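---
title: "Methods: compositional stress-microbiome analysis in gutstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional stress-microbiome analysis in gutstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chronic social stress (weekly regrouping, crowding, restricted feeder space)
activates the HPA axis of growing pigs, depresses feed intake and growth,
and — through the microbiota–gut–brain axis — is expected to reshape the
intestinal microbial community. The analytical difficulty is that 16S
genus-level count tables are *compositional* (only relative information,
row sums fixed by sequencing depth), *sparse* (here ~57% zeros), and
*dominated* by a single genus (a Prevotella-like taxon at ~30% relative
abundance), while the experimental design is small (38 animals, two balanced
groups from 9 litters) and structured (litter, pen, three sampling sites).
`gutstress` packages the full chain from raw counts to biomarker and
susceptibility calls, with every stage testable against synthetic cohorts of
known ground truth.

# Models and procedures

## Preprocessing

1. **Prevalence-threshold search.** For each threshold on a grid (default
   0.05–0.95 by 0.05), genera present in at least that fraction of samples
   *within at least one treatment group* are retained, and the out-of-bag
   misclassification error of a bagged ensemble of depth-limited CART-style
   trees (gini splits, default 500 trees) fitted on relative abundances is
   recorded. The returned threshold minimises OOB error, ties going to the
   smallest threshold. This emulates the published prevalence-interval
   workflow whose internals (split/replicate scheme, tree count) are not
   stated; the contract is the search loop, not the third-party package. No
   CART implementation is guaranteed in the deployment image, so the trees
   are implemented in the package (vectorised split search).
2. **Abundance filter.** Genera with mean relative abundance *strictly
   below* 0.001 are removed; the boundary case is retained, reading the rule
   "lower than" literally.
3. **Dirichlet zero replacement + clr.** For each sample, K (default 128)
   proportion vectors are drawn from Dirichlet(counts + 0.5) and each draw
   is clr-transformed. Zeros receive posterior mass, so no pseudo-count
   enters a log. Point-estimate consumers (PLS-DA, ordination) use the
   element-wise *mean instance*; Welch's *t* uses all K instances and
   reports the mean p over instances ("expected p"). Prior mass 0.5 and
   K = 128 are the cited method's defaults; the study itself states neither.

Filter order is prevalence search first, then abundance filter, matching the
narrative order of the source workflow.

## Diversity

Richness is the number of genera with non-zero count; the *adjusted Shannon
index* is interpreted as Pielou-type evenness H/ln(G_obs) — the cited
reference is not explicit, but reported values of 0.63–0.70 on 69–81
observed genera match evenness, not raw H, which would exceed 3. Alpha
diversity is computed on the *unfiltered* table (reported richness exceeds
the post-filter genus counts, so filtering first would be inconsistent).
Treatment contrasts use a Gaussian mixed model with a litter random
intercept, REML-fitted (via lme4), Wald t with residual df = n − #litters −
1; singular fits fall back to OLS.

PERMANOVA partitions the Gower-centred inner-product matrix of Bray–Curtis
dissimilarities by sequential projection (litter entered first, treatment
tested after), with free permutation of sample labels and the
(1 + b)/(1 + m) p-value convention. The study states neither the restriction
scheme nor the SS type; both choices are logged in the output. vegan's
`adonis2` reproduces the SS and pseudo-F exactly and serves as the
independent oracle in the test-suite.

## PLS-DA, VIP, sequential elimination

PLS1 (single centred 0/1 response) by NIPALS with X-deflation; a two-column
dummy response would give the same discrimination at more cost. Components
are chosen by leave-one-out CV on classification error (threshold 0.5 on the
decentred prediction — groups are near-balanced, so Bayes-optimal
thresholding is unnecessary). VIP_j = sqrt(p · Σ_a SSY_a (w_aj/‖w_a‖)² /
Σ_a SSY_a); the identity Σ VIP² = p is asserted on every fitted model.

The elimination loop drops all genera with VIP < 0.8 each round (cumulative
re-evaluation of survivors), refits with LOO-selected components, and stops
when the candidate round's LOO error *exceeds* the previous round's
("started losing discrimination ability" operationalised), when no genus
falls below the cut, or when fewer than 3 genera would remain; the last
round before the stop is returned. Termination is guaranteed: the retained
set strictly shrinks or a stop fires.

**Known property:** because the stop rule is scored by the same LOO error
used to accept rounds, the *final* LOO error is optimistically biased under
the null (pure-noise simulations give ≈0.23 mean error where chance is 0.5).
The unbiased null quantity is the round-0 error, which the tests assert is
at chance level. This selection bias is inherent to the published procedure,
not an implementation artefact; final classification rates on real data
should be read with that caveat.

## Pathogen susceptibility

The classifier labels an animal susceptible to a pathogen genus at a site
when its relative abundance is at least 2.5× (inclusive, "at least") the
median within its treatment group; an all-zero group median yields undefined
ratios and everyone resistant, with a warning. The 2.5 factor is motivated
by the one-sided normal tail at 2.5 SD (≈0.006).

The Bayesian layer is a Gaussian mixed model (treatment + susceptibility
fixed, litter random intercept) sampled by Gibbs with fully conjugate
updates: coefficients jointly normal; variances inverse-gamma through the
parameter-expansion representation of half-Student-t(3) priors (scale
2.5·sd(y)); fixed effects N(0, (10·sd(y))²). Four chains of 2000 iterations
(half warm-up) by default; split-chain R-hat > 1.1 flags non-convergence
without aborting. Pr0 is the fraction of kept draws above zero. The original
analysis used an off-the-shelf sampler with default priors; the conjugate
Gibbs version is self-contained and testable, and matches OLS in the
weak-prior limit (asserted in the tests).

## Phenotypes

Cortisol AUC is the trapezoid over clock time (07:00–16:00, 9 h span) — the
integration rule is not stated in the source and the "ground" variant is the
transparent default. ADG = weight span / days; FCR = DFI/ADG (undefined at
ADG ≤ 0). Individual DFI apportions each pen's feed total proportionally to
a·w^0.75 + b·ADG (maintenance + growth); the originally cited allocation
method is not described in the source, so this transparent substitute is
used — shares sum to the pen total exactly, and only the a:b ratio matters
within a pen. Contrasts are control − stress (the convention the published
least-squares-means table uses), via the shared mixed-model operation.

# The synthetic cohort generator

The generator *states a world* resembling the study and is not tuned per
test:

* 38 animals, 9 litters (every litter in both arms, group sizes within 1),
  pens of ≤4 within treatment, 3 sites, 60 genera, 20,000 reads/sample
  (depth unstated in the source; 20k is typical of MiSeq genus tables).
* Latent log-abundances: genus baseline ladder + treatment shift for planted
  genera + litter random effect (SD 0.25) + animal noise (SD 0.5), mapped
  through softmax to multinomial probabilities. Planted shifts are expressed
  in units of the total between-animal SD (√(0.25² + 0.5²) ≈ 0.56 log
  units per planted SD).
* The ladder's span is calibrated by bisection until a pilot replicate's
  zero fraction is within ±2 points of the 57% target (other seeds stay
  well within the ±10-point contract band).
* The dominant genus is pinned near a 33% mean share; pathogen genera sit at
  their field-typical shares (Clostridium ~4%, Treponema ~5%, Streptococcus
  ~2%, Campylobacter lower) rather than an arbitrary rare position.
* Planted biomarkers are drawn from the informative top quarter of the
  ladder: real biomarkers are by construction among the genera that survive
  the study's own filters, and a genus observed in 5% of samples cannot
  carry a recoverable effect.
* Susceptible subsets (4 animals per pathogen, drawn independently of
  treatment) get an 8× abundance boost. At this boost and dispersion the
  per-animal classifier operating point is ≈0.92 sensitivity / 0.95
  specificity; the probability that the 4 susceptibles are *exactly* the 4
  top-ranked animals is only ≈0.7 (roughly the 4th power of the per-animal
  rate), so joint-rank statements stronger than that are not attainable in
  this world.
* Phenotypes: control means 1.33 kg/d ADG, 2.79 kg/d DFI, 192.5 cortisol
  AUC, 44.4 lesions; stress effects −0.21, −0.35, +107.13, +59.69 — the
  published least-squares means. Weights are exactly linear in ADG (so the
  growth computation is deterministic given the latent ADG); cortisol
  profiles share a fixed diurnal shape scaled to the target AUC with
  mean-zero point noise.

What the generator does **not** emulate: read-level error, taxonomy
misassignment, Dirichlet-multinomial overdispersion beyond the log-normal
animal noise, site-to-site correlation of the *same* animal beyond shared
litter/treatment effects, and pen-level social network structure. A green
recovery test therefore establishes that the pipeline recovers planted
effects in a well-specified compositional world — not that it is robust to
upstream bioinformatic error.

# Numerical choices

* Dirichlet draws via normalised gammas; underflowed draws are clamped to
  the smallest positive double before the log (relevant only for prior-mass
  cells at extreme sparsity).
* PLS components are capped at rank; weight vectors below 1e−12 norm
  truncate the component sequence.
* Mixed-model Wald df = n − #litters − 1; PERMANOVA p resolution is set by
  the permutation count (999 default; 199 in the replicate calibration
  suites, which only needs resolution at 0.05 — replicate counts are never
  reduced below the stated minimums).
* Gibbs chains in the calibration suite are shortened (2 × 600) — the
  calibration statistic (Pr0 exceedance rate over 200 replicates) is
  insensitive to chain length once mixing is adequate (split R-hat ≈ 1).
* Ties: smallest prevalence threshold, smallest component count, first
  minimum everywhere `which.min` is used.

# Limitations

* The OOB search approximates, not reproduces, the published
  prevalence-interval package; chosen thresholds are data-dependent and not
  comparable across implementations.
* Expected-p Welch aggregation is conservative near the null (measured
  type-I ≈ 0.02–0.03 at nominal 0.05 through the full pipeline) — a known
  property of averaging p-values over Monte-Carlo instances.
* The final-round classification rate of the elimination loop is
  optimistically biased (see above); compare models on the round-0 error or
  external data.
* Real-study results that depend on the deposited sequencing data (specific
  biomarker lists, site-specific classification rates, Pr0 triplets) are
  out of reach of a synthetic world and are deliberately not asserted
  anywhere in the suite.
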