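# gutstress

Compositional analysis of the porcine gut microbiome under chronic social
stress.

`gutstress` is an R package for genus-level 16S studies that ask whether a
social stressor (regrouping, crowding, restricted feeder space) reshapes the
intestinal microbiota of growing pigs, and which genera drive the change. It
re-implements, as tested and reusable components, the full analysis chain of
such a study:

* **Compositional preprocessing** — prevalence-threshold search scored by
  the out-of-bag error of a bagged-tree ensemble, a mean relative-abundance
  filter (`< 0.001` removed), Monte-Carlo Dirichlet zero replacement
  (counts + 0.5 prior), and the centred log-ratio (clr) transform
  `clr_j = ln x_j − mean_k ln x_k`.
* **Diversity** — richness `G_obs`, adjusted Shannon index (evenness
  `H / ln G_obs`), mixed-model treatment contrasts (litter as random
  intercept), Bray–Curtis dissimilarity `Σ|x−y| / Σ(x+y)`, within-group
  dissimilarity means, and PERMANOVA with sequential sums of squares
  (litter first, 999 free permutations, `p = (1+b)/(1+m)`).
* **Biomarker discovery** — PLS-DA (NIPALS PLS1 on the clr mean instance),
  leave-one-out selection of the number of latent components, VIP scores
  (`Σ VIP² = p`), and the sequential elimination loop that drops `VIP < 0.8`
  genera until discrimination starts to degrade; Welch's *t* on every
  Monte-Carlo instance (expected *p*, BH-adjusted) with effect sizes in
  pooled-SD units.
* **Pathogen susceptibility** — an animal is *susceptible* to a pathogen
  genus (Clostridium, Treponema, Streptococcus, Campylobacter by default)
  when its relative abundance is ≥ 2.5× the within-treatment-group median;
  a Gibbs-sampled Bayesian mixed model (treatment + susceptibility fixed,
  litter random, half-t priors on variances) reports posterior sign
  probabilities Pr0.
* **Stress phenotypes** — trapezoidal cortisol AUC over the 07:00–16:00
  diurnal profile, ADG/DFI/FCR with pen-level feed apportioned by metabolic
  weight + gain, skin-lesion totals over six body zones, and Table-1-style
  group contrasts (control − stress).
* **Synthetic cohorts** — a generator that emulates the study design
  (38 animals, 9 litters in both arms, 3 sites, ~60 genera with ~57% zeros
  and a ~30% Prevotella-like dominant, planted enriched/depleted genera,
  heavy-tailed susceptible subpopulations) with the ground truth written
  beside the data, so every stage has a parameter-recovery test.

## Worked example

```r
library(gutstress)

design <- cohort_design(seed = 42)          # 38 pigs, 9 litters, 3 sites
truth  <- planted_truth(design)             # 5 planted biomarkers at 1.5 SD
study  <- simulate_cohort(design, truth)

tab <- study$tables$feces
j   <- join_metadata(tab, study$metadata)

pp <- preprocess_site(tab, j$treatment, grid = seq(0.2, 0.8, 0.2),
                      n_trees = 60, K = 32, seed = 42)
bm <- biomarker_discovery(pp$ensemble, j$treatment)
head(bm$report[, c("genus", "vip", "effect_sd", "direction", "p", "q")], 5)
#>   genus  vip effect_sd direction        p        q
#> 1   g01 1.90      1.63  enriched 1.44e-05 8.64e-05
#> 2   g03 1.85      1.86  enriched 1.87e-06 1.69e-05
#> 3   g09 1.79      2.01  enriched 7.43e-07 1.34e-05
#> 4   g07 1.50     -1.51  depleted 7.45e-05 3.35e-04
#> 5   g11 1.45     -1.17  depleted 2.82e-03 1.01e-02
bm$classification_rate
#> [1] 0.9736842
sort(c(truth$enriched, truth$depleted))     # the planted ground truth
#> [1] "g01" "g03" "g07" "g09" "g11"
```

The five genera the elimination loop retains with the highest VIPs are
exactly the five planted ones; the final model classifies 97.4% of animals
correctly in leave-one-out CV, and the signed effect sizes (clr difference
in pooled-SD units) recover the planted ±1.5 SD shifts.

```r
dv <- diversity_report(tab, study$metadata, n_perm = 999, seed = 42)
dv$permanova
#>        term df    SS pseudo_F     p
#> 1    litter  8 0.423     1.09 0.318
#> 2 treatment  1 0.416     8.61 0.001
#> 3  residual 28 1.354       NA    NA
#> 4     total 37 2.193       NA    NA
round(dv$within_group_bc, 3)
#>  stress control
#>   0.291   0.306
```

The planted community shift is detected by PERMANOVA (treatment *p* = 0.001
after litter), and the within-group Bray–Curtis means fall in the ~0.26–0.40
range typical of real porcine genus tables.

## Command line

```sh
exec/gutstress simulate  --seed 1 --out study/           # counts + truth.json
exec/gutstress diversity --in study/ --out study/ --perms 999
exec/gutstress biomarkers --in study/ --out study/ --site feces
exec/gutstress resistance --in study/ --out study/ --factor 2.5
exec/gutstress phenotypes --in study/ --out study/
```

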