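# brantmix

Individual ("frailty") heterogeneity in the demography of long-lived geese,
and what it means for harvest.  `brantmix` implements, as a tested R package,
the two halves of that analysis for colony mark–recapture data of the kind
collected on female Pacific black brant:

1. **A multievent (hidden-Markov) capture–mark–recapture model** with a
   two-class finite mixture ("high" / "low" quality) in first-year survival,
   recruitment and detection.  Birds are marked as goslings (HY) or as adult
   breeders (ASY), are only ever re-encountered as breeders, and their quality
   class is never observed — it is a hidden state estimated through
   year-specific initial-class probabilities.  The package provides the exact
   conditional likelihood (scaled forward algorithm over a nine-state chain),
   maximum-likelihood fitting with random multistarts and an analytic adjoint
   gradient, QAIC model ranking under an overdispersion coefficient, and
   U-CARE-style goodness-of-fit components (TEST3.SR, TEST3.SM, TEST2.CT,
   TEST2.CL) with directional z statistics and ĉ estimation.

2. **A six-state two-quality projection matrix** (gosling, prebreeder,
   breeder × quality class, post-breeding census) with quality inheritance
   `d`, used to compute growth rates λ, stable structures `w`, reproductive
   values `v`, and the harvest-compensation index

   *b* = (Σ wᵢvᵢhᵢ / Σ wᵢvᵢ) / (Σ wᵢhᵢ),

   the ratio of reproductive-value-weighted to unweighted harvest proportion.
   Harvest scenarios fix relative vulnerabilities (quality ratio,
   prebreeder/breeder ratio) and compare three growth-rate responses:
   uniform λ(0)(1−h), the sensitivity approximation λ(0)(1−b·h), and the
   dominant eigenvalue of the harvested matrix.

A synthetic-data module simulates encounter histories from the same
generative model, so every stage — likelihood, fitting, goodness-of-fit,
model ranking — is testable without the field data.

## Worked example

```r
library(brantmix)

## simulate a colony, fit the generating model, rank against a simpler one
fx  <- make_fixture("paper_like", seed = 1, n_HY = 1500, n_ASY = 1000)
fit <- fit_model(fx$histories, fx$spec, n_starts = 10, seed = 1)
mixture_estimates(fit)[c("phiA", "a_A", "a_B", "phiJ_gap")]

## goodness of fit and overdispersion
print(gof_tests(fx$histories))

## the matrix-model pipeline: variant selection, calibration, tables
rt <- reproduce_tables()
rt$table1
rt$table2
```

The matrix pipeline prints (abridged):

```
  inheritance clutch_high clutch_low lambda  GOS_A  PB_A  BR_A  GOS_B  PB_B  BR_B
1         0.8           4          4  1.058  0.172 0.249 0.291  0.047 0.099 0.142
2         0.5           4          4  1.044  0.134 0.191 0.222  0.075 0.157 0.222
3         0.8           5          3  1.089  0.199 0.298 0.353  0.023 0.051 0.076

  scenario ratio_quality ratio_stage     b lambda0
1        1           0.5           2 0.816   1.058
2        2           0.5           2 0.787   1.089
3        3           0.3           3 0.635   1.089
```

Row 1 of the first table anchors the calibration: the egg-to-census fecundity
multiplier `s0` (here 0.242, `pb_adult` prebreeder-survival variant) is chosen
so the 0.8-inheritance, equal-clutch matrix grows at λ = 1.058.  The other
rows are then predictions: λ falls to 1.044 when quality is not inherited
(and the breeder reproductive values equalise at 0.222), and rises to 1.089
when high-quality females lay larger clutches.  The second table shows the
compensation index of the three reference harvest scenarios: concentrating
harvest on low-quality birds and prebreeders (scenario 3) drives *b* down to
0.64, meaning a 10% overall harvest costs only about 6.4% of growth — the
harvested matrix itself gives λ = 1.009 there, 0.028 above the uniform-harvest
response of 0.981.

A thin command line sits over the same functions:

```sh
Rscript inst/scripts/brantmix.R simulate --preset tiny --seed 1 --out out/
Rscript inst/scripts/brantmix.R reproduce-tables --out out/
```

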