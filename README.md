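# mtleo

Comparative modelling of mammalian maximum lifespan from mitochondrial
metabolism and the amino-acid composition of the mtDNA-encoded membrane
proteins.

## The science

The rate-of-living hypothesis — that lifetime energy expenditure
`LEE = MLS × msBMR` is roughly constant — explains the mammal-wide
inverse trend between lifespan and mass-specific basal metabolic rate,
but fails within orders (rodents most famously: the naked mole-rat lives
~7× longer than a similar-sized mouse) and leaves LEE widely dispersed.

`mtleo` implements a framework that replaces msBMR with a
per-mitochondrion metabolic rate. With `B = ln(BMR/a)/ln(M)` the exact
per-species allometric exponent (so `a·M^B = BMR` identically),

```
mtMR(α) = a · M^((B−1)/α),        α ≥ 1
mtLEO(α) = MLS × mtMR(α)          (equals LEE at α = 1)
```

The free parameter α reshapes the mass-dependence of the metabolic rate;
it is chosen by minimizing the dispersion of `ln mtLEO` across species,
either about its mean or about the regression of `ln mtLEO` on four
amino-acid variables (AAVs) of the mtDNA-encoded membrane proteins:

* **SC, TC, CC** — Ser, Thr, Cys content (%) of the hydrophobic domains,
  the sites whose windowed Kyte–Doolittle hydropathy `S_av` exceeds 1.5,
  pooled over the six large proton-pump subunits (ND2, ND4, ND5, CO1,
  CO3, CYTB);
* **HYD** — mean `S_av` over those sites.

The lifespan model is the weighted log-linear regression

```
ln mtLEO(α) = A0 + W·(A1·SC + A2·TC + A3·CC + A4·HYD) + ε
⇔   MLS = exp(AAV) / mtMR,   AAV = W·(A1·SC + … + A4·HYD) + A0
```

with `W` a per-species branching weight (1 in the standard analysis):
predicted lifespan decomposes into a protein-stability factor and a
metabolic factor. Stratified per-clade fits give each clade its own α —
large in rodents (AAVs dominate), 1 in cetaceans (metabolism dominates).

## Worked example

The package ships a synthetic-data generator whose defaults emulate a
72-species mammalian study with known ground truth (generating
α = 2.1, coefficients A0…A4 = −2.0, 0.1, 0.1, −0.3, −1.0):

```r
library(mtleo)

st   <- generate_traits(generator_spec(seed = 1))
fit  <- fit_allometry(st$traits)
scan <- scan_alpha(st$traits, st$aav, fit = fit, grid = seq(1, 8, 0.05))
lf   <- fit_mtleo_regression(st$traits, st$aav, fit = fit,
                             alpha = scan$alpha_star_reg)
print(fit)
print(scan)
print(lf)
```

```
Allometric fit BMR = a * M^b: a = 0.021586 W, b = 0.7467 (n = 72, R = 0.997)
Alpha scan over [1.00, 8.00] (141 points, n = 72 species)
  s.d. about mean       minimized at alpha = 1.80
  s.d. about regression minimized at alpha = 2.10
  multiple correlation  maximized at alpha = 2.20 (R = 0.879)
Lifespan regression at alpha = 2.10 (n = 72):
   A0 = -1.7586, A1 = 0.0988, A2 = 0.0984, A3 = -0.2072, A4 = -1.1246
  R = 0.877, F(4, 67) = 55.94, p = 1.18e-20, AIC = -231.0, sigma = 0.1944
  outliers (outside the 95% band): sp005, sp022, sp025
```

The scan recovers the generating α (2.1) on the regression criterion and
the fitted coefficients sit close to the generating values; R is the
multiple correlation on the `ln mtLEO` scale. The decomposition per
species:

```r
head(predict_mls(lf), 3)
```

```
  species  mls_obs     mass_g    exp_aav        mtmr mls_pred    ratio
1   sp001 5.411988    722.039 0.04742030 0.008987246 5.276399 5.276399
2   sp002 5.951587   4025.940 0.04726219 0.007683573 6.151068 6.151068
3   sp003 9.382863 102323.066 0.05679506 0.006169024 9.206490 9.206490
```

`mls_pred = exp_aav / mtmr`: a species' predicted lifespan in years as
the ratio of its protein-stability factor to its per-mitochondrion
metabolic rate. Real data enter the same way through
`read_trait_table()`, `read_aav_table()` (or FASTA via
`read_protein_fasta()` + `aav_table()`) and `read_weights()`;
`run_full_pipeline(run_config(...))` orchestrates every stage and writes
CSV/JSON reports.

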