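---
title: "Modelling mammalian lifespan from mitochondrial metabolic rate and membrane-protein composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mammalian lifespan from mitochondrial metabolic rate and membrane-protein composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtleo)
```

## The problem

The classical rate-of-living hypothesis holds that the lifetime energy
expenditure `LEE = MLS × msBMR` — maximum lifespan times mass-specific
basal metabolic rate — is roughly constant across species. It captures a
real mammal-wide trend (small, metabolically fast species die young) but
fails in two well-known ways: within several orders, rodents most
prominently, lifespan and msBMR are not inversely related (the naked
mole-rat lives about seven times longer than a house mouse of similar
size), and LEE itself varies widely across mammals and birds.

`mtleo` implements a framework that addresses both failures by replacing
msBMR with a *per-mitochondrion* metabolic rate. msBMR is proportional to
the product of mitochondrial density and the metabolic rate per
mitochondrion; only the latter reflects the energetic state of the
organelle whose membrane proteins are encoded by mtDNA. The package
combines that rate with four sequence-derived variables describing the
stability of those membrane proteins, and asks how much of the
interspecific variation in lifespan the two ingredients explain.

## The model

### Per-mitochondrion metabolic rate

Basal metabolic rate follows the allometric law `BMR ≈ a·M^b` (fit by OLS
of `ln BMR` on `ln M`; `fit_allometry()`). Each species is then given the
exponent `B = ln(BMR/a)/ln(M)` that reproduces its observed BMR exactly,
so `msBMR = a·M^(B−1)` is an identity, not an approximation
(`derive_exponent()`). The per-mitochondrion rate is defined as the
one-parameter family

```
mtMR(α) = a · M^((B−1)/α),      α ≥ 1,
```

which leaves msBMR in place at `α = 1` and flattens toward the
mass-independent constant `a` as `α → ∞` (`mtmr()`). On noiseless
allometric data the slope of `ln mtMR` against `ln M` is `(b−1)/α` —
e.g. −0.125 at `b = 0.75`, `α = 2`, close to the observed exponent of
mass-specific *maximal* metabolic rate. The displayed form of this
definition is the unique power law satisfying three constraints stated
for it: equality with msBMR at `α = 1`, near-constancy at large `α`, and
the −0.125 mammal-wide exponent at `α ≈ 2`.

The lifetime energy output per mitochondrion is `mtLEO(α) = MLS ×
mtMR(α)`, which equals LEE at `α = 1` (`derive_metabolism()`).

### Amino-acid variables of the membrane proteins

From the 13 mtDNA-encoded protein sequences the package computes, per
species (`compute_aav()`, `aav_table()`):

* a per-residue hydropathy score `S` (Kyte–Doolittle by default; the
  scale is a named vector and swappable),
* its centered moving average `S_av` over an odd window (default 11, the
  conventional width for membrane-helix detection; positions whose full
  window does not fit carry no value — windows are never truncated, which
  keeps the statistic unbiased at the termini),
* the hydrophobic domains: sites with `S_av > 1.5`, strict inequality,
* four variables pooled over the six large proton-pump subunits
  (ND2, ND4, ND5, CO1, CO3, CYTB by default): **SC**, **TC**, **CC** —
  Ser, Thr and Cys as percentages of the selected sites — and **HYD**,
  the mean `S_av`.

Ser/Thr support inter-helical hydrogen bonding (dynamic stability), Cys
is the main oxidation-sensitive residue, and HYD measures how deeply the
helices sit in the lipid environment; together they summarize the
stability/mobility balance of the respiratory-chain machinery.

Two conventions were genuinely open and are both implemented: HYD
defaults to the mean over *selected* sites (`hyd_mean = "selected"`),
with the mean over all positions with a defined `S_av` selectable;
non-standard residues (X, B, Z, gaps) carry no score and make every
window containing them undefined and unselectable, rather than being
assigned an invented hydropathy.

### Choosing α and fitting lifespan

`scan_alpha()` traces, over a grid of α (default 1–20 in steps of 0.05,
reported to about one decimal), the dispersion of `ln mtLEO(α)`: its
standard deviation about the mean (denominator n−1) and the residual
standard deviation about the OLS regression of `ln mtLEO` on the four
weighted AAVs (denominator n−k−1, refitted at every α), plus the
multiple correlation. The dispersion minima and correlation maximum are
the candidate α's; ties break toward smaller α, and a boundary optimum
raises a warning because the profile can be nearly flat (large-α optima
mean mtMR is effectively mass-independent). The denominators are a
convention the source analysis does not pin down; both dispersion
criteria are ratio-based in `sd_reduction()`, so the choice largely
cancels there.

The lifespan model itself is the weighted log-linear regression

```
ln mtLEO(α) = A0 + W·(A1·SC + A2·TC + A3·CC + A4·HYD) + ε,
```

with `W` a per-species branching weight multiplying the AAV combination
only — not the intercept and not the response (`fit_mtleo_regression()`).
Rearranged, `MLS = exp(AAV)/mtMR` with
`AAV = W·(A1·SC + … + A4·HYD) + A0`: predicted lifespan decomposes into a
protein-stability factor and a metabolic factor (`predict_mls()`,
`mls_from_decomposition()`). Reported statistics: multiple correlation R
(identical to the Pearson correlation of observed and fitted
`ln mtLEO`), the observed-versus-predicted `ln MLS` correlation `R_mls`
(these differ when the metabolic slope is constrained to one), the
overall F with its exact tail probability, the Gaussian-likelihood AIC
`n·ln(RSS/n) + 2(k+1)` (constant dropped — only differences are
meaningful), and the residual σ.

Outliers are species outside the two-sided 95% *prediction* band of the
regression (`flag_outliers()`); the narrower mean-confidence band is
selectable. The prediction band was chosen as the default because it is
the convention under which a handful of species per ~70 (≈4–5%) are
flagged, matching how deviants are usually reported in this literature.

`robustness_variants()` refits with a free slope `A5` on the metabolic
term: on `ln mtMR` the model predicts `A5 = −1`, and on `ln msBMR` it
predicts `A5 = −1/α` (since `ln mtMR = ln msBMR/α` up to a constant),
with unchanged AAV coefficients — a direct check that the constrained
form is not forcing the fit.

### Stratified per-clade analysis

Clades differ in how the two factors contribute: in rodents the AAVs
dominate (the α optimum is large, mtMR nearly mass-independent), in
cetaceans the metabolic factor dominates (α optimum at 1). five
clade-level groups (Rodentia/Glires, Cetacea, Primates, Laurasiatheria
excluding cetaceans, other) ship as definitions in
`inst/extdata/mammal_group_definitions.csv`; users supply their own
species-to-group mapping. `stratified_analysis()` scans α per group
(minimizing the dispersion about the AAV regression line — the criterion
used for the per-clade optimizations; `criterion = "mean"` is
selectable), fits each group at its own α, and pools the per-species
predictions into an overall observed-versus-predicted correlation. The
all-species allometric constant `a` is reused by default
(`refit_allometry = TRUE` refits per clade). Groups below the minimum
fitting size (6 = regressors + 2) are reported as skipped, never dropped
silently.

### Branching weights

The weight `W` enters the regression as a per-species multiplier of the
AAV combination. The primary contract is to *read* weights supplied with
a study (`read_weights()`, or a `w` column). Because no computable
definition of the weights accompanies the published analyses, the two
derivation schemes in `weights_from_tree()` — inverse root-to-tip path
length, and per-clade multipliers — are clearly labelled approximations
for synthetic and exploratory work; both are normalized to mean 1 so the
weights cannot rescale the response. `build_nj_tree()` provides a
convenience neighbor-joining tree on Poisson-corrected p-distances of
aligned sequences, again an approximation and not a substitute for
model-based inference.

## The synthetic-data generator

`generator_spec()` / `generate_traits()` produce trait, AAV and weight
tables with a full ground-truth record, and `generate_sequences()`
builds protein sequences realizing prescribed AAVs. The generator's
defaults are the package's reference study conditions, chosen once to
emulate a realistic mammalian comparative dataset:

* **n = 72 species**, the size at which the mammal-wide analyses run;
* **mass log-uniform on 10 g–10⁸ g**, the house-mouse-to-bowhead-whale
  span;
* **a = 0.02 W, b = 0.75** (Kleiber-type scaling with BMR in watts and
  mass in grams) with **ln-BMR noise sd 0.3**, which reproduces the
  strong but imperfect `R ≈ 0.95`-grade allometric correlation;
* **AAV ranges** SC ∈ [4, 10] %, TC ∈ [6, 12] %, CC ∈ [0.5, 2.5] %,
  HYD ∈ [2.0, 2.8], typical extraction values for mammalian mtDNA-encoded
  subunits under the Kyte–Doolittle scale;
* **α_true = 2.1** and coefficients `A0 = −2.0, A1 = 0.1, A2 = 0.1,
  A3 = −0.3, A4 = −1.0`: signs follow the terrestrial-mammal pattern
  (SC, TC up with lifespan; CC, HYD down) and magnitudes put the AAV
  contribution on the same ln-lifespan scale as the metabolic term, so
  generated lifespans span roughly 1–70 years;
* **ln-MLS noise sd 0.2**, which places the combined-model correlation in
  the high-0.8 regime reported for mammal-wide fits.

Sequences are constructed, not evolved: an Ile/Ala background keeps every
full-window site above the selection threshold, Ser/Thr/Cys are placed at
evenly spaced selected positions at the prescribed counts, and the
Ile:Ala ratio is found by a monotone integer search against the HYD
target. Extraction therefore recovers SC/TC/CC exactly at the resolution
of one residue count and HYD to ~0.01. What the generator deliberately
does *not* emulate: phylogenetic autocorrelation among species (traits
are drawn independently), correlated AAVs, measurement error structure in
AnAge-style databases, or realistic protein evolution. Passing the
round-trip and recovery tests therefore demonstrates the estimators'
correctness under the stated model, not robustness to real-data
violations of it.

## Numerical choices and degenerate inputs

* `B` is undefined at `M = 1 g` (`ln M = 0`); the package raises an
  explicit error telling the caller to change units rather than perturb
  the mass.
* Rank-deficient or near-collinear AAV designs (condition number above
  1e10) are errors naming the offending columns, not silent drops.
* Residuals below ~1e-8 are never flagged as outliers, so numerically
  perfect fits report zero outliers.
* The scan grid is discrete; optima are reported at grid resolution and
  tie-broken toward smaller α. Golden-section refinement was considered
  and rejected: the published optima are one-decimal values and the
  profiles near large-α optima are nearly flat.
* All pipeline CSV/JSON outputs are byte-reproducible given the same
  configuration; figures are excluded from that guarantee.

## Validation problem sizes

The shipped test-and-validation suite runs the full pipeline at the
reference size (n = 72), the allometric recovery at n = 347, the
calibration study as 200 replicates of n = 72 (coefficient 95% CI
coverage pooled across the five coefficients must reach 93%), stratified
recovery on two 30-species clades with α of 1.3 and 3.5, and oracle
comparisons on random sequences of 40–120 residues. These sizes were
chosen to match the study scales the package targets while keeping the
whole suite fast enough to run routinely.

## Known limitations

* The α scan identifies α only through the mass-dependence of residual
  dispersion; on narrow mass ranges, or when `B − 1` varies little, the
  profile is flat and the optimum poorly determined (the boundary warning
  is the symptom).
* The branching-weight schemes are heuristics; published weighted fits
  can only be reproduced with the weights that accompany the original
  data.
* The stratified pooled correlation is computed over groups large enough
  to fit; skipped groups are reported but their species do not enter the
  pooled statistic.
* No phylogenetically generalized least squares: `W` is a scalar
  per-species weight, not an error-covariance structure, by design.

## A minimal session

```{r example, eval = FALSE}
st <- generate_traits(generator_spec(seed = 1))
fit <- fit_allometry(st$traits)
scan <- scan_alpha(st$traits, st$aav, fit = fit, grid = seq(1, 8, 0.05))
lf <- fit_mtleo_regression(st$traits, st$aav, fit = fit,
                           alpha = scan$alpha_star_reg)
print(lf)
head(predict_mls(lf))
```
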