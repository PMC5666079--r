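clean_study <- function(seed = 17, alpha = 2.1) {
  generate_traits(generator_spec(bmr_noise_sd = 0, mls_noise_sd = 0,
                                 alpha_true = alpha, seed = seed))
}

test_that("noiseless data return the generating coefficients exactly", {
  st <- clean_study()
  suppressWarnings({
    fit <- fit_allometry(st$traits)
    lf <- fit_mtleo_regression(st$traits, st$aav, fit = fit, alpha = 2.1)
  })
  expect_equal(unname(lf$coefficients),
               unname(st$truth$spec$coef[c("A0", "A1", "A2", "A3", "A4")]),
               tolerance = 1e-8)
  expect_equal(lf$R, 1, tolerance = 1e-9)
  expect_equal(sum(lf$outliers), 0)
})

test_that("R equals the Pearson correlation of observed and fitted values", {
  st <- generate_traits(generator_spec(seed = 6))
  lf <- fit_mtleo_regression(st$traits, st$aav, alpha = 2.1)
  y <- log(st$traits$mls_yr * lf$metabolism$mtmr)
  expect_equal(lf$R, cor(y, lf$fitted_ln_mtleo), tolerance = 1e-12)
  expect_equal(lf$R_mls, cor(log(st$traits$mls_yr), lf$fitted_ln_mls),
               tolerance = 1e-12)
  # in the free-slope combined model the multiple R equals the Pearson
  # correlation between observed and fitted ln(MLS)
  rb <- robustness_variants(st$traits, st$aav, alpha = 2.1)
  expect_equal(rb$mtmr$R,
               cor(log(st$traits$mls_yr), fitted(rb$mtmr$model)),
               tolerance = 1e-12)
})

test_that("prediction decomposes as MLS = exp(AAV)/mtMR", {
  st <- generate_traits(generator_spec(seed = 9))
  lf <- fit_mtleo_regression(st$traits, st$aav, alpha = 1.8)
  pr <- predict_mls(lf)
  expect_equal(pr$mls_pred, pr$exp_aav / pr$mtmr, tolerance = 1e-12)
  # ln(pred MLS) + ln(mtMR) is the fitted ln(mtLEO)
  expect_equal(log(pr$mls_pred) + log(pr$mtmr), lf$fitted_ln_mtleo,
               tolerance = 1e-10)
  # decomposition identity helper
  expect_equal(mls_from_decomposition(0.0492, 0.0143), 0.0492 / 0.0143)
  expect_equal(mls_from_decomposition(1, 1), 1)
})

test_that("error paths: small n, collinearity, bad weights, missing AAVs", {
  st <- generate_traits(generator_spec(seed = 14))
  small <- st$traits[1:5, ]
  expect_error(fit_mtleo_regression(small, st$aav[1:5, ], alpha = 2),
               "more than 5 species")
  aav_coll <- st$aav
  aav_coll$HYD <- 0.02 * aav_coll$SC   # exactly collinear with SC
  expect_error(fit_mtleo_regression(st$traits, aav_coll, alpha = 2),
               "rank deficient|collinear")
  expect_error(fit_mtleo_regression(st$traits, st$aav, alpha = 2,
                                    weights = rep(-1, nrow(st$traits))),
               "positive")
  lf <- fit_mtleo_regression(st$traits, st$aav, alpha = 2)
  expect_error(predict_mls(lf, traits = st$traits, aav = st$aav[-1, ]),
               "species mismatch")
  expect_error(predict_mls(lf, traits = st$traits), "without matching AAVs")
})

test_that("implanted 4-sigma deviants are the flagged outliers", {
  # natural scatter truncated at 1.5 sigma keeps every regular species
  # inside the 95% prediction band; three 4-sigma deviants are implanted
  sigma <- 0.2
  sp <- generator_spec(mls_noise_sd = 0, seed = 77)
  st <- generate_traits(sp)
  set.seed(78)
  u <- runif(nrow(st$traits), pnorm(-1.5), pnorm(1.5))
  tr <- st$traits
  tr$mls_yr <- tr$mls_yr * exp(sigma * qnorm(u))
  idx <- c(10, 40, 65)
  tr$mls_yr[idx] <- st$traits$mls_yr[idx] * exp(4 * sigma * c(1, -1, 1))
  lf <- fit_mtleo_regression(tr, st$aav, alpha = 2.1)
  expect_setequal(which(lf$outliers), idx)
  # widening the band never adds flags
  fl99 <- flag_outliers(lf, level = 0.999)
  expect_true(all(which(fl99) %in% which(lf$outliers)))
  # the confidence band is narrower than the prediction band
  fl_conf <- flag_outliers(lf, band = "confidence")
  expect_true(all(which(lf$outliers) %in% which(fl_conf)))
})

test_that("free-slope refits recover A5 = -1 and -1/alpha", {
  st <- clean_study(seed = 19, alpha = 2)
  suppressWarnings({
    fit <- fit_allometry(st$traits)
    rb <- robustness_variants(st$traits, st$aav, fit = fit, alpha = 2)
  })
  expect_equal(rb$mtmr$A5, -1, tolerance = 1e-8)
  expect_equal(rb$msbmr$A5, -0.5, tolerance = 1e-8)
  expect_equal(unname(rb$mtmr$coefficients[c("A1", "A2", "A3", "A4")]),
               c(0.1, 0.1, -0.3, -1.0), tolerance = 1e-8)
  # noisy: A5 within 3 standard errors of -1
  stn <- generate_traits(generator_spec(seed = 20))
  rbn <- robustness_variants(stn$traits, stn$aav, alpha = 2.1)
  expect_lt(abs(rbn$mtmr$A5 + 1), 3 * rbn$mtmr$A5_se)
  expect_lt(abs(rbn$msbmr$A5 + 1 / 2.1), 3 * rbn$msbmr$A5_se)
})

test_that("weights multiply the AAV combination; common rescaling is absorbed", {
  st <- generate_traits(generator_spec(seed = 25))
  lf1 <- fit_mtleo_regression(st$traits, st$aav, alpha = 2.1)
  # unit weights equal the unweighted path bit for bit
  lfu <- fit_mtleo_regression(st$traits, st$aav, alpha = 2.1,
                              weights = unit_weights(st$traits$species))
  expect_identical(lf1$coefficients, lfu$coefficients)
  # scaling all weights by c rescales A1..A4 by 1/c, predictions unchanged
  lfc <- fit_mtleo_regression(st$traits, st$aav, alpha = 2.1,
                              weights = rep(2.5, nrow(st$traits)))
  expect_equal(unname(lfc$coefficients[-1]) * 2.5,
               unname(lf1$coefficients[-1]), tolerance = 1e-9)
  expect_equal(lfc$fitted_ln_mls, lf1$fitted_ln_mls, tolerance = 1e-9)
  expect_equal(lfc$R, lf1$R, tolerance = 1e-12)
})

test_that("model comparison favours the full generating set", {
  st <- generate_traits(generator_spec(seed = 33))
  cmp <- model_comparison(st$traits, st$aav, alpha = 2.1)
  full <- cmp[cmp$model == "SC,TC,HYD,CC" & cmp$response == "ln(mtLEO)", ]
  subsets <- cmp[cmp$model %in% c("SC,TC,HYD", "SC,TC,CC", "HYD,CC", "CC") &
                   cmp$response == "ln(mtLEO)", ]
  expect_true(all(full$R >= subsets$R))
  expect_true(all(full$AIC <= subsets$AIC))  # all four AAVs truly generate
  combined <- cmp[cmp$model == "mtMR,SC,TC,HYD,CC", ]
  expect_equal(combined$response, "ln(MLS)")
  expect_gt(combined$R, cmp$R[cmp$model == "mtMR"])
})

test_that("stratified analysis with one group degenerates to the one-step fit", {
  st <- generate_traits(generator_spec(seed = 37))
  grid <- seq(1, 6, 0.05)
  strat <- stratified_analysis(st$traits, st$aav, grid = grid)
  sc <- scan_alpha(st$traits, st$aav, grid = grid)
  lf <- fit_mtleo_regression(st$traits, st$aav, alpha = sc$alpha_star_reg)
  expect_equal(length(strat$fits), 1L)
  expect_equal(unname(strat$alpha), sc$alpha_star_reg)
  expect_equal(strat$fits[[1]]$coefficients, lf$coefficients,
               tolerance = 1e-12)
  expect_equal(strat$pooled_R, lf$R_mls, tolerance = 1e-12)
})

test_that("per-group alphas are recovered and pooling beats one-step when groups differ", {
  sp <- generator_spec(n_species = 60, mls_noise_sd = 0.1,
                       group_alpha = c(g1 = 1.3, g2 = 3.5),
                       group_sizes = c(g1 = 30, g2 = 30), seed = 55)
  st <- generate_traits(sp)
  grid <- seq(1, 6, 0.05)
  strat <- stratified_analysis(st$traits, st$aav, grid = grid)
  expect_equal(unname(strat$alpha["g1"]), 1.3, tolerance = 0.35)
  expect_equal(unname(strat$alpha["g2"]), 3.5, tolerance = 0.7)
  one <- fit_mtleo_regression(st$traits, st$aav,
                              alpha = scan_alpha(st$traits, st$aav,
                                                 grid = grid)$alpha_star_reg)
  expect_gt(strat$pooled_R, one$R_mls)
  # small groups are recorded as skipped, never dropped silently
  tr <- st$traits
  tr$group[1:3] <- "tiny"
  strat2 <- stratified_analysis(tr, st$aav, grid = grid)
  expect_equal(unname(strat2$skipped["tiny"]), 3)
  expect_error(stratified_analysis(st$traits, st$aav,
                                   group = rep(NA, nrow(st$traits))),
               "without a group")
})
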