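test_that("regression dispersion never exceeds dispersion about the mean", {
  st <- generate_traits(generator_spec(seed = 10))
  sc <- scan_alpha(st$traits, st$aav, grid = seq(1, 8, 0.1))
  # sd_reg uses n-k-1, sd_mean n-1: compare on the same scale
  n <- sc$n; k <- sc$k
  rss_reg <- sc$table$sd_reg^2 * (n - k - 1)
  rss_mean <- sc$table$sd_mean^2 * (n - 1)
  expect_true(all(rss_reg <= rss_mean + 1e-12))
})

test_that("scan output is invariant to row order and response shifts", {
  st <- generate_traits(generator_spec(seed = 12))
  grid <- seq(1, 6, 0.1)
  sc <- scan_alpha(st$traits, st$aav, grid = grid)
  perm <- sample(nrow(st$traits))
  sc_p <- scan_alpha(st$traits[perm, ], st$aav[perm, ], grid = grid)
  expect_equal(sc$table, sc_p$table, tolerance = 1e-10)
  # multiplying MLS by a constant shifts ln(mtLEO) but not dispersions
  tr2 <- st$traits; tr2$mls_yr <- tr2$mls_yr * 7.3
  fit <- fit_allometry(st$traits)
  sc2 <- scan_alpha(tr2, st$aav, fit = fit,
                    grid = grid)
  sc1 <- scan_alpha(st$traits, st$aav, fit = fit, grid = grid)
  expect_equal(sc1$table$sd_mean, sc2$table$sd_mean, tolerance = 1e-10)
  expect_equal(sc1$table$sd_reg, sc2$table$sd_reg, tolerance = 1e-10)
  expect_equal(sc1$table$corr, sc2$table$corr, tolerance = 1e-10)
})

test_that("a rate-of-living world selects alpha = 1", {
  # MLS * msBMR exactly constant: generated with alpha_true = 1, no AAV
  # effect, no lifespan noise
  sp <- generator_spec(alpha_true = 1, mls_noise_sd = 0,
                       coef = c(A0 = 1, A1 = 0, A2 = 0, A3 = 0, A4 = 0),
                       seed = 31)
  st <- generate_traits(sp)
  expect_equal(stats::sd(log(st$traits$mls_yr * st$traits$bmr_w /
                               st$traits$mass_g)), 0, tolerance = 1e-12)
  expect_warning(scan_alpha(st$traits, st$aav, grid = seq(1, 10, 0.1)),
                 "boundary")
  sc <- suppressWarnings(scan_alpha(st$traits, st$aav,
                                    grid = seq(1, 10, 0.1)))
  expect_equal(sc$alpha_star_mean, 1)
})

test_that("the generating alpha is recovered from synthetic data", {
  # noiseless: exact to grid resolution, with perfect fit at the optimum
  sp <- generator_spec(bmr_noise_sd = 0, mls_noise_sd = 0,
                       alpha_true = 2.1, seed = 17)
  st <- generate_traits(sp)
  sc <- suppressWarnings(  # noiseless allometry is a perfect fit
    scan_alpha(st$traits, st$aav, grid = seq(1, 5, 0.05)))
  expect_equal(sc$alpha_star_reg, 2.1, tolerance = 1e-9)
  expect_equal(sc$alpha_star_corr, 2.1, tolerance = 1e-9)
  i <- which(abs(sc$table$alpha - 2.1) < 1e-9)
  expect_lt(sc$table$sd_reg[i], 1e-10)
  expect_equal(sc$table$corr[i], 1, tolerance = 1e-9)
})

test_that("ties break toward the smaller alpha", {
  st <- generate_traits(generator_spec(seed = 23))
  sc <- scan_alpha(st$traits, st$aav, grid = seq(1, 6, 0.05))
  tb <- sc$table
  expect_equal(sc$alpha_star_reg,
               min(tb$alpha[tb$sd_reg == min(tb$sd_reg)]))
})

test_that("sd_reduction measures the dispersion narrowing", {
  st <- generate_traits(generator_spec(seed = 29))
  sc <- scan_alpha(st$traits, st$aav, grid = seq(1, 8, 0.05))
  i_ref <- 1L
  i_star <- which(abs(sc$table$alpha - sc$alpha_star_mean) < 1e-9)
  expect_equal(sd_reduction(sc, 1, "mean"),
               100 * (1 - sc$table$sd_mean[i_star] / sc$table$sd_mean[i_ref]),
               tolerance = 1e-12)
  expect_gte(sd_reduction(sc, 1, "mean"), 0)
  expect_error(sd_reduction(sc, 1.234), "not on the scan grid")
  # flat profile: reduction is zero (alpha never enters when B = 1)
  tr_flat <- make_clean_traits(b = 0.75)
  tr_flat$bmr_w <- 0.02 * tr_flat$mass_g  # B = 1 for every species
  tr_flat$mls_yr <- seq(2, 40, length.out = nrow(tr_flat))
  suppressWarnings(fit_flat <- fit_allometry(tr_flat))
  st2 <- generate_traits(generator_spec(n_species = nrow(tr_flat), seed = 1))
  aav_flat <- st2$aav
  aav_flat$species <- tr_flat$species
  sc_flat <- suppressWarnings(scan_alpha(tr_flat, aav_flat, fit = fit_flat,
                                         grid = seq(1, 3, 0.5)))
  expect_equal(sd_reduction(sc_flat, 1, "mean"), 0, tolerance = 1e-9)
})

test_that("species mismatches and degenerate designs are reported", {
  st <- generate_traits(generator_spec(seed = 41))
  aav_bad <- st$aav[-3, ]
  expect_error(scan_alpha(st$traits, aav_bad, grid = seq(1, 2, 0.5)),
               "species mismatch")
  aav_const <- st$aav
  aav_const$CC <- 1.0
  expect_error(scan_alpha(st$traits, aav_const, grid = seq(1, 2, 0.5)),
               "CC")
})
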