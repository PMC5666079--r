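#' Weighted log-linear lifetime-energy-output regression
#'
#' Fits by ordinary least squares
#' `ln(mtLEO(alpha)) = A0 + A1*(W*SC) + A2*(W*TC) + A3*(W*CC) + A4*(W*HYD)`,
#' where `W` is a per-species weight multiplying the AAV linear
#' combination (1 in the standard analysis). Rearranged, the model
#' predicts lifespan as `MLS = exp(AAV)/mtMR` with
#' `AAV = W*(A1*SC + A2*TC + A3*CC + A4*HYD) + A0` (see [predict_mls()]).
#'
#' Reported statistics: the multiple correlation `R` (equal to the Pearson
#' correlation between observed and fitted `ln(mtLEO)`), the correlation
#' `R_mls` between observed and predicted `ln(MLS)` (these differ because
#' the metabolic slope is constrained to one; they coincide in the
#' free-slope refit of [robustness_variants()]), the overall
#' F-statistic with its tail probability `p` from `F(k, n-k-1)`,
#' `AIC = n*ln(RSS/n) + 2*(k+1)` (Gaussian-likelihood form with the
#' additive constant dropped, so only AIC differences are meaningful), and
#' the residual standard deviation `sigma` (denominator n-k-1).
#'
#' @inheritParams scan_alpha
#' @param alpha The alpha at which mtMR/mtLEO are evaluated.
#' @param outlier_level Confidence level of the outlier band stored with
#'   the fit (see [flag_outliers()]).
#' @return Object of class `"lifespan_fit"`: coefficients `A0..A4`,
#'   `alpha`, per-species weights, `R`, `F`, `p`, `AIC`, `sigma`,
#'   `fitted_ln_mtleo`, `fitted_ln_mls`, `residuals`, `outliers`, the
#'   aligned input tables, the metabolic table and the underlying `lm`.
#' @export
fit_mtleo_regression <- function(traits, aav, fit = fit_allometry(traits),
                                 weights = NULL, alpha,
                                 outlier_level = 0.95) {
  al <- .align_inputs(traits, aav, weights)
  n <- nrow(al$traits)
  k <- 4L
  if (n <= k + 1L) {
    stop("regression with ", k, " AAVs needs more than ", k + 1L,
         " species, got ", n)
  }
  kap <- kappa(cbind(1, al$X), exact = TRUE)
  if (kap > 1e10) {
    stop("weighted AAV columns are (near-)collinear (condition number ",
         format(kap, digits = 3), ")")
  }
  met <- derive_metabolism(al$traits, fit, alpha)
  dat <- data.frame(y = log(met$mtleo),
                    SCw = al$X[, "SC"], TCw = al$X[, "TC"],
                    CCw = al$X[, "CC"], HYDw = al$X[, "HYD"])
  fm <- stats::lm(y ~ SCw + TCw + CCw + HYDw, data = dat)
  sm <- summary(fm)
  rss <- sum(stats::residuals(fm)^2)
  Fst <- unname(sm$fstatistic)
  res <- structure(
    list(
      alpha = alpha,
      coefficients = stats::setNames(stats::coef(fm),
                                     c("A0", "A1", "A2", "A3", "A4")),
      W = stats::setNames(al$w, al$traits$species),
      R = sqrt(sm$r.squared),
      R_mls = stats::cor(log(al$traits$mls_yr),
                         unname(stats::fitted(fm)) - log(met$mtmr)),
      F = Fst[1L],
      p = stats::pf(Fst[1L], Fst[2L], Fst[3L], lower.tail = FALSE),
      AIC = n * log(rss / n) + 2 * (k + 1L),
      sigma = sqrt(rss / (n - k - 1L)),
      n = n, k = k,
      species = al$traits$species,
      fitted_ln_mtleo = unname(stats::fitted(fm)),
      fitted_ln_mls = unname(stats::fitted(fm)) - log(met$mtmr),
      residuals = unname(stats::residuals(fm)),
      traits = al$traits, aav = al$aav, metabolism = met,
      allometric_fit = fit,
      model = fm
    ),
    class = "lifespan_fit"
  )
  res$outliers <- flag_outliers(res, level = outlier_level)
  res$outlier_level <- outlier_level
  res
}

#' @export
print.lifespan_fit <- function(x, ...) {
  cat(sprintf("Lifespan regression at alpha = %.2f (n = %d):\n", x$alpha, x$n))
  cat("  ", paste(sprintf("%s = %.4f", names(x$coefficients),
                          x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  R = %.3f, F(%d, %d) = %.2f, p = %.3g, AIC = %.1f, sigma = %.4f\n",
              x$R, x$k, x$n - x$k - 1L, x$F, x$p, x$AIC, x$sigma))
  if (any(x$outliers)) {
    cat("  outliers (outside the ", 100 * x$outlier_level,
        "% band): ", paste(x$species[x$outliers], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Predicted lifespan and its decomposition
#'
#' Rearranges the fitted log-linear model into
#' `MLS = exp(AAV) / mtMR`, the decomposition of predicted lifespan into
#' a protein-stability factor `exp(AAV)` and a metabolic factor `mtMR`.
#' By construction `ln(predicted MLS) + ln(mtMR)` equals the fitted value
#' of `ln(mtLEO)`.
#'
#' @param object A `"lifespan_fit"`.
#' @param traits,aav,weights Optional new data (defaults: the fit's own).
#' @return `data.frame` with `species`, `mls_obs`, `mass_g`, `exp_aav`,
#'   `mtmr`, `mls_pred` and `ratio` (= `mls_pred`, kept as an explicit
#'   `exp(AAV)/mtMR` column for decomposition tables).
#' @seealso [mls_from_decomposition()]
#' @export
predict_mls <- function(object, traits = NULL, aav = NULL, weights = NULL) {
  stopifnot(inherits(object, "lifespan_fit"))
  if (is.null(traits)) {
    traits <- object$traits
    aav <- object$aav
    w <- unname(object$W)
    met <- object$metabolism
  } else {
    if (is.null(aav)) stop("new traits supplied without matching AAVs")
    al <- .align_inputs(traits, aav, weights)
    traits <- al$traits; aav <- al$aav; w <- al$w
    met <- derive_metabolism(traits, object$allometric_fit, object$alpha)
  }
  cf <- object$coefficients
  aav_lin <- w * (cf["A1"] * aav$SC + cf["A2"] * aav$TC +
                  cf["A3"] * aav$CC + cf["A4"] * aav$HYD) + cf["A0"]
  exp_aav <- exp(unname(aav_lin))
  data.frame(
    species = traits$species,
    mls_obs = traits$mls_yr,
    mass_g = traits$mass_g,
    exp_aav = exp_aav,
    mtmr = met$mtmr,
    mls_pred = exp_aav / met$mtmr,
    ratio = exp_aav / met$mtmr,
    stringsAsFactors = FALSE
  )
}

#' Lifespan from the stability/metabolism decomposition
#'
#' The algebraic identity `MLS = exp(AAV) / mtMR` relating predicted
#' lifespan to the protein-stability factor and the per-mitochondrion
#' metabolic rate. Exposed for decomposition tables where `exp(AAV)` and
#' `mtMR` are reported separately.
#'
#' @param exp_aav `exp(AAV)` value(s).
#' @param mtmr `mtMR` value(s) (arbitrary units).
#' @return Predicted MLS in years.
#' @examples
#' mls_from_decomposition(0.0492, 0.0143)  # ~3.4 yr, a small short-lived rodent
#' @export
mls_from_decomposition <- function(exp_aav, mtmr) {
  stopifnot(all(mtmr > 0))
  exp_aav / mtmr
}

#' Flag species outside the regression's confidence band
#'
#' Flags species whose observed `ln(mtLEO)` lies outside the two-sided
#' band of the fitted regression at the given level. The default band is
#' the prediction interval for a new observation; the narrower
#' mean-confidence band is selectable.
#'
#' @param object A `"lifespan_fit"`.
#' @param level Band coverage (default 0.95).
#' @param band `"prediction"` (default) or `"confidence"`.
#' @return Named logical vector (TRUE = outlier). The band convention is
#'   attached as attribute `"band"`.
#' @export
flag_outliers <- function(object, level = 0.95,
                          band = c("prediction", "confidence")) {
  stopifnot(inherits(object, "lifespan_fit"))
  band <- match.arg(band)
  # predict.lm warns that prediction intervals on the training data refer
  # to future responses; that is precisely the convention wanted here
  pr <- suppressWarnings(
    stats::predict(object$model, interval = band, level = level))
  y <- object$fitted_ln_mtleo + object$residuals
  out <- (y < pr[, "lwr"] | y > pr[, "upr"]) &
    abs(object$residuals) > 1e-8 * max(1, abs(y))  # ignore machine noise
  structure(stats::setNames(unname(out), object$species), band = band)
}

#' Free-slope robustness refits
#'
#' Instead of constraining the metabolic term of the lifespan model to a
#' unit slope, refits `ln(MLS)` with a free coefficient `A5` on the
#' metabolic regressor: once on `ln(mtMR)` (expected `A5 = -1`) and once
#' on `ln(msBMR)` (expected `A5 = -1/alpha`, since
#' `ln(mtMR) = ln(msBMR)/alpha + (1 - 1/alpha) ln(a)`). Under the model
#' the AAV coefficients and the multiple correlation match the
#' constrained fit, with only `A0` shifting in the msBMR variant.
#'
#' @inheritParams fit_mtleo_regression
#' @return List of class `"mtleo_robustness"`: for each variant the
#'   coefficients (`A5`, `A1..A4`, `A0`), standard error of `A5`, and
#'   `R`; plus the expected slopes.
#' @export
robustness_variants <- function(traits, aav, fit = fit_allometry(traits),
                                weights = NULL, alpha) {
  al <- .align_inputs(traits, aav, weights)
  met <- derive_metabolism(al$traits, fit, alpha)
  base <- data.frame(y = log(al$traits$mls_yr),
                     SCw = al$X[, "SC"], TCw = al$X[, "TC"],
                     CCw = al$X[, "CC"], HYDw = al$X[, "HYD"])
  one <- function(metab) {
    d <- base
    d$metab <- log(metab)
    fm <- stats::lm(y ~ metab + SCw + TCw + CCw + HYDw, data = d)
    cf <- stats::coef(fm)
    list(A5 = unname(cf["metab"]),
         A5_se = unname(summary(fm)$coefficients["metab", "Std. Error"]),
         coefficients = stats::setNames(
           cf[c("(Intercept)", "metab", "SCw", "TCw", "CCw", "HYDw")],
           c("A0", "A5", "A1", "A2", "A3", "A4")),
         R = sqrt(summary(fm)$r.squared),
         model = fm)
  }
  structure(
    list(mtmr = one(met$mtmr), msbmr = one(met$msbmr),
         alpha = alpha,
         expected = c(mtmr = -1, msbmr = -1 / alpha)),
    class = "mtleo_robustness"
  )
}

#' @export
print.mtleo_robustness <- function(x, ...) {
  cat(sprintf("Free-slope refits at alpha = %.2f:\n", x$alpha))
  cat(sprintf("  ln(mtMR)  slope A5 = %.4f (se %.4f; expected -1)\n",
              x$mtmr$A5, x$mtmr$A5_se))
  cat(sprintf("  ln(msBMR) slope A5 = %.4f (se %.4f; expected %.4f)\n",
              x$msbmr$A5, x$msbmr$A5_se, x$expected["msbmr"]))
  invisible(x)
}

#' Model-comparison table over AAV subsets and the metabolic term
#'
#' Fits, for each listed regressor set, ln-scale OLS models of three
#' responses -- `ln(MLS)`, `ln(mtLEO(alpha))` and `ln(LEE)` -- and
#' tabulates R, F, p and AIC. The default sets mirror the comparison of
#' AAV subsets against the metabolic term and the combined model
#' (`mtMR` only and `mtMR` + AAVs are fitted for the `ln(MLS)` response
#' only, where they are meaningful).
#'
#' @inheritParams fit_mtleo_regression
#' @param sets Named list of regressor sets; entries are subsets of
#'   `c("SC","TC","CC","HYD")`, optionally including `"mtmr"`.
#' @return `data.frame` with columns `model`, `response`, `R`, `F`, `p`,
#'   `AIC`, `k`.
#' @export
model_comparison <- function(traits, aav, fit = fit_allometry(traits),
                             weights = NULL, alpha,
                             sets = list(
                               "SC,TC,HYD" = c("SC", "TC", "HYD"),
                               "SC,TC,CC" = c("SC", "TC", "CC"),
                               "HYD,CC" = c("HYD", "CC"),
                               "CC" = "CC",
                               "SC,TC,HYD,CC" = c("SC", "TC", "HYD", "CC"),
                               "mtMR" = "mtmr",
                               "mtMR,SC,TC,HYD,CC" = c("mtmr", "SC", "TC",
                                                       "CC", "HYD"))) {
  al <- .align_inputs(traits, aav, weights)
  met <- derive_metabolism(al$traits, fit, alpha)
  n <- nrow(al$traits)
  responses <- list(`ln(MLS)` = log(al$traits$mls_yr),
                    `ln(mtLEO)` = log(met$mtleo),
                    `ln(LEE)` = log(met$lee))
  rows <- list()
  for (set_name in names(sets)) {
    vars <- sets[[set_name]]
    has_met <- "mtmr" %in% vars
    aav_vars <- setdiff(vars, "mtmr")
    X <- al$X[, aav_vars, drop = FALSE]
    if (has_met) X <- cbind(`ln_mtmr` = log(met$mtmr), X)
    resp_use <- if (has_met) "ln(MLS)" else names(responses)
    for (rn in resp_use) {
      y <- responses[[rn]]
      fm <- stats::lm(y ~ X)
      sm <- summary(fm)
      kk <- ncol(X)
      rss <- sum(stats::residuals(fm)^2)
      Fst <- unname(sm$fstatistic)
      rows[[length(rows) + 1L]] <- data.frame(
        model = set_name, response = rn,
        R = sqrt(sm$r.squared), F = Fst[1L],
        p = stats::pf(Fst[1L], Fst[2L], Fst[3L], lower.tail = FALSE),
        AIC = n * log(rss / n) + 2 * (kk + 1L), k = kk,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
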