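#' Plot an alpha scan
#'
#' Dispersion about the mean, dispersion about the AAV regression and the
#' multiple correlation as functions of alpha, with the located optima
#' marked.
#'
#' @param x An `"alpha_scan"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.alpha_scan <- function(x, ...) {
  tb <- x$table
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::matplot(tb$alpha, cbind(tb$sd_mean, tb$sd_reg), type = "l",
                    lty = 1, col = c("black", "blue"),
                    xlab = expression(alpha),
                    ylab = "s.d. of ln(mtLEO)",
                    main = "Dispersion of ln(mtLEO) vs alpha", ...)
  graphics::abline(v = c(x$alpha_star_mean, x$alpha_star_reg),
                   col = c("black", "blue"), lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(tb$alpha, tb$corr, type = "l", col = "red", axes = FALSE,
                 xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4, col.axis = "red")
  graphics::mtext("multiple correlation R", side = 4, line = 2.5,
                  col = "red")
  graphics::legend("bottomright", bty = "n", lty = 1,
                   col = c("black", "blue", "red"),
                   legend = c("s.d. about mean", "s.d. about regression",
                              "correlation"))
  invisible(x)
}

#' Plot observed versus predicted lifespan
#'
#' Observed `ln(MLS)` against the model's fitted `ln(MLS)`, identity line
#' shown, outliers (outside the stored confidence band) highlighted.
#'
#' @param x A `"lifespan_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lifespan_fit <- function(x, ...) {
  obs <- log(x$traits$mls_yr)
  pred <- x$fitted_ln_mls
  graphics::plot(pred, obs, pch = 19,
                 col = ifelse(x$outliers, "red", "grey30"),
                 xlab = "predicted ln(MLS)", ylab = "observed ln(MLS)",
                 main = sprintf("alpha = %.2f, R = %.3f", x$alpha, x$R),
                 ...)
  graphics::abline(0, 1, lty = 2)
  if (any(x$outliers)) {
    graphics::text(pred[x$outliers], obs[x$outliers],
                   labels = x$species[x$outliers], pos = 3, cex = 0.7,
                   col = "red")
  }
  invisible(x)
}

#' Compare the distributions of ln(LEE) and ln(mtLEO)
#'
#' Overlaid kernel densities of lifetime energy expenditure (alpha = 1)
#' and mitochondrial lifetime energy output at the chosen alpha,
#' illustrating how the alpha optimization narrows the distribution.
#'
#' @param met_ref Metabolic table at alpha = 1 (see
#'   [derive_metabolism()]).
#' @param met_opt Metabolic table at the optimized alpha.
#' @export
plot_leo_distributions <- function(met_ref, met_opt) {
  d1 <- stats::density(log(met_ref$lee))
  d2 <- stats::density(log(met_opt$mtleo))
  graphics::plot(d1, lty = 2, xlim = range(d1$x, d2$x),
                 ylim = range(d1$y, d2$y),
                 xlab = "ln(lifetime energy output)",
                 main = "ln(LEE) vs ln(mtLEO)")
  graphics::lines(d2, lty = 1)
  graphics::legend("topright", bty = "n", lty = c(2, 1),
                   legend = c("LEE (alpha = 1)",
                              sprintf("mtLEO (alpha = %.2f)",
                                      attr(met_opt, "alpha"))))
  invisible(NULL)
}
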