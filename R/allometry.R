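#' Read a species trait table
#'
#' Expects a CSV with columns `species`, `mass_g` (body mass, g),
#' `bmr_w` (basal metabolic rate, W) and `mls_yr` (maximum lifespan, yr),
#' plus an optional `group` clade label (defaults to `"all"`) and an
#' optional per-species weight column `w`. This is the layout of an AnAge
#' export.
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
read_trait_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "mass_g", "bmr_w", "mls_yr")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("trait table misses column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(x$group)) x$group <- "all"
  validate_traits(x)
  x
}

validate_traits <- function(traits) {
  stopifnot(is.data.frame(traits))
  need <- c("species", "mass_g", "bmr_w", "mls_yr")
  miss <- setdiff(need, names(traits))
  if (length(miss)) stop("trait table misses column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(traits$species)) {
    stop("duplicated species in trait table: ",
         paste(unique(traits$species[duplicated(traits$species)]),
               collapse = ", "))
  }
  for (cl in c("mass_g", "bmr_w", "mls_yr")) {
    v <- traits[[cl]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("column '", cl, "' must be strictly positive and finite")
    }
  }
  invisible(traits)
}

#' Fit the allometric scaling law BMR = a * M^b
#'
#' Ordinary least squares of ln(BMR) on ln(M) across species;
#' `a = exp(intercept)` (W), `b = slope` (dimensionless).
#'
#' @param traits Trait `data.frame` (see [read_trait_table()]).
#' @return Object of class `"allometric_fit"`: list with `a`, `b`, `n`,
#'   `r2`, `r` and the underlying `lm` model.
#' @examples
#' tr <- data.frame(species = paste0("s", 1:5),
#'                  mass_g = c(10, 100, 1e3, 1e4, 1e5))
#' tr$bmr_w <- 0.02 * tr$mass_g^0.75
#' tr$mls_yr <- 10
#' fit_allometry(tr)  # recovers a = 0.02, b = 0.75
#' @export
fit_allometry <- function(traits) {
  validate_traits(traits)
  if (nrow(traits) < 3L) {
    stop("allometric fit needs at least 3 species, got ", nrow(traits))
  }
  fm <- stats::lm(log(bmr_w) ~ log(mass_g), data = traits)
  cf <- stats::coef(fm)
  r2 <- summary(fm)$r.squared
  structure(
    list(a = unname(exp(cf[1L])), b = unname(cf[2L]), n = nrow(traits),
         r2 = r2, r = sqrt(r2), model = fm),
    class = "allometric_fit"
  )
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("Allometric fit BMR = a * M^b: a = %.5g W, b = %.4f (n = %d, R = %.3f)\n",
              x$a, x$b, x$n, x$r))
  invisible(x)
}

#' Per-species allometric exponent B
#'
#' `B = ln(BMR/a) / ln(M)` is the exponent that reproduces each species'
#' observed BMR exactly under the fitted scale constant `a`:
#' `a * M^B = BMR` to machine precision.
#'
#' @param traits Trait `data.frame`.
#' @param fit An `"allometric_fit"`.
#' @return Numeric vector of B values, named by species.
#' @export
derive_exponent <- function(traits, fit) {
  validate_traits(traits)
  stopifnot(inherits(fit, "allometric_fit"))
  lm_ <- log(traits$mass_g)
  sing <- which(abs(lm_) < 1e-9)
  if (length(sing)) {
    stop("body mass of exactly 1 g makes ln(M) = 0 and B undefined for: ",
         paste(traits$species[sing], collapse = ", "),
         "; express mass in a unit where no species sits at exactly 1")
  }
  stats::setNames(log(traits$bmr_w / fit$a) / lm_, traits$species)
}

#' Alpha-parameterized mitochondrial metabolic rate
#'
#' `mtMR(alpha) = a * M^((B-1)/alpha)` (arbitrary units): a family of
#' mass-dependences that interpolates between the mass-specific BMR
#' (`alpha = 1`, where `mtMR = msBMR = a * M^(B-1) = BMR/M`) and a
#' mass-independent constant `a` (`alpha -> Inf`). On noiseless allometric
#' data with exponent `b`, the slope of `ln(mtMR)` vs `ln(M)` is
#' `(b-1)/alpha` (e.g. -0.125 at b = 0.75, alpha = 2).
#'
#' @inheritParams derive_exponent
#' @param alpha Free exponent-reshaping parameter, `>= 1`.
#' @return Numeric vector named by species.
#' @export
mtmr <- function(traits, fit, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 1) {
    stop("alpha must be a single finite value >= 1 (got ", alpha, ")")
  }
  B <- derive_exponent(traits, fit)
  stats::setNames(fit$a * traits$mass_g^((B - 1) / alpha), traits$species)
}

#' Derived metabolic quantities per species
#'
#' Computes for each species the exact exponent `B`, the mass-specific BMR
#' `msBMR = BMR/M` (W/g), the lifetime energy expenditure
#' `LEE = MLS * msBMR` (W yr/g), the alpha-parameterized `mtMR` and the
#' mitochondrial lifetime energy output `mtLEO = MLS * mtMR`. At
#' `alpha = 1`, `mtMR = msBMR` and `mtLEO = LEE` by construction.
#'
#' @inheritParams mtmr
#' @return `data.frame` with columns `species`, `B`, `msbmr`, `lee`,
#'   `mtmr`, `mtleo` and attribute `"alpha"`.
#' @export
derive_metabolism <- function(traits, fit, alpha = 1) {
  B <- derive_exponent(traits, fit)
  mt <- mtmr(traits, fit, alpha)
  out <- data.frame(
    species = traits$species,
    B = unname(B),
    msbmr = traits$bmr_w / traits$mass_g,
    lee = traits$mls_yr * traits$bmr_w / traits$mass_g,
    mtmr = unname(mt),
    mtleo = traits$mls_yr * unname(mt),
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  out
}
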