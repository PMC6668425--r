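#' Diet and enteric-methane isotope observations
#'
#' Loads the packaged 43-record table of paired (delta13C_diet,
#' delta13C_CH4) observations used to calibrate the diet-to-methane
#' regression. The packaged table is a synthetic stand-in constructed so that
#' an ordinary least-squares fit reproduces the published regression
#' statistics of the literature compilation it emulates; see the methods
#' vignette for the construction.
#'
#' @param path Optional path to an alternative CSV with the same columns:
#'   `species`, `d13c_diet`, `sd_diet`, `d13c_ch4`, `sd_ch4`, `year`,
#'   `source_id`, `provenance` (`"reported"` or `"composition"`).
#'
#' @return A tibble of observations.
#' @export
ruminant_diet_observations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diet_ch4_observations_synthetic.csv",
                        package = "rumisotope", mustWork = TRUE)
  }
  obs <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("species", "d13c_diet", "sd_diet", "d13c_ch4", "sd_ch4",
                  "year", "source_id", "provenance") %in% names(obs)))
  obs
}

#' Adjust composition-derived diet signatures to the measurement year
#'
#' Observations whose delta13C_diet was computed from feed composition use
#' category signatures referenced to 2012; they are shifted to the year the
#' methane was measured using the atmospheric delta13C-CO2 trend. Directly
#' reported diet signatures pass through unchanged.
#'
#' @param obs Observation tibble as from [ruminant_diet_observations()].
#' @param co2_series delta13C-CO2 series for [co2_adjustment()].
#'
#' @return The tibble with `d13c_diet` adjusted where `provenance ==
#'   "composition"`.
#' @export
adjust_observation_diet_delta <- function(obs, co2_series) {
  obs <- tibble::as_tibble(obs)
  comp <- obs$provenance == "composition"
  if (any(comp & is.na(obs$year))) {
    stop("composition-derived observation without a measurement year",
         call. = FALSE)
  }
  if (any(comp)) {
    obs$d13c_diet[comp] <- obs$d13c_diet[comp] +
      co2_adjustment(obs$year[comp], co2_series)
  }
  obs
}

#' Fit the diet-to-methane delta13C regression
#'
#' Linear regression of delta13C_CH4 on delta13C_diet, with measurement
#' uncertainty propagated by a perturb-and-refit Monte Carlo: both coordinates
#' of every observation are drawn from Gaussians centred on the observed
#' values with the stated per-point standard deviations, an ordinary
#' least-squares fit is run per draw, and the spread of the refitted
#' coefficients supplies the standard errors and parameter covariance. The
#' reported coefficients are those of the central (unperturbed) OLS fit, so
#' they are free of the regression-dilution attenuation that affects the mean
#' of errors-in-variables draws; the draw means are retained in the returned
#' object for inspection.
#'
#' @param obs Observation tibble with columns `d13c_diet`, `sd_diet`,
#'   `d13c_ch4`, `sd_ch4` (at least 3 rows).
#' @param n_draws Number of perturb-and-refit draws (default 2000).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return An object of class `diet_ch4_fit`: a list with `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `r_squared`, `cov` (2x2
#'   parameter covariance), `mc_mean` (draw-mean coefficients), `n_obs`,
#'   `n_draws` and `method`.
#' @export
fit_diet_ch4_regression <- function(obs, n_draws = 2000, seed = NULL) {
  obs <- tibble::as_tibble(obs)
  stopifnot(all(c("d13c_diet", "d13c_ch4", "sd_diet", "sd_ch4") %in%
                  names(obs)))
  n <- nrow(obs)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  x <- obs$d13c_diet
  y <- obs$d13c_ch4
  if (stats::sd(x) < 1e-12) {
    stop("degenerate delta13C_diet spread; regression not identifiable",
         call. = FALSE)
  }
  central <- stats::lm(y ~ x)
  r2 <- summary(central)$r.squared

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  xs <- matrix(stats::rnorm(n * n_draws, x, obs$sd_diet), nrow = n)
  ys <- matrix(stats::rnorm(n * n_draws, y, obs$sd_ch4), nrow = n)
  xbar <- colMeans(xs)
  ybar <- colMeans(ys)
  sxx <- colSums(xs^2) - n * xbar^2
  sxy <- colSums(xs * ys) - n * xbar * ybar
  slopes <- sxy / sxx
  intercepts <- ybar - slopes * xbar
  draws <- cbind(slope = slopes, intercept = intercepts)

  structure(
    list(
      slope = unname(stats::coef(central)[2]),
      intercept = unname(stats::coef(central)[1]),
      se_slope = stats::sd(slopes),
      se_intercept = stats::sd(intercepts),
      r_squared = r2,
      cov = stats::cov(draws),
      mc_mean = c(slope = mean(slopes), intercept = mean(intercepts)),
      n_obs = n,
      n_draws = n_draws,
      method = "perturb-and-refit OLS (errors in both variables)"
    ),
    class = "diet_ch4_fit"
  )
}

#' @export
print.diet_ch4_fit <- function(x, ...) {
  cat("Diet to enteric-CH4 delta13C regression\n")
  cat(sprintf("  delta13C_CH4 = %.3f x delta13C_diet %+.2f permil\n",
              x$slope, x$intercept))
  cat(sprintf("  SE(slope) = %.3f, SE(intercept) = %.2f permil, R2 = %.3f\n",
              x$se_slope, x$se_intercept, x$r_squared))
  cat(sprintf("  %d observations, %d Monte Carlo draws (%s)\n",
              x$n_obs, x$n_draws, x$method))
  invisible(x)
}

#' Predict delta13C of enteric methane from diet delta13C
#'
#' @param model A `diet_ch4_fit` object.
#' @param d13c_diet Diet signature(s), permil.
#' @param interval If `TRUE`, return a tibble with a 95% confidence band from
#'   the parameter covariance.
#'
#' @return Numeric vector, or a tibble with `fit`, `lwr`, `upr`.
#' @export
predict_delta13c_ch4 <- function(model, d13c_diet, interval = FALSE) {
  stopifnot(inherits(model, "diet_ch4_fit"))
  fit <- model$slope * d13c_diet + model$intercept
  if (!interval) return(fit)
  v <- model$cov["slope", "slope"] * d13c_diet^2 +
    2 * model$cov["slope", "intercept"] * d13c_diet +
    model$cov["intercept", "intercept"]
  half <- stats::qnorm(0.975) * sqrt(pmax(v, 0))
  tibble::tibble(fit = fit, lwr = fit - half, upr = fit + half)
}

#' Exact and linearized fractionation forms
#'
#' First-order kinetic isotope fractionation during rumen fermentation:
#' with `alpha = R_diet / R_CH4 = 1 + epsilon`, the exact form is
#' `delta13C_CH4 = (1000 + delta13C_diet) / (1 + epsilon/1000) - 1000`
#' and the usual linearization is
#' `delta13C_CH4 = delta13C_diet - epsilon`.
#' The sign convention stores `epsilon` as a positive discrimination in
#' permil (products depleted in 13C), so larger `epsilon` means lighter
#' methane.
#'
#' @param d13c_diet Diet signature(s), permil vs VPDB.
#' @param epsilon_permil Discrimination in permil; must satisfy
#'   `|epsilon| < 100` (i.e. |epsilon| < 0.1 as a fraction).
#'
#' @return A tibble with columns `exact` and `linear` (permil).
#' @export
epsilon_forms <- function(d13c_diet, epsilon_permil) {
  if (any(abs(epsilon_permil) >= 100)) {
    stop("|epsilon| must be below 100 permil", call. = FALSE)
  }
  alpha <- 1 + epsilon_permil / 1000
  if (any(alpha == 0)) stop("alpha = 0 is singular", call. = FALSE)
  tibble::tibble(
    exact = (1000 + d13c_diet) / alpha - 1000,
    linear = d13c_diet - epsilon_permil
  )
}

#' Flux-weighted isotopic signature
#'
#' Emission-weighted mean delta13C over countries (or any grouping):
#' `sum(F * delta) / sum(F)`.
#'
#' @param f Emission fluxes (weights), same length as `delta`.
#' @param delta delta13C values, permil.
#'
#' @return The weighted mean, permil.
#' @export
flux_weighted_signature <- function(f, delta) {
  stopifnot(length(f) == length(delta))
  if (any(f < 0)) stop("fluxes must be >= 0", call. = FALSE)
  if (sum(f) <= 0) stop("all-zero fluxes; weighted mean undefined",
                        call. = FALSE)
  sum(f * delta) / sum(f)
}
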