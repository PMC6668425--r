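#' Monte Carlo configuration
#'
#' Distribution specification for the uncertainty propagation: digestibilities
#' and the methane conversion factor are Gaussian around their central values
#' with the standard deviations carried by the parameter lists (truncated to
#' the physically valid ranges), the four feed-category signatures are
#' Gaussian with their stated sds, and the regression coefficients are drawn
#' multivariate-normal from the fit covariance. Parameters are drawn once per
#' ensemble member and shared across all countries and years (the stated
#' uncertainties are systematic, not per-country).
#'
#' @param n_ensemble Ensemble size (default 1000, >= 2).
#' @param seed Integer seed.
#' @param energy An [energy_params()] list.
#' @param emission An [emission_params()] list.
#' @param isotope An [isotope_params()] list.
#' @param regression A `diet_ch4_fit` object, or a list with elements `mean`
#'   (named `slope`, `intercept`) and `cov` (2x2), or `NULL` to hold the
#'   coefficients fixed at `slope = 0.91`, `intercept = -43.49` with zero
#'   variance.
#' @param f_de_bounds Truncation bounds for digestibility draws.
#'
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_ensemble = 1000, seed = 1,
                      energy = energy_params(),
                      emission = emission_params(),
                      isotope = isotope_params(),
                      regression = NULL,
                      f_de_bounds = c(0.3, 0.9)) {
  if (n_ensemble < 2) stop("n_ensemble must be >= 2", call. = FALSE)
  if (is.null(regression)) {
    regression <- list(mean = c(slope = 0.91, intercept = -43.49),
                       cov = matrix(0, 2, 2,
                                    dimnames = list(c("slope", "intercept"),
                                                    c("slope", "intercept"))))
  } else if (inherits(regression, "diet_ch4_fit")) {
    regression <- list(
      mean = c(slope = regression$slope, intercept = regression$intercept),
      cov = regression$cov)
  }
  if (!all(c("mean", "cov") %in% names(regression)) ||
      !all(dim(regression$cov) == c(2, 2))) {
    stop("invalid regression distribution spec", call. = FALSE)
  }
  structure(
    list(n_ensemble = n_ensemble, seed = seed, energy = energy,
         emission = emission, isotope = isotope, regression = regression,
         f_de_bounds = f_de_bounds),
    class = "mc_config"
  )
}

# Gaussian draw truncated to (lo, hi) by resampling
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lo | x >= hi)
  }
  x
}

#' Draw the Monte Carlo parameter ensemble
#'
#' @param config An [mc_config()].
#'
#' @return A tibble with `n_ensemble` rows and columns `f_de_concentrates`,
#'   `f_de_grass`, `f_de_so`, `y_m`, the four feed-category delta13C values,
#'   `slope` and `intercept`. Deterministic under the config seed.
#' @export
sample_parameters <- function(config = mc_config()) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  n <- config$n_ensemble
  en <- config$energy
  em <- config$emission
  iso <- config$isotope
  b <- config$f_de_bounds
  reg <- config$regression
  # MVN draw for the regression coefficients
  ch <- tryCatch(chol(reg$cov), error = function(e) NULL)
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  coefs <- if (is.null(ch) || all(reg$cov == 0)) {
    matrix(rep(reg$mean, each = n), ncol = 2)
  } else {
    sweep(z %*% ch, 2, reg$mean, "+")
  }
  tibble::tibble(
    f_de_concentrates = rnorm_trunc(n, en$f_de_concentrates,
                                    en$sd_f_de_concentrates, b[1], b[2]),
    f_de_grass = rnorm_trunc(n, en$f_de_grass, en$sd_f_de_grass, b[1], b[2]),
    f_de_so = rnorm_trunc(n, en$f_de_so, en$sd_f_de_so, b[1], b[2]),
    y_m = rnorm_trunc(n, em$y_m, em$sd_y_m, 0, Inf),
    d13c_c3_concentrates = stats::rnorm(n, iso$d13c_c3_concentrates,
                                        iso$sd_c3_concentrates),
    d13c_c3_grass_other = stats::rnorm(n, iso$d13c_c3_grass_other,
                                       iso$sd_c3_grass_other),
    d13c_c4_concentrates = stats::rnorm(n, iso$d13c_c4_concentrates,
                                        iso$sd_c4_concentrates),
    d13c_c4_grass_other = stats::rnorm(n, iso$d13c_c4_grass_other,
                                       iso$sd_c4_grass_other),
    slope = coefs[, 1],
    intercept = coefs[, 2]
  )
}

# deterministic pipeline for one parameter vector: returns global annual
# series of q_so, F_CH4, DM-weighted d13c_diet, flux-weighted d13c_ch4
pipeline_one_draw <- function(world, p, co2_adj, e_ge, e_ch4) {
  rem_c <- rem(p$f_de_concentrates)
  rem_g <- rem(p$f_de_grass)
  rem_s <- rem(p$f_de_so)
  q_conc <- world$q_c3_concentrates + world$q_c4_concentrates
  q_so <- (world$me -
             q_conc * e_ge * p$f_de_concentrates * rem_c -
             world$q_grass * e_ge * p$f_de_grass * rem_g) /
    (e_ge * p$f_de_so * rem_s)
  q_so <- pmax(q_so, 0)
  fr <- world$c4_grass_fraction
  q_c3 <- world$q_c3_concentrates + (world$q_grass + q_so) * (1 - fr)
  q_c4_go <- (world$q_grass + q_so) * fr
  total <- q_conc + world$q_grass + q_so
  d13c_diet <- (world$q_c3_concentrates * p$d13c_c3_concentrates +
                  world$q_c4_concentrates * p$d13c_c4_concentrates +
                  (world$q_grass + q_so) * (1 - fr) * p$d13c_c3_grass_other +
                  q_c4_go * p$d13c_c4_grass_other) / total + co2_adj
  f_ch4 <- total * e_ge * p$y_m / (e_ch4 * 1e9)
  d13c_ch4 <- p$slope * d13c_diet + p$intercept
  yr <- world$year
  f_glob <- rowsum(f_ch4, yr)
  list(
    years = sort(unique(yr)),
    q_so = as.numeric(rowsum(q_so, yr)),
    f_ch4 = as.numeric(f_glob),
    d13c_diet = as.numeric(rowsum(d13c_diet * total, yr) /
                             rowsum(total, yr)),
    d13c_ch4 = as.numeric(rowsum(d13c_ch4 * f_ch4, yr) / f_glob)
  )
}

#' Run the Monte Carlo ensemble through the pipeline
#'
#' Executes the full deterministic pipeline (energy balance, diet mixing,
#' Tier 2 emissions, regression application, flux weighting) once per
#' parameter draw and summarises global annual series of other-feed use,
#' diet delta13C, enteric emissions and the flux-weighted emission signature
#' as means, sds and empirical 2.5/97.5 percentiles.
#'
#' @param world A tibble with one row per country x year and columns
#'   `country`, `year`, `q_c3_concentrates`, `q_c4_concentrates`, `q_grass`,
#'   `c4_grass_fraction`, `me`.
#' @param draws Parameter draws from [sample_parameters()].
#' @param co2_series delta13C-CO2 series (for the diet adjustment).
#' @param e_ge Gross energy density, MJ (kg DM)^-1.
#' @param e_ch4 Energy content of methane, MJ (kg CH4)^-1.
#' @param max_failure_rate Abort when more than this fraction of draws fails
#'   (default 0.05).
#'
#' @return A list of class `ensemble_summary` with tibble `summary`
#'   (`variable`, `year`, `mean`, `sd`, `lo`, `hi`), the per-draw matrices in
#'   `draws` (variable -> n_draws x n_years matrix) and `n_failed`.
#' @export
run_ensemble <- function(world, draws, co2_series,
                         e_ge = 18.45, e_ch4 = 55.65,
                         max_failure_rate = 0.05) {
  world <- tibble::as_tibble(world)
  need <- c("country", "year", "q_c3_concentrates", "q_c4_concentrates",
            "q_grass", "c4_grass_fraction", "me")
  stopifnot(all(need %in% names(world)))
  co2_adj <- co2_adjustment(world$year, co2_series)
  n <- nrow(draws)
  years <- sort(unique(world$year))
  vars <- c("q_so", "f_ch4", "d13c_diet", "d13c_ch4")
  mats <- lapply(vars, function(v) {
    matrix(NA_real_, nrow = n, ncol = length(years))
  })
  names(mats) <- vars
  failed <- logical(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      pipeline_one_draw(world, draws[i, ], co2_adj, e_ge, e_ch4),
      error = function(e) NULL)
    if (is.null(res)) {
      failed[i] <- TRUE
    } else {
      for (v in vars) mats[[v]][i, ] <- res[[v]]
    }
  }
  if (mean(failed) > max_failure_rate) {
    stop(sum(failed), " of ", n, " ensemble draws failed (> ",
         100 * max_failure_rate, "%)", call. = FALSE)
  }
  summarise_mat <- function(m, v) {
    ok <- m[!failed, , drop = FALSE]
    tibble::tibble(
      variable = v, year = years,
      mean = colMeans(ok),
      sd = apply(ok, 2, stats::sd),
      lo = apply(ok, 2, stats::quantile, probs = 0.025, names = FALSE),
      hi = apply(ok, 2, stats::quantile, probs = 0.975, names = FALSE)
    )
  }
  summary <- dplyr::bind_rows(mapply(summarise_mat, mats, vars,
                                     SIMPLIFY = FALSE))
  structure(list(summary = summary, draws = mats, years = years,
                 n_failed = sum(failed)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Monte Carlo ensemble summary:",
      nrow(x$draws$f_ch4) - x$n_failed, "successful draws,",
      length(x$years), "years\n")
  print(utils::head(x$summary))
  invisible(x)
}
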