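#' Ruminant energy-balance parameters
#'
#' Gross energy density of feed and digestible energy fractions for the three
#' ruminant feed classes (concentrates, grass, stover + occasional). The
#' digestibility central values follow IPCC (2006) guidance: 80% for a
#' concentrate diet (95% CI 75-85%) and 55% for medium-quality forage
#' (95% CI 45-65%). 95% confidence intervals are converted to Gaussian
#' standard deviations as `(hi - lo) / 3.92` for Monte Carlo sampling.
#'
#' @param f_de_concentrates Digestible fraction of gross energy in concentrate
#'   feeds (dimensionless, default 0.80).
#' @param f_de_grass Digestible fraction for grass (default 0.55).
#' @param f_de_so Digestible fraction for stover and occasional feeds
#'   (default 0.55).
#' @param e_ge_feed Gross energy density of feed, MJ per kg dry matter
#'   (default 18.45).
#' @param sd_f_de_concentrates,sd_f_de_grass,sd_f_de_so Standard deviations
#'   used by the Monte Carlo module; defaults derive from the stated 95% CIs.
#'
#' @return A list of class `energy_params`.
#' @seealso [rem()], [solve_other_feeds()]
#' @export
energy_params <- function(f_de_concentrates = 0.80,
                          f_de_grass = 0.55,
                          f_de_so = 0.55,
                          e_ge_feed = 18.45,
                          sd_f_de_concentrates = (0.85 - 0.75) / 3.92,
                          sd_f_de_grass = (0.65 - 0.45) / 3.92,
                          sd_f_de_so = (0.65 - 0.45) / 3.92) {
  for (f in c(f_de_concentrates, f_de_grass, f_de_so)) {
    if (!is.numeric(f) || f <= 0 || f >= 1) {
      stop("digestible energy fractions must lie in (0, 1)", call. = FALSE)
    }
  }
  stopifnot(e_ge_feed > 0)
  structure(
    list(
      f_de_concentrates = f_de_concentrates,
      f_de_grass = f_de_grass,
      f_de_so = f_de_so,
      e_ge_feed = e_ge_feed,
      sd_f_de_concentrates = sd_f_de_concentrates,
      sd_f_de_grass = sd_f_de_grass,
      sd_f_de_so = sd_f_de_so
    ),
    class = "energy_params"
  )
}

#' Enteric emission parameters (IPCC Tier 2)
#'
#' The methane conversion factor `y_m` is the fraction of gross feed energy
#' converted to methane; the default 6.5% (95% CI +/- 1.0%) represents
#' widespread ruminant diets for cattle and mature sheep. `e_ch4` is the
#' energy content of methane.
#'
#' @param y_m Methane conversion factor as a fraction (default 0.065).
#' @param sd_y_m Standard deviation of `y_m` for Monte Carlo sampling;
#'   default converts the +/- 1.0% 95% CI (i.e. 0.01 / 1.96).
#' @param e_ch4 Energy content of methane, MJ per kg CH4 (default 55.65).
#'
#' @return A list of class `emission_params`.
#' @export
emission_params <- function(y_m = 0.065,
                            sd_y_m = 0.01 / 1.96,
                            e_ch4 = 55.65) {
  if (y_m <= 0 || y_m >= 0.15) {
    stop("y_m must lie in (0, 0.15)", call. = FALSE)
  }
  stopifnot(e_ch4 > 0)
  structure(
    list(y_m = y_m, sd_y_m = sd_y_m, e_ch4 = e_ch4),
    class = "emission_params"
  )
}

#' Feed-category carbon isotope signatures
#'
#' delta13C means and uncertainties for the four feed categories, all
#' referenced to the year 2012 (temporal variation is carried entirely by the
#' atmospheric delta13C-CO2 adjustment, see [co2_adjustment()]). The stated
#' uncertainty is treated as one standard deviation for Monte Carlo sampling.
#'
#' @param d13c_c3_concentrates,d13c_c3_grass_other,d13c_c4_concentrates,d13c_c4_grass_other
#'   Category means in permil vs VPDB.
#' @param sd_c3_concentrates,sd_c3_grass_other,sd_c4_concentrates,sd_c4_grass_other
#'   Category standard deviations in permil.
#' @param apply_co2_adjustment Logical; apply the atmospheric delta13C-CO2
#'   trend adjustment when computing diet signatures (default `TRUE`).
#'
#' @return A list of class `isotope_params`.
#' @export
isotope_params <- function(d13c_c3_concentrates = -25.10,
                           d13c_c3_grass_other = -28.25,
                           d13c_c4_concentrates = -12.24,
                           d13c_c4_grass_other = -13.3,
                           sd_c3_concentrates = 2.27,
                           sd_c3_grass_other = 1.68,
                           sd_c4_concentrates = 0.34,
                           sd_c4_grass_other = 1.1,
                           apply_co2_adjustment = TRUE) {
  deltas <- c(d13c_c3_concentrates, d13c_c3_grass_other,
              d13c_c4_concentrates, d13c_c4_grass_other)
  if (any(deltas <= -40) || any(deltas >= 0)) {
    stop("feed-category delta13C values must lie in (-40, 0) permil",
         call. = FALSE)
  }
  sds <- c(sd_c3_concentrates, sd_c3_grass_other,
           sd_c4_concentrates, sd_c4_grass_other)
  if (any(sds < 0)) stop("signature uncertainties must be >= 0", call. = FALSE)
  structure(
    list(
      d13c_c3_concentrates = d13c_c3_concentrates,
      d13c_c3_grass_other = d13c_c3_grass_other,
      d13c_c4_concentrates = d13c_c4_concentrates,
      d13c_c4_grass_other = d13c_c4_grass_other,
      sd_c3_concentrates = sd_c3_concentrates,
      sd_c3_grass_other = sd_c3_grass_other,
      sd_c4_concentrates = sd_c4_concentrates,
      sd_c4_grass_other = sd_c4_grass_other,
      apply_co2_adjustment = apply_co2_adjustment
    ),
    class = "isotope_params"
  )
}

#' Feed conversion ratio schedules
#'
#' Linear-in-time FCR schedules for monogastric production. Developed-country
#' anchors: poultry meat and eggs 1.95 kg DM (kg live-weight gain or kg
#' eggs)^-1 in 2005 declining at 0.01 yr^-1; pigs 3.28 kg DM (kg live-weight
#' gain)^-1 in 1995 declining at 0.015 yr^-1. Developing countries use a 1.2x
#' multiplier. Extrapolation is floored at `floor_frac` of the anchor value so
#' the ratio can never reach zero.
#'
#' @param poultry,egg,pig Lists with elements `base` (kg DM per kg), `anchor`
#'   (calendar year) and `rate` (change per year, negative for improvement).
#' @param developing_multiplier FCR multiplier for developing countries
#'   (default 1.2).
#' @param floor_frac Lower bound on extrapolated FCR as a fraction of the
#'   anchor value (default 0.5).
#'
#' @return A list of class `fcr_schedule`.
#' @export
fcr_schedule <- function(poultry = list(base = 1.95, anchor = 2005, rate = -0.01),
                         egg = list(base = 1.95, anchor = 2005, rate = -0.01),
                         pig = list(base = 3.28, anchor = 1995, rate = -0.015),
                         developing_multiplier = 1.2,
                         floor_frac = 0.5) {
  for (sp in list(poultry, egg, pig)) {
    stopifnot(is.list(sp), sp$base > 0)
  }
  structure(
    list(poultry = poultry, egg = egg, pig = pig,
         developing_multiplier = developing_multiplier,
         floor_frac = floor_frac),
    class = "fcr_schedule"
  )
}

#' Species feed-composition shares
#'
#' Which commodity groups poultry, laying hens and pigs draw their concentrate
#' ration from, as fixed proportions summing to one per species. The default
#' table is a documented stand-in for a German-diet-based ration model:
#' monogastrics draw on maize, other cereals, oilseed cakes, brans and pulses;
#' oilseeds and the residual "others" group are left to ruminants.
#'
#' @param shares A data frame with columns `species` (one of `"poultry_meat"`,
#'   `"eggs"`, `"pig"`), `group` (one of the seven commodity groups) and
#'   `share`. Shares must be non-negative and sum to 1 within species.
#'
#' @return A tibble validated as a share table.
#' @export
feed_composition_shares <- function(shares = NULL) {
  if (is.null(shares)) {
    shares <- tibble::tribble(
      ~species,       ~group,          ~share,
      "poultry_meat", "maize",          0.40,
      "poultry_meat", "other_cereals",  0.30,
      "poultry_meat", "cakes",          0.18,
      "poultry_meat", "brans",          0.08,
      "poultry_meat", "pulses",         0.04,
      "eggs",         "maize",          0.40,
      "eggs",         "other_cereals",  0.30,
      "eggs",         "cakes",          0.18,
      "eggs",         "brans",          0.08,
      "eggs",         "pulses",         0.04,
      "pig",          "maize",          0.30,
      "pig",          "other_cereals",  0.35,
      "pig",          "cakes",          0.15,
      "pig",          "brans",          0.15,
      "pig",          "pulses",         0.05
    )
  }
  shares <- tibble::as_tibble(shares)
  stopifnot(all(c("species", "group", "share") %in% names(shares)))
  if (any(shares$share < 0)) stop("shares must be >= 0", call. = FALSE)
  sums <- tapply(shares$share, shares$species, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    stop("shares must sum to 1 within each species", call. = FALSE)
  }
  bad <- setdiff(shares$group, commodity_groups())
  if (length(bad)) {
    stop("unknown commodity group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  shares
}

#' The seven concentrate feed commodity groups
#'
#' @return Character vector of group names.
#' @export
commodity_groups <- function() {
  c("maize", "other_cereals", "oilseeds", "cakes", "brans", "pulses", "others")
}

#' Dressing percentages
#'
#' Carcass weight as a fraction of live weight: 70% for poultry and 60% for
#' pigs.
#'
#' @param poultry,pig Dressing fractions in (0, 1].
#' @return A named list.
#' @export
dressing_fractions <- function(poultry = 0.70, pig = 0.60) {
  stopifnot(poultry > 0, poultry <= 1, pig > 0, pig <= 1)
  list(poultry = poultry, pig = pig)
}
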