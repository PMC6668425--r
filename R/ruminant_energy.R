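#' Fraction of digestible energy available for maintenance (REM)
#'
#' IPCC (2006) Vol. 4 Ch. 10 Eq. 10.14, with digestible energy expressed in
#' percent:
#' `REM = 1.123 - 4.092e-3 DE + 1.126e-5 DE^2 - 25.4 / DE`.
#'
#' @param f_de Digestible fraction of gross energy as a fraction in
#'   `[0.3, 0.9]` (the validity envelope enforced here).
#'
#' @return REM as a fraction in (0, 1). Vectorised.
#' @examples
#' rem(0.55) # about 0.469
#' @export
rem <- function(f_de) {
  if (any(f_de < 0.3) || any(f_de > 0.9)) {
    stop("f_de outside the validity envelope [0.3, 0.9]", call. = FALSE)
  }
  de <- f_de * 100
  out <- 1.123 - 4.092e-3 * de + 1.126e-5 * de^2 - 25.4 / de
  if (any(out <= 0) || any(out >= 1)) {
    stop("REM fell outside (0, 1); check digestibility input", call. = FALSE)
  }
  out
}

#' Solve the ruminant energy balance for stover and occasional feeds
#'
#' The metabolizable energy requirement of the national ruminant herd is met
#' by concentrates, grass and a residual class of stover and occasional feeds
#' ("other feeds"). Given ME (MJ yr^-1) and the first two feed quantities,
#' the other-feeds quantity is the closed-form solution of
#' `ME = sum_class Q * E_GE * f_DE * REM(f_DE)`.
#'
#' Negative solutions (inputs supplying more ME than required) are clamped to
#' zero and flagged.
#'
#' @param me Metabolizable energy requirement, MJ yr^-1 (vectorised).
#' @param q_concentrates,q_grass Feed quantities, kg DM.
#' @param params An [energy_params()] list.
#'
#' @return A tibble with columns `q_so` (kg DM) and logical `clamped`.
#' @export
solve_other_feeds <- function(me, q_concentrates, q_grass,
                              params = energy_params()) {
  if (any(me < 0) || any(q_concentrates < 0) || any(q_grass < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  e <- params$e_ge_feed
  me_conc <- q_concentrates * e * params$f_de_concentrates *
    rem(params$f_de_concentrates)
  me_grass <- q_grass * e * params$f_de_grass * rem(params$f_de_grass)
  denom <- e * params$f_de_so * rem(params$f_de_so)
  q_so <- (me - me_conc - me_grass) / denom
  clamped <- q_so < 0
  if (any(clamped)) {
    warning(sum(clamped), " country-year(s) with ME already exceeded by ",
            "concentrates + grass; other feeds clamped to zero", call. = FALSE)
  }
  tibble::tibble(q_so = pmax(q_so, 0), clamped = clamped)
}

#' Country-level C4 grass fraction from gridded inputs
#'
#' Averages a gridded C4 grass fraction to the country level, weighting each
#' grid cell by its grass-biomass use. Countries with zero total grass use get
#' a flagged neutral fraction of 0 with a warning.
#'
#' @param grid A tibble with columns `country`, `c4_fraction` and `grass_use`
#'   (one row per grid cell; `lat`/`lon` columns are allowed and ignored).
#'
#' @return A tibble with columns `country`, `c4_grass_fraction` and logical
#'   `flagged`.
#' @export
aggregate_c3c4_fractions <- function(grid) {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("country", "c4_fraction", "grass_use") %in% names(grid)))
  if (any(grid$c4_fraction < 0) || any(grid$c4_fraction > 1)) {
    stop("c4_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(grid$grass_use < 0)) stop("grass_use must be >= 0", call. = FALSE)
  out <- grid |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(
      total_use = sum(.data$grass_use),
      c4_grass_fraction = ifelse(
        .data$total_use > 0,
        sum(.data$c4_fraction * .data$grass_use) / .data$total_use, 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$total_use == 0) |>
    dplyr::select("country", "c4_grass_fraction", "flagged")
  if (any(out$flagged)) {
    warning("countries with zero grass use assigned a flagged fraction of 0: ",
            paste(out$country[out$flagged], collapse = ", "), call. = FALSE)
  }
  out
}

#' Assemble the six-pool ruminant diet basket
#'
#' Splits grass by the country C4 grass fraction and splits stover/occasional
#' feeds by the same C3:C4 ratio as grass (other feeds are produced and
#' consumed locally, so they follow the local grass C3/C4 geography).
#'
#' @param q_conc_c3,q_conc_c4 Ruminant concentrate pools, kg DM.
#' @param q_grass Total grass-biomass use, kg DM.
#' @param c4_grass_fraction Country C4 grass fraction in `[0, 1]`.
#' @param q_so Stover + occasional feeds, kg DM.
#'
#' @return A tibble with the six pools `q_c3_concentrates`,
#'   `q_c4_concentrates`, `q_c3_grass`, `q_c4_grass`, `q_c3_so`, `q_c4_so`.
#' @export
assemble_diet_basket <- function(q_conc_c3, q_conc_c4, q_grass,
                                 c4_grass_fraction, q_so) {
  if (any(c(q_conc_c3, q_conc_c4, q_grass, q_so) < 0)) {
    stop("feed quantities must be non-negative", call. = FALSE)
  }
  if (any(c4_grass_fraction < 0) || any(c4_grass_fraction > 1)) {
    stop("c4_grass_fraction must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    q_c3_concentrates = q_conc_c3,
    q_c4_concentrates = q_conc_c4,
    q_c3_grass = q_grass * (1 - c4_grass_fraction),
    q_c4_grass = q_grass * c4_grass_fraction,
    q_c3_so = q_so * (1 - c4_grass_fraction),
    q_c4_so = q_so * c4_grass_fraction
  )
}
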