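#' Atmospheric delta13C-CO2 adjustment factor
#'
#' Plants incorporate the delta13C of the CO2 they fix, so feed signatures
#' referenced to 2012 are shifted to year `j` by
#' `Delta(j) = delta13C_CO2(j) - delta13C_CO2(reference_year)`. No time lag is
#' applied between the atmospheric trend and the plant signature.
#'
#' @param year Calendar year(s) present in the series.
#' @param series A tibble with columns `year` and `d13c_co2` (permil vs VPDB).
#' @param reference_year Reference year of the feed-category signatures
#'   (default 2012).
#'
#' @return Adjustment in permil (vectorised over `year`).
#' @export
co2_adjustment <- function(year, series, reference_year = 2012) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("year", "d13c_co2") %in% names(series)))
  idx <- match(year, series$year)
  ref <- match(reference_year, series$year)
  if (anyNA(idx) || is.na(ref)) {
    stop("year(s) missing from the delta13C-CO2 series: ",
         paste(c(year[is.na(idx)], if (is.na(ref)) reference_year),
               collapse = ", "), call. = FALSE)
  }
  series$d13c_co2[idx] - series$d13c_co2[ref]
}

#' delta13C of the ruminant diet
#'
#' Mass-weighted mean of the four feed-category signatures over the six diet
#' pools, plus the atmospheric delta13C-CO2 adjustment for the year:
#' C3 concentrates, C4 concentrates, C3 grass + other feeds, C4 grass + other
#' feeds. Category values are constants of the reference year 2012; all
#' temporal variation flows through [co2_adjustment()].
#'
#' @param basket A diet basket from [assemble_diet_basket()] (rows are
#'   country-years).
#' @param params An [isotope_params()] list.
#' @param year Calendar year(s), recycled against the basket rows.
#' @param series delta13C-CO2 series for [co2_adjustment()]; may be `NULL`
#'   when `params$apply_co2_adjustment` is `FALSE`.
#'
#' @return delta13C_diet in permil vs VPDB (one value per basket row).
#' @export
diet_delta13c <- function(basket, params = isotope_params(),
                          year = 2012, series = NULL) {
  basket <- tibble::as_tibble(basket)
  pools <- c("q_c3_concentrates", "q_c4_concentrates", "q_c3_grass",
             "q_c4_grass", "q_c3_so", "q_c4_so")
  stopifnot(all(pools %in% names(basket)))
  total <- rowSums(basket[, pools])
  if (any(total <= 0)) {
    stop("diet basket with zero total dry matter", call. = FALSE)
  }
  num <- basket$q_c3_concentrates * params$d13c_c3_concentrates +
    basket$q_c4_concentrates * params$d13c_c4_concentrates +
    (basket$q_c3_grass + basket$q_c3_so) * params$d13c_c3_grass_other +
    (basket$q_c4_grass + basket$q_c4_so) * params$d13c_c4_grass_other
  delta <- num / total
  if (isTRUE(params$apply_co2_adjustment)) {
    if (is.null(series)) {
      stop("a delta13C-CO2 series is required when apply_co2_adjustment ",
           "is TRUE", call. = FALSE)
    }
    delta <- delta + co2_adjustment(rep_len(year, length(delta)), series)
  }
  delta
}
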