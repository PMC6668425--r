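#' Gross energy intake of a ruminant diet basket
#'
#' `GE = (sum of all six pools) x E_GE`, with the gross energy density of feed
#' E_GE = 18.45 MJ per kg dry matter by default.
#'
#' @param basket A diet basket from [assemble_diet_basket()], or a numeric
#'   vector of total dry matter intakes in kg.
#' @param e_ge_feed Gross energy density, MJ (kg DM)^-1.
#'
#' @return Gross energy in MJ (one value per basket row).
#' @export
gross_energy <- function(basket, e_ge_feed = 18.45) {
  if (is.numeric(basket)) {
    total <- basket
  } else {
    basket <- tibble::as_tibble(basket)
    pools <- c("q_c3_concentrates", "q_c4_concentrates", "q_c3_grass",
               "q_c4_grass", "q_c3_so", "q_c4_so")
    stopifnot(all(pools %in% names(basket)))
    total <- rowSums(basket[, pools])
  }
  if (any(total < 0)) stop("dry matter intake must be >= 0", call. = FALSE)
  total * e_ge_feed
}

#' Enteric methane emissions (IPCC Tier 2)
#'
#' `F = GE x Y_m / (E_CH4 x 1e9)`: the fraction `Y_m` of gross feed energy is
#' converted to methane with energy content `E_CH4` = 55.65 MJ (kg CH4)^-1;
#' the 1e9 converts kg to Tg.
#'
#' @param ge Gross energy intake, MJ (vectorised).
#' @param params An [emission_params()] list.
#'
#' @return Emissions in Tg CH4.
#' @examples
#' # 1000 kg DM of feed:
#' enteric_ch4(gross_energy(1000)) * 1e9 # about 21.55 kg CH4
#' @export
enteric_ch4 <- function(ge, params = emission_params()) {
  if (any(ge < 0)) stop("gross energy must be >= 0", call. = FALSE)
  ge * params$y_m / (params$e_ch4 * 1e9)
}
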