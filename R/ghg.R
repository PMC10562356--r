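## Greenhouse-gas accounting: CO2-equivalent conversion and net biome
## exchange (NBE). Canonical internal units are kgC ha-1 for stocks and
## harvest and gC m-2 for fluxes; every conversion lives here.

#' Accounting factors
#'
#' Immutable conversion factors: carbon to CO2 mass 44/12 (kept as the exact
#' ratio), 100-year global warming potentials 298 for N2O and 25 for CH4,
#' and the gC m-2 to kgC ha-1 multiplier 10.
#'
#' @return named list of factors.
#' @export
ghg_factors <- function() {
  list(carbon_to_co2 = 44 / 12, gwp_n2o = 298, gwp_ch4 = 25,
       gcm2_to_kgha = 10)
}

#' Convert carbon mass to CO2 mass
#'
#' @param mass_c carbon mass (any unit, sign preserved).
#' @return mass x 44/12.
#' @export
carbon_to_co2 <- function(mass_c) mass_c * (44 / 12)

#' CO2 equivalents of non-CO2 gases
#'
#' @param n2o_mass,ch4_mass non-negative gas masses.
#' @return 298 x N2O + 25 x CH4.
#' @export
gwp_co2eq <- function(n2o_mass, ch4_mass) {
  if (any(n2o_mass < 0) || any(ch4_mass < 0)) {
    stop("gas masses must be non-negative", call. = FALSE)
  }
  298 * n2o_mass + 25 * ch4_mass
}

#' Net biome exchange
#'
#' NBE = (NEE + harvested carbon) as CO2 plus the CO2 equivalents of N2O and
#' CH4 from drained organic soils, with NEE = -NEP:
#' `nbe = (-nep * 10 + harvested_c) * 44/12 + (298 * n2o + 25 * ch4) * 10`.
#' Negative NBE is a net GHG sink, positive a source.
#'
#' @param nep net ecosystem production, gC m-2 yr-1.
#' @param harvested_c harvested biomass carbon, kgC ha-1 yr-1.
#' @param n2o,ch4 gas fluxes, g m-2 yr-1 (zero except on drained organic
#'   soil).
#' @param soil_class optional vector; non-zero gas fluxes on `"mineral"`
#'   pixels are a contract error.
#' @return NBE, kgCO2eq ha-1 yr-1. All arguments vectorised.
#' @export
compute_nbe <- function(nep, harvested_c, n2o = 0, ch4 = 0, soil_class = NULL) {
  if (!is.null(soil_class) &&
      any(soil_class == "mineral" & (n2o != 0 | ch4 != 0))) {
    stop("non-CO2 gas fluxes supplied for mineral-soil pixels", call. = FALSE)
  }
  (-nep * 10 + harvested_c) * (44 / 12) + (298 * n2o + 25 * ch4) * 10
}

#' Aggregate regional per-area values to country level
#'
#' Area-weighted mean of the regional values; the corresponding total
#' (sum of value x area) is attached as attribute `total`.
#'
#' @param region_values per-area values, one per region.
#' @param region_areas positive region areas (any common unit).
#' @return country per-area value with attribute `total`.
#' @export
aggregate_country <- function(region_values, region_areas) {
  if (length(region_values) != length(region_areas)) {
    stop("region_values and region_areas lengths differ", call. = FALSE)
  }
  if (any(region_areas <= 0)) stop("region areas must be > 0", call. = FALSE)
  total <- sum(region_values * region_areas)
  structure(total / sum(region_areas), total = total)
}
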