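## Mineral-soil carbon: a three-pool first-order decay chain (fast litter,
## slow, humus-like) with decay rates spanning two orders of magnitude and
## cascading transfers; drained organic soils carry static emission
## coefficients and a constant sampled peat carbon stock instead.

#' Create soil pool matrix
#'
#' @param n number of pixels.
#' @param fast,slow,humus initial stocks, kgC ha-1 (recycled to length `n`).
#' @return numeric matrix `n x 3` with columns fast, slow, humus.
#' @export
soil_pools <- function(n, fast = 0, slow = 0, humus = 0) {
  m <- cbind(fast = rep_len(fast, n), slow = rep_len(slow, n),
             humus = rep_len(humus, n))
  if (any(m < 0)) stop("soil pools must be non-negative", call. = FALSE)
  m
}

#' One annual mineral-soil step
#'
#' First-order decay of each pool, optionally temperature-modified by a Q10
#' response around 5 deg C mean air temperature. A fraction of the fast-pool
#' loss transfers to the slow pool and of the slow-pool loss to the humus
#' pool; the remainder and the whole humus loss are heterotrophic
#' respiration. Litter enters the fast pool. Mass balance is exact:
#' `delta(total) = litter_in - respiration`.
#'
#' @param pools matrix from [soil_pools()].
#' @param litter_in non-negative litter input per pixel, kgC ha-1 yr-1.
#' @param weather_summary optional list with `mean_tair` (deg C) enabling the
#'   Q10 modifier; `NULL` leaves rates unmodified.
#' @param params an `fc_params` (uses the soil pool: k_fast, k_slow, k_humus,
#'   t_fast_slow, t_slow_humus, q10).
#' @return list with `pools` (updated matrix) and `respiration` (vector,
#'   kgC ha-1 yr-1).
#' @export
mineral_soil_step <- function(pools, litter_in, weather_summary = NULL,
                              params = default_parameter_set()) {
  if (any(litter_in < 0)) stop("litter_in must be non-negative", call. = FALSE)
  ys <- params$yasso
  tmod <- if (!is.null(weather_summary) && !is.null(weather_summary$mean_tair)) {
    ys[["q10"]]^((weather_summary$mean_tair - 5) / 10)
  } else 1
  k <- pmin(c(ys[["k_fast"]], ys[["k_slow"]], ys[["k_humus"]]) * tmod, 1)
  loss_f <- k[1] * as.vector(pools[, 1])
  loss_s <- k[2] * as.vector(pools[, 2])
  loss_h <- k[3] * as.vector(pools[, 3])
  litter_in <- as.vector(litter_in)
  t12 <- ys[["t_fast_slow"]]
  t23 <- ys[["t_slow_humus"]]
  new <- pools
  new[, 1] <- pools[, 1] - loss_f + litter_in
  new[, 2] <- pools[, 2] - loss_s + t12 * loss_f
  new[, 3] <- pools[, 3] - loss_h + t23 * loss_s
  resp <- (1 - t12) * loss_f + (1 - t23) * loss_s + loss_h
  list(pools = new, respiration = resp)
}

#' Iterate soil pools to steady state
#'
#' Repeats cycles of annual steps until the relative change of the mean total
#' soil carbon between successive cycles falls below `tolerance`, or
#' `max_cycles` is reached (then flagged, not an error).
#'
#' @param litter_fun function(cycle) returning a matrix (years x pixels) or
#'   vector of annual litter inputs for one cycle, kgC ha-1 yr-1.
#' @param pools0 initial pool matrix.
#' @param params an `fc_params`.
#' @param tolerance relative-change convergence criterion (> 0).
#' @param max_cycles cycle cap.
#' @param years_per_cycle annual steps per cycle.
#' @param weather_summaries optional list (length `years_per_cycle`) of
#'   summaries passed to [mineral_soil_step()].
#' @return list with `pools`, `converged` (logical), `cycles`.
#' @export
spin_up_pools <- function(litter_fun, pools0, params = default_parameter_set(),
                          tolerance = 1e-4, max_cycles = 300,
                          years_per_cycle = 7, weather_summaries = NULL) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  pools <- pools0
  prev_total <- mean(rowSums(pools))
  for (cycle in seq_len(max_cycles)) {
    litter <- litter_fun(cycle)
    if (is.null(dim(litter))) litter <- matrix(litter, nrow = years_per_cycle,
                                               ncol = nrow(pools))
    for (y in seq_len(years_per_cycle)) {
      ws <- if (is.null(weather_summaries)) NULL else weather_summaries[[y]]
      pools <- mineral_soil_step(pools, litter[y, ], ws, params)$pools
    }
    total <- mean(rowSums(pools))
    if (abs(total - prev_total) <= tolerance * max(total, .Machine$double.eps)) {
      return(list(pools = pools, converged = TRUE, cycles = cycle))
    }
    prev_total <- total
  }
  warning("soil spin-up did not converge within max_cycles", call. = FALSE)
  list(pools = pools, converged = FALSE, cycles = max_cycles)
}

#' Spin up soil under the coupled stand model
#'
#' Emulates the initial-state construction: the coupled stand + soil model is
#' run over randomly ordered repetitions of the seven historical years
#' (weather and realised harvest levels), resetting the stand to its initial
#' state each cycle while the soil pools carry over, until the mean total
#' soil carbon is stationary between cycles. The resulting state depends on
#' the sampled initial stand and the parameter set, as intended.
#'
#' @param stand initial `fc_stand` (reset at every cycle start).
#' @param weather_hist `fc_weather` covering the 7 historical years.
#' @param harvest_fracs per-historical-year fraction of stem volume removed
#'   (length 7), emulating realised harvest pressure during spin-up.
#' @param params an `fc_params`.
#' @param tolerance,max_cycles convergence control (see [spin_up_pools()]).
#' @return list with `pools`, `converged`, `cycles`. Uses the current RNG
#'   state for the random year ordering.
#' @export
spin_up_soil <- function(stand, weather_hist, harvest_fracs = rep(0.02, 7),
                         params = default_parameter_set(),
                         tolerance = 1e-4, max_cycles = 300) {
  years <- unique(weather_hist$year)
  nyr <- length(years)
  mineral <- stand$soil_class == "mineral"
  ## pre-split weather and summaries once
  wy <- lapply(years, function(y) weather_hist[weather_hist$year == y, ])
  ws <- lapply(wy, function(w) list(mean_tair = mean(w$tair)))
  n <- nrow(stand)
  ## analytic warm start: one probe cycle estimates the mean litter flux and
  ## temperature modifier, and the pools start at the linear-chain fixed
  ## point for that forcing, so the iteration refines rather than fills
  probe <- {
    st <- stand
    lit <- matrix(0, nyr, n)
    for (j in seq_len(nyr)) {
      gpp <- annual_gpp(st, wy[[j]], params)
      step <- grow_stand(st, gpp, params)
      st <- step$stand
      lit[j, ] <- step$flux$litter + step$flux$mort_litter
    }
    colMeans(lit)
  }
  ys <- params$yasso
  tmod_mean <- mean(vapply(ws, function(w) ys[["q10"]]^((w$mean_tair - 5) / 10),
                           numeric(1)))
  kf <- min(ys[["k_fast"]] * tmod_mean, 1)
  ks <- min(ys[["k_slow"]] * tmod_mean, 1)
  kh <- min(ys[["k_humus"]] * tmod_mean, 1)
  pools <- cbind(fast = probe / kf,
                 slow = ys[["t_fast_slow"]] * probe / ks,
                 humus = ys[["t_fast_slow"]] * ys[["t_slow_humus"]] * probe / kh)
  prev_total <- 0
  converged <- FALSE
  cycles <- max_cycles
  for (cycle in seq_len(max_cycles)) {
    st <- stand
    ord <- sample.int(nyr)
    for (j in ord) {
      gpp <- annual_gpp(st, wy[[j]], params)
      step <- grow_stand(st, gpp, params)
      st <- step$stand
      ## harvest pressure: fractional stem removal, residues become litter
      f <- harvest_fracs[j]
      removed_c <- f * st$tree_c
      resid_litter <- removed_c * (1 - params$crobas[["stem_frac"]]) * 0.5
      st$tree_c <- st$tree_c - removed_c
      st$stem_vol <- st$stem_vol * (1 - f)
      litter <- step$flux$litter + step$flux$mort_litter + resid_litter
      pools <- mineral_soil_step(pools, litter, ws[[j]], params)$pools
    }
    total <- mean(rowSums(pools[mineral, , drop = FALSE]))
    if (cycle > 1 &&
        abs(total - prev_total) <= tolerance * max(total, .Machine$double.eps)) {
      converged <- TRUE
      cycles <- cycle
      break
    }
    prev_total <- total
  }
  if (!converged) warning("soil spin-up did not converge within max_cycles",
                          call. = FALSE)
  list(pools = pools, converged = converged, cycles = cycles)
}

#' Drained organic soil emission coefficient table
#'
#' Five coefficients by emission type: CH4 for all sites, N2O and CO2 each
#' split into nutrient-rich (site types 1--3) and nutrient-poor (> 3)
#' classes. Default means and standard deviations are the national
#' coefficients: CH4 (0.34, 0.12) gCH4 m-2 yr-1; N2O rich (0.23, 0.04) and
#' poor (0.077, 0.004) gN2O m-2 yr-1; CO2 rich (240, 70) and poor (-70, 30)
#' gCO2 m-2 yr-1 (a negative coefficient is soil uptake).
#'
#' @param means,sds length-5 numeric overrides in emission-type order.
#' @return data.frame of class `fc_ef_table` with columns et, gas,
#'   site_group, unit, mean, sd, value (`value` starts at `mean`).
#' @export
emission_coefficient_table <- function(means = c(0.34, 0.23, 0.077, 240, -70),
                                       sds = c(0.12, 0.04, 0.004, 70, 30)) {
  if (any(sds < 0)) stop("emission coefficient sds must be >= 0", call. = FALSE)
  out <- data.frame(
    et = 1:5,
    gas = c("CH4", "N2O", "N2O", "CO2", "CO2"),
    site_group = c("all", "1-3", ">3", "1-3", ">3"),
    unit = c("gCH4 m-2 yr-1", "gN2O m-2 yr-1", "gN2O m-2 yr-1",
             "gCO2 m-2 yr-1", "gCO2 m-2 yr-1"),
    mean = means, sd = sds, value = means,
    stringsAsFactors = FALSE)
  class(out) <- c("fc_ef_table", "data.frame")
  out
}

#' Sample emission coefficients
#'
#' Draws each coefficient independently from Normal(mean, sd^2). Gases that
#' are strictly positive quantities (CH4, N2O) are truncated at zero (the
#' number of truncations is recorded in attribute `truncated`); the CO2
#' coefficients keep their sign, which is meaningful (uptake). One draw is
#' held constant for a whole simulation, all pixels and regions.
#'
#' @param table an [emission_coefficient_table()].
#' @return the table with a new `value` column. Uses the current RNG state.
#' @export
sample_emission_coefficients <- function(table = emission_coefficient_table()) {
  v <- stats::rnorm(5, table$mean, table$sd)
  nonneg <- table$gas %in% c("CH4", "N2O")
  truncated <- sum(nonneg & v < 0)
  v[nonneg] <- pmax(v[nonneg], 0)
  table$value <- v
  attr(table, "truncated") <- truncated
  table
}

#' Organic-soil GHG emissions by site type
#'
#' Static per-area fluxes for drained organic soil pixels: site types 1--3
#' take the nutrient-rich N2O and CO2 coefficients, types above 3 the
#' nutrient-poor ones; the CH4 coefficient applies everywhere.
#'
#' @param site_type integer 1..5, vectorised.
#' @param coefficients an `fc_ef_table` (its `value` column is used).
#' @param soil_class optional vector; any `"mineral"` entry is a contract
#'   error, since mineral soils carry dynamic pools instead.
#' @return data.frame with columns co2 (gCO2 m-2 yr-1), ch4 (gCH4 m-2 yr-1),
#'   n2o (gN2O m-2 yr-1).
#' @export
organic_soil_emissions <- function(site_type, coefficients = emission_coefficient_table(),
                                   soil_class = NULL) {
  if (!is.null(soil_class) && any(soil_class == "mineral")) {
    stop("organic_soil_emissions called for mineral-soil pixels", call. = FALSE)
  }
  if (any(!site_type %in% 1:5)) stop("site_type must be in 1..5", call. = FALSE)
  rich <- site_type <= 3
  v <- coefficients$value
  data.frame(co2 = ifelse(rich, v[4], v[5]),
             ch4 = rep(v[1], length(site_type)),
             n2o = ifelse(rich, v[2], v[3]))
}

#' Sample the peat carbon stock
#'
#' One Normal(543400, 18500^2) kgC ha-1 draw per simulation, applied to every
#' drained-organic-soil pixel and held constant over the simulated years.
#'
#' @param mean,sd distribution parameters, kgC ha-1.
#' @return a positive scalar stock. Uses the current RNG state.
#' @export
sample_peat_stock <- function(mean = 543400, sd = 18500) {
  max(stats::rnorm(1, mean, sd), 0)
}
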