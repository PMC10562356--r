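# lazily built, memoised ensembles shared across test files; sizes are the
# package's test-scale study conditions

.ens_cache <- new.env(parent = emptyenv())

# 4 heterogeneous regions, mean 500 pixels, 50 simulations, one RCP x four
# harvest intensities
shared_ensemble <- function() {
  if (is.null(.ens_cache$shared)) {
    landscape <- generate_landscape(n_regions = 4, segments_per_region = 1000,
                                    seed = 1)
    cfg <- simulation_config(n_sim = 50, n_pixels = 500, master_seed = 1)
    .ens_cache$shared <- run_monte_carlo(
      landscape, scenario_grid("RCP4.5",
                               c("NoHarv", "LowHarv", "BaseHarv", "MaxHarv")),
      cfg)
  }
  .ens_cache$shared
}

# small ensemble whose only substantive between-run variation is the harvest
# scenario: single-vector parameter pools, so parameter columns are constant
harvest_only_ensemble <- function() {
  if (is.null(.ens_cache$harvest_only)) {
    landscape <- generate_landscape(n_regions = 2, segments_per_region = 400,
                                    seed = 11, n_pool = 1)
    cfg <- simulation_config(n_sim = 15, n_pixels = 150, master_seed = 11,
                             years = 2015:2035)
    .ens_cache$harvest_only <- run_monte_carlo(
      landscape, scenario_grid("RCP4.5", c("LowHarv", "BaseHarv", "MaxHarv")),
      cfg)
  }
  .ens_cache$harvest_only
}

# country-level area-weighted aggregate of one output, per (harv, sim)
country_by_sim <- function(ensemble, year, var) {
  d <- ensemble$outputs
  d <- d[d$year == year, ]
  sp <- split(d, paste(d$harv, d$sim, sep = "|"))
  key <- do.call(rbind, strsplit(names(sp), "|", fixed = TRUE))
  data.frame(harv = key[, 1], sim = as.integer(key[, 2]),
             value = vapply(sp, function(x) as.numeric(
               aggregate_country(x[[var]], ensemble$region_areas[x$region])),
               numeric(1)),
             row.names = NULL)
}
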