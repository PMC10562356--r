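# shared fixtures, all built in code

# a minimal stand data.frame with the columns the model expects
make_stand <- function(n = 1, tree_c = 50000, gv_c = 500, basal_area = 20,
                       dbh = 22, height = 18, age = 60,
                       prop_pine = 1, prop_spruce = 0, prop_birch = 0,
                       stem_vol = 150, n_stems = 600, crown_height = 8,
                       site_type = 3, soil_class = "mineral",
                       land_class = "productive") {
  out <- data.frame(
    pixel_id = seq_len(n),
    tree_c = rep_len(tree_c, n), gv_c = rep_len(gv_c, n),
    basal_area = rep_len(basal_area, n), dbh = rep_len(dbh, n),
    height = rep_len(height, n), age = rep_len(age, n),
    prop_pine = rep_len(prop_pine, n), prop_spruce = rep_len(prop_spruce, n),
    prop_birch = rep_len(prop_birch, n),
    stem_vol = rep_len(stem_vol, n), n_stems = rep_len(n_stems, n),
    crown_height = rep_len(crown_height, n),
    crown_ratio = pmin(1, rep_len(crown_height, n) /
                         pmax(rep_len(height, n), 1e-9)),
    site_type = rep_len(site_type, n),
    soil_class = rep_len(soil_class, n), land_class = rep_len(land_class, n),
    stringsAsFactors = FALSE)
  class(out) <- c("fc_stand", "data.frame")
  out
}

# constant synthetic weather year: every day identical drivers
flat_weather_year <- function(rad = 12, tair = 12, vpd = 0.5, precip = 2,
                              co2 = 400, year = 2015) {
  data.frame(year = year, doy = 1:365, rad = rad, tair = tair, vpd = vpd,
             precip = precip, co2 = co2)
}

# parameter set with selected components overridden
params_with <- function(crobas = NULL, preles = NULL, yasso = NULL) {
  p <- default_parameter_set()
  for (nm in names(crobas)) p$crobas[[nm]] <- crobas[[nm]]
  for (nm in names(preles)) p$preles[[nm]] <- preles[[nm]]
  for (nm in names(yasso)) p$yasso[[nm]] <- yasso[[nm]]
  p
}
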