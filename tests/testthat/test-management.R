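test_that("eligibility respects land class and triggers", {
  rules <- harvest_rules()
  # protected land exceeding every trigger is never harvested
  prot <- make_stand(age = 150, dbh = 40, height = 30, basal_area = 40,
                     land_class = "protected")
  expect_equal(eligible_action(prot, rules), "none")
  poor <- make_stand(age = 150, dbh = 40, land_class = "poorly_productive")
  expect_equal(eligible_action(poor, rules), "none")
  # young sparse stand below all triggers
  young <- make_stand(age = 15, dbh = 8, height = 7, basal_area = 10)
  expect_equal(eligible_action(young, rules), "none")
  # age alone triggers a clearcut under the OR combinator (pine: 80 y)
  old <- make_stand(age = 85, dbh = 15, height = 14, basal_area = 18)
  expect_equal(eligible_action(old, rules), "clearcut")
  # dense mid-aged stand is thinned (pine thinning trigger 26 m2/ha)
  dense <- make_stand(age = 40, dbh = 16, height = 15, basal_area = 30)
  expect_equal(eligible_action(dense, rules), "thinning")
  # AND combinator requires all three clearcut conditions
  rules_and <- harvest_rules(clearcut_combinator = "and")
  expect_equal(eligible_action(old, rules_and), "none")
})

test_that("scenario targets apply the published multipliers", {
  expect_equal(scenario_targets(100, "MaxHarv"), 120)
  expect_equal(scenario_targets(100, "LowHarv"), 60)
  expect_equal(scenario_targets(100, "BaseHarv"), 100)
  expect_equal(scenario_targets(123.4, "NoHarv"), 0)
  expect_error(scenario_targets(-1, "BaseHarv"), ">= 0")
})

test_that("country harvest target noise has a 2% coefficient of variation", {
  set.seed(21)
  draws <- vapply(1:1e5, function(i) sample_country_target(70), numeric(1))
  expect_lt(abs(sd(draws) / mean(draws) - 0.02), 0.001)
  expect_equal(sample_country_target(0), 0)
  set.seed(5); a <- sample_country_target(70)
  set.seed(5); b <- sample_country_target(70)
  expect_identical(a, b)
})

test_that("country-to-region allocation is share-exact and conserving", {
  expect_equal(allocate_country_to_regions(100, c(0.5, 0.3, 0.2)),
               c(50, 30, 20))
  expect_equal(allocate_country_to_regions(77, 1), 77)
  expect_error(allocate_country_to_regions(100, c(0.6, 0.6)), "sum to 1")
  set.seed(4)
  for (i in 1:50) {
    sh <- stats::rgamma(5, 1); sh <- sh / sum(sh)
    expect_equal(sum(allocate_country_to_regions(123.4, sh)), 123.4,
                 tolerance = 1e-9)
  }
})

## three clearcut-eligible pixels, 50 m3 yield each (residues left on site)
trace_stand <- function(yields_m3, p = default_parameter_set()) {
  n <- length(yields_m3)
  make_stand(n, age = 100, dbh = 30, height = 26, basal_area = 25,
             stem_vol = yields_m3,
             tree_c = yields_m3 * p$crobas[["c_per_m3"]] / p$crobas[["stem_frac"]])
}

test_that("allocation stop rule and shortfall match hand-derived traces", {
  rules <- harvest_rules(energy_wood_fraction = 0)   # round wood only
  st <- trace_stand(c(50, 50, 50))
  set.seed(1)
  out <- allocate_regional_harvest(st, 60, rules, rep_area_ha = 1)
  expect_length(out$harvested_ids, 2)     # stop after the 2nd pixel
  expect_equal(out$realized_round, 100)
  expect_equal(out$shortfall, 0)
  # eligible total 80 against target 120: all cut, shortfall 40
  st2 <- trace_stand(c(30, 30, 20))
  set.seed(2)
  out2 <- allocate_regional_harvest(st2, 120, rules, rep_area_ha = 1)
  expect_equal(out2$realized_round, 80)
  expect_equal(out2$shortfall, 40)
  expect_length(out2$harvested_ids, 3)
  # zero target harvests nothing
  out0 <- allocate_regional_harvest(st, 0, rules, rep_area_ha = 1)
  expect_length(out0$harvested_ids, 0)
  expect_equal(out0$stand$tree_c, st$tree_c)
})

test_that("clearcut resets state and conserves carbon to harvest plus litter", {
  p <- default_parameter_set()
  rules <- harvest_rules(energy_wood_fraction = 0.5)
  st <- trace_stand(c(50, 50, 50))
  set.seed(3)
  out <- allocate_regional_harvest(st, 1e4, rules, rep_area_ha = 1, params = p)
  expect_length(out$harvested_ids, 3)
  cut <- out$stand
  expect_true(all(cut$age[out$harvested_ids] == 0))
  expect_true(all(cut$tree_c[out$harvested_ids] == 0))
  removed <- st$tree_c - cut$tree_c
  expect_equal(removed, out$harvested_c + out$residue_litter_c,
               tolerance = 1e-9)
  expect_gt(out$realized_energy, 0)
  expect_error(allocate_regional_harvest(st, -5, rules, 1), ">= 0")
})

test_that("thinning removes the configured fraction and keeps stocks valid", {
  p <- default_parameter_set()
  rules <- harvest_rules()
  st <- make_stand(1, age = 40, dbh = 16, height = 15, basal_area = 30,
                   stem_vol = 180, tree_c = 180 * 300)
  set.seed(1)
  out <- allocate_regional_harvest(st, 1e4, rules, rep_area_ha = 1, params = p)
  expect_equal(out$actions, "thinning")
  expect_equal(out$stand$basal_area, 30 * 0.7, tolerance = 1e-12)
  expect_equal(out$stand$stem_vol, 180 * 0.7, tolerance = 1e-12)
  expect_true(all(out$stand$tree_c >= 0))
  removed <- st$tree_c - out$stand$tree_c
  expect_equal(removed, out$harvested_c + out$residue_litter_c,
               tolerance = 1e-9)
})

test_that("the random harvest order is uniform over eligible pixels", {
  rules <- harvest_rules(energy_wood_fraction = 0)
  st <- trace_stand(rep(50, 5))
  hits <- integer(5)
  set.seed(17)
  n_rep <- 2000
  for (i in seq_len(n_rep)) {
    out <- allocate_regional_harvest(st, 60, rules, rep_area_ha = 1)
    hits[out$harvested_ids] <- hits[out$harvested_ids] + 1
  }
  # each replicate harvests exactly 2 of 5; uniform expectation 2/5 each
  expect_equal(sum(hits), 2 * n_rep)
  expect_gt(stats::chisq.test(hits)$p.value, 0.01)
})

test_that("harvest rule validation rejects malformed rules", {
  expect_error(harvest_rules(species = data.frame(
    species = "pine", clearcut_dbh = 26, clearcut_height = 25,
    clearcut_age = 80, thin_ba = 26, thin_removal = 1.2)), "\\(0,1\\)")
})
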