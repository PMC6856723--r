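test_that("strain panels have the specified composition and all grow", {
  p1 <- generate_strain_panel(panel_spec(0, TRUE, FALSE, seed = 1))
  expect_length(p1, 1)
  expect_gt(standalone_growth(p1[[1]]), 0)

  p5 <- generate_strain_panel(panel_spec(3, TRUE, TRUE, seed = 7))
  expect_length(p5, 5)
  expect_true(all(vapply(p5, standalone_growth, 0) > 0))
  # exactly the two keystones carry sulfur chemistry
  has_sulfur <- vapply(p5, function(r) {
    smet <- met_key(r$metabolites$id, r$metabolites$compartment)[r$metabolites$is_sulfur]
    any(vapply(r$reactions, function(x) any(names(x$stoichiometry) %in% smet), FALSE))
  }, FALSE)
  expect_equal(sum(has_sulfur), 2)
  expect_setequal(names(p5)[has_sulfur], c("mucin_degrader", "taurine_respirer"))
})

test_that("the mucin degrader secretes methionine under standalone FBA", {
  recon <- generate_strain_panel(panel_spec(0, TRUE, FALSE, seed = 1))[[1]]
  dt <- toy_european_diet()
  constrained <- recon
  constrained$reactions <- lapply(recon$reactions, function(rxn) {
    if (is_exchange(rxn) && rxn$lb < 0) {
      base <- sub("\\[[a-z]+\\]$", "", names(rxn$stoichiometry))
      rxn$lb <- if (base %in% names(dt$uptake_bounds)) -dt$uptake_bounds[[base]] else 0
    }
    rxn
  })
  sol <- fba(constrained, "EX_met_L", "max")
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
})

test_that("abundance profiles sum to one and respond to the keystone shift", {
  panel <- generate_strain_panel(panel_spec(3, TRUE, TRUE, seed = 7))
  pr <- generate_abundance_profiles(panel, 20, 20, keystone_shift = 0, seed = 2)
  sums <- vapply(pr$profiles, function(p) sum(p$abundances), 0)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(vapply(pr$profiles, function(p) all(p$abundances >= 0), TRUE)))

  # null shift: large-sample group means agree
  pr0 <- generate_abundance_profiles(panel, 400, 400, keystone_shift = 0, seed = 3)
  ab0 <- vapply(pr0$profiles, function(p) p$abundances[["taurine_respirer"]], 0)
  g0 <- pr0$groups$group == "PD"
  expect_gt(t.test(ab0[g0], ab0[!g0])$p.value, 0.01)

  # shift 0.7 at n = 200/200: one-sided Welch detects it in nearly all seeds
  hits <- vapply(1:30, function(s) {
    pr <- generate_abundance_profiles(panel, 200, 200, keystone_shift = 0.7, seed = s)
    ab <- vapply(pr$profiles, function(p)
      sum(p$abundances[c("mucin_degrader", "taurine_respirer")]), 0)
    g <- pr$groups$group == "PD"
    t.test(ab[g], ab[!g], alternative = "greater")$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  expect_error(generate_abundance_profiles(list(), 5, 5), "empty")
})

test_that("generators are bit-reproducible under a fixed seed", {
  panel <- generate_strain_panel(panel_spec(2, TRUE, TRUE, seed = 9))
  expect_identical(panel, generate_strain_panel(panel_spec(2, TRUE, TRUE, seed = 9)))
  pr <- generate_abundance_profiles(panel, 5, 5, 0.5, seed = 4)
  expect_identical(pr, generate_abundance_profiles(panel, 5, 5, 0.5, seed = 4))
  sp <- cohort_spec(metabolites = c("A", "B"), seed = 5)
  expect_identical(generate_longitudinal_metabolome(sp),
                   generate_longitudinal_metabolome(sp))
  sv <- survival_spec(n_subjects = 500, target_events = 30, seed = 6)
  expect_identical(generate_survival_cohort(sv), generate_survival_cohort(sv))
  expect_identical(generate_coverage_table(panel, 10, 0.3, seed = 7),
                   generate_coverage_table(panel, 10, 0.3, seed = 7))
})

test_that("trajectory templates are recovered by the fitted model", {
  reps <- 40
  est <- replicate(reps, {
    s <- cohort_spec(metabolites = "m1",
                     trajectory_assignments = list(m1 = "type3"),
                     seed = sample.int(1e6, 1))
    f <- fit_trajectory_model(generate_longitudinal_metabolome(s), "m1")
    c(f$beta_group, f$beta_gw1, f$beta_gw2)
  })
  truth <- c(0.4, -0.4, -0.8)
  expect_true(all(abs(rowMeans(est) - truth) < 0.08))

  est2 <- replicate(reps, {
    s <- cohort_spec(metabolites = "m1",
                     trajectory_assignments = list(m1 = "type2"),
                     seed = sample.int(1e6, 1))
    f <- fit_trajectory_model(generate_longitudinal_metabolome(s), "m1")
    c(f$beta_group, f$beta_gw1, f$beta_gw2)
  })
  m2 <- rowMeans(est2)
  expect_lt(abs(m2[1]), 0.08)                    # no baseline difference
  expect_equal(m2[3] / m2[2], 2, tolerance = 0.25)  # doubling interaction
})

test_that("levodopa dosing yields the stated 3-OMD fold range", {
  tab <- generate_longitudinal_metabolome(cohort_spec(metabolites = "A", seed = 8))
  takers <- tab$metabolite_id == "3omd" & tab$levodopa_dose > 0
  folds <- exp(0.614 * tab$levodopa_dose[takers])
  expect_true(all(folds >= 10 - 1e-9 & folds <= 600 + 1e-9))
  expect_error(cohort_spec(trajectory_assignments = list(a = "type9"),
                           metabolites = "a"), "unknown trajectory")
})

test_that("survival generator calibrates events and is null-correct", {
  ev <- vapply(1:3, function(s)
    sum(generate_survival_cohort(survival_spec(seed = s))$event), 0)
  expect_true(all(ev >= 133 & ev <= 181))

  # doubling n roughly doubles events
  e1 <- sum(generate_survival_cohort(survival_spec(
    n_subjects = 3000, target_events = 60, seed = 11))$event)
  e2 <- sum(generate_survival_cohort(survival_spec(
    n_subjects = 6000, target_events = 120, seed = 11))$event)
  expect_gt(e2 / e1, 1.6)
  expect_lt(e2 / e1, 2.4)

  hr0 <- vapply(1:60, function(s) {
    d <- generate_survival_cohort(survival_spec(n_subjects = 2000, target_events = 80,
                                                log_hazard_per_sd = 0, seed = 100 + s))
    cox_per_sd(d)$estimate
  }, 0)
  expect_gt(mean(hr0), 0.97)
  expect_lt(mean(hr0), 1.03)
  expect_error(survival_spec(n_subjects = 100, target_events = 100), "target_events")
})

test_that("coverage tables honour the dropout rate", {
  panel <- generate_strain_panel(panel_spec(8, TRUE, TRUE, seed = 2))
  cov0 <- generate_coverage_table(panel, 20, dropout_rate = 0, seed = 1)
  expect_true(all(cov0 >= 0.1))           # nothing filtered downstream
  cov5 <- generate_coverage_table(panel, 100, dropout_rate = 0.5, seed = 1)
  n_low <- sum(cov5 < 0.1)
  expect_gte(n_low, 450); expect_lte(n_low, 550)
  expect_true(all(cov5 >= 0))
  expect_error(generate_coverage_table(panel, 5, dropout_rate = 1), "dropout_rate")
})
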