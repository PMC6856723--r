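test_that("reaction abundances are abundance-weighted carriage", {
  panel <- generate_strain_panel(panel_spec(2, TRUE, TRUE, seed = 3))
  profiles <- list(
    list(subject_id = "s1", abundances = c(mucin_degrader = 0.003, taurine_respirer = 0.097,
                                           bg01 = 0.5, bg02 = 0.4)),
    list(subject_id = "s2", abundances = c(mucin_degrader = 0.25, taurine_respirer = 0.25,
                                           bg01 = 0.25, bg02 = 0.25)))
  ra <- reaction_abundances(panel, profiles, c("FERM", "SHSL", "BSH"))
  # FERM is in every strain
  expect_true(all(abs(ra$abundance[ra$reaction_id == "FERM"] - 1) < 1e-12))
  # SHSL only in the mucin degrader
  expect_equal(ra$abundance[ra$reaction_id == "SHSL" & ra$subject_id == "s1"], 0.003)
  # carriers + non-carriers partition the community
  bsh <- ra$abundance[ra$reaction_id == "BSH" & ra$subject_id == "s1"]
  non_carrier <- 1 - bsh
  expect_equal(bsh + non_carrier, 1)
  expect_true(all(ra$abundance >= 0 & ra$abundance <= 1))
  expect_error(reaction_abundances(panel, profiles, "NOPE"), "no strain")
})

test_that("fractional regression matches the closed-form logit difference", {
  y <- c(rep(0.8, 6), rep(0.2, 6))
  g <- rep(c(1, 0), each = 6)
  fr <- fractional_regression(y, g, n_boot = 50, seed = 1)
  expect_equal(fr$estimate, qlogis(0.8) - qlogis(0.2), tolerance = 1e-6)
  expect_equal(fr$estimate, 2 * log(4), tolerance = 1e-6)

  # identical group distributions: log-OR 0, p near 1
  y0 <- rep(c(0.3, 0.5, 0.7), 4)
  fr0 <- fractional_regression(y0, rep(c(1, 0), 6), n_boot = 200, seed = 2)
  expect_lt(abs(fr0$estimate), 1e-8)
  expect_gt(fr0$p, 0.9)

  # degenerate response
  frd <- fractional_regression(rep(0.4, 10), rep(c(1, 0), 5), n_boot = 10, seed = 1)
  expect_equal(frd$estimate, 0)
  expect_equal(frd$p, 1)
  expect_error(fractional_regression(c(-0.1, 0.5), c(1, 0)), "\\[0, 1\\]")

  # reproducible under seed
  expect_identical(
    fractional_regression(y, g, n_boot = 100, seed = 9),
    fractional_regression(y, g, n_boot = 100, seed = 9))
})

test_that("group-shifted abundances at the field anchors are detected", {
  panel <- generate_strain_panel(panel_spec(3, TRUE, TRUE, seed = 7))
  # control mean 0.20%, case mean 0.34%; tight Dirichlet fixture so the
  # anchor contrast, not sampling noise, dominates
  hits <- vapply(1:25, function(s) {
    pr <- generate_abundance_profiles(panel, 31, 28, keystone_shift = 0.7,
                                      seed = s, keystone_base = 0.002,
                                      concentration = 2000)
    ab <- vapply(pr$profiles, function(p) p$abundances[["taurine_respirer"]], 0)
    fr <- fractional_regression(ab, pr$groups$group == "PD", n_boot = 200, seed = s)
    fr$estimate > 0 && fr$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("secretion group test recovers keystone-driven differences", {
  panel <- generate_strain_panel(panel_spec(3, TRUE, TRUE, seed = 7))
  pr <- generate_abundance_profiles(panel, 25, 25, keystone_shift = 1.5, seed = 21)
  cov <- t(vapply(pr$profiles, function(p) p$abundances * 40, numeric(length(panel))))
  pots <- do.call(rbind, lapply(rownames(cov), function(sid) {
    prr <- coverage_to_abundance(cov[sid, ], subject_id = sid)
    cm <- suppressWarnings(build_community(panel, prr))
    secretion_screen(cm, c("met_L", "so3"))
  }))
  res <- secretion_group_test(pots, pr$groups, n_boot = 300, seed = 5)
  expect_true(all(c("estimate", "p", "q") %in% names(res)))
  met_row <- res[res$target_id == "met_L", ]
  expect_gt(met_row$estimate, 0)
  expect_lt(met_row$p, 0.05)
  # deterministic under seed
  expect_identical(res, secretion_group_test(pots, pr$groups, n_boot = 300, seed = 5))
})

test_that("permuted group labels give roughly nominal secretion test sizes", {
  set.seed(33)
  pots <- data.frame(subject_id = sprintf("s%02d", 1:40),
                     metabolite = "m",
                     potential = exp(rnorm(40)))
  rej <- vapply(1:60, function(i) {
    groups <- data.frame(subject_id = pots$subject_id,
                         group = sample(rep(c("PD", "control"), 20)))
    secretion_group_test(pots, groups, n_boot = 200, seed = i)$p < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.15)
})

test_that("variance explained behaves at the fixed points and selects powers", {
  set.seed(4)
  x <- runif(59, 0.5, 3)
  expect_equal(variance_explained(x, 2 * x + 1)$r_squared, 1)
  r2_null <- vapply(1:30, function(s) {
    set.seed(s); variance_explained(runif(59, 0.5, 3), rnorm(59))$r_squared
  }, 0)
  expect_lt(mean(r2_null), 0.1)
  sel <- vapply(1:40, function(s) {
    set.seed(s)
    xx <- runif(59, 0.5, 3)
    identical(variance_explained(xx, 2 * xx^(-0.5) + rnorm(59, 0, 0.1))$powers, -0.5)
  }, TRUE)
  expect_gte(mean(sel), 0.7)
  expect_equal(variance_explained(rep(1, 12), rnorm(12))$r_squared, 0)
  expect_error(variance_explained(1:5, 1:5), "at least 10")
})

test_that("Fisher enumeration equals the closed-form exact test", {
  expect_equal(sulfur_enrichment(
    stats::setNames(rep(0.5, 6), letters[1:6]),
    stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), letters[1:6]))$p, 1)
  expect_equal(fisher_exact_p(matrix(c(2, 0, 0, 2), 2, 2)), 1 / 3, tolerance = 1e-12)
  # random tables with n <= 40 against stats::fisher.test
  set.seed(10)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2, 2)
    if (sum(tab) == 0 || sum(tab) > 40) next
    expect_equal(fisher_exact_p(tab), fisher.test(tab)$p.value, tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("the sulfur over-representation table is built and tested correctly", {
  # 5/10 sulfur and 6/161 non-sulfur metabolites below alpha
  p <- c(runif(5, 0, 0.009), runif(5, 0.2, 1),
         runif(6, 0, 0.009), runif(155, 0.2, 1))
  names(p) <- paste0("m", seq_along(p))
  isS <- stats::setNames(rep(c(TRUE, FALSE), c(10, 161)), names(p))
  res <- sulfur_enrichment(p, isS, alpha = 0.01)
  expect_equal(unname(res$table), matrix(c(5, 5, 6, 155), 2, 2, byrow = TRUE))
  expect_equal(res$p, fisher.test(res$table)$p.value, tolerance = 1e-9)
  expect_lt(res$p, 0.01)
  expect_error(sulfur_enrichment(numeric(0), logical(0)), "empty")
})
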