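null_table <- function(seed, mets = c("A", "B")) {
  generate_longitudinal_metabolome(cohort_spec(metabolites = mets, seed = seed))
}

test_that("outlier exclusion removes exactly the planted observations", {
  tab <- null_table(1, "A")
  tab <- tab[tab$metabolite_id == "A", ]
  expect_identical(nrow(preprocess_metabolome(tab)), nrow(tab))   # all |z| <= 4

  tab2 <- tab
  tab2$log_concentration[5] <- mean(tab$log_concentration) +
    6 * stats::sd(tab$log_concentration)
  out <- preprocess_metabolome(tab2)
  expect_equal(nrow(out), nrow(tab2) - 1)
  expect_equal(unname(attr(out, "n_removed")["A"]), 1, ignore_attr = TRUE)
  # idempotent on its own output
  expect_equal(nrow(preprocess_metabolome(out)), nrow(out))
})

test_that("baseline levodopa intake is re-classified from extreme 3-OMD", {
  tab <- null_table(2)
  hot <- tab$subject_id == "PD001" & tab$wave == "BL" & tab$metabolite_id == "3omd"
  tab$log_concentration[hot] <- tab$log_concentration[hot] + log(50)
  out <- reclassify_baseline_levodopa(tab)
  flagged <- out[out$subject_id == "PD001" & out$wave == "BL", ]
  expect_true(all(flagged$levodopa_intake))
  expect_true(all(is.na(flagged$levodopa_dose)))
})

test_that("trajectory templates classify to their intended types", {
  for (ty in c("type1", "type2", "type3")) {
    s <- cohort_spec(metabolites = "m", trajectory_assignments = stats::setNames(list(ty), "m"),
                     seed = 17)
    f <- fit_trajectory_model(generate_longitudinal_metabolome(s), "m")
    expect_lt(f$global_p, 0.05)
    expect_identical(classify_trajectory(f), ty)
  }
  s0 <- cohort_spec(metabolites = "m", seed = 18)
  f0 <- fit_trajectory_model(generate_longitudinal_metabolome(s0), "m")
  expect_identical(classify_trajectory(f0, global_q = 0.9), "none")
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- null_table(3, "A")
  expect_error(fit_trajectory_model(tab[tab$group == "PD", ], "A"), "group")
  expect_error(fit_trajectory_model(tab[tab$wave == "BL", ], "A"), "waves")
  expect_error(fit_trajectory_model(tab, "nope"), "no records")
})

test_that("the global Wald test holds its size under the null", {
  rej <- vapply(1:200, function(s) {
    f <- fit_trajectory_model(null_table(4000 + s, "A"), "A")
    f$global_p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.015)
  expect_lte(mean(rej), 0.10)
})

test_that("robust SEs exceed model-based SEs under heteroscedasticity", {
  # residual spread grows with age, so high-leverage observations are noisy
  set.seed(6)
  ratio <- replicate(30, {
    tab <- null_table(sample.int(1e6, 1), "A")
    d <- tab[tab$metabolite_id == "A", ]
    d$log_concentration <- d$log_concentration +
      stats::rnorm(nrow(d), 0, 0.06 * abs(d$age - 65))
    d$group <- factor(d$group, levels = c("control", "PD"))
    d$wave <- factor(as.character(d$wave))
    m <- sulfurflux:::fit_ri_model(log_concentration ~ group + wave + age + sex, d)
    sqrt(m$vcov_robust["age", "age"]) / sqrt(m$vcov_model["age", "age"])
  })
  expect_gt(mean(ratio), 1)
})

test_that("the interaction screen emits one test per ordered pair", {
  tab <- null_table(7, paste0("x", 1:4))  # plus 3omd -> 5 metabolites
  scr <- interaction_screen(tab)
  expect_equal(nrow(scr), 5 * 4)
  expect_true(all(scr$q >= scr$p - 1e-12))
  tab10 <- null_table(8, paste0("y", 1:9))
  expect_equal(nrow(interaction_screen(tab10, adjust_medication = FALSE)), 10 * 9)
})

test_that("a null interaction screen is FDR-controlled", {
  fdp <- vapply(1:15, function(s) {
    scr <- interaction_screen(null_table(900 + s, c("A", "B", "C")),
                              adjust_medication = FALSE)
    mean(scr$q < 0.05)
  }, 0)
  expect_lte(mean(fdp), 0.05 + 0.03)
})

test_that("an embedded interaction is recovered without material bias", {
  est <- vapply(1:40, function(s) {
    sp <- cohort_spec(metabolites = c("A", "B"),
                      interaction_effects = list(list("A", "B", -0.36)),
                      seed = 7000 + s)
    fit_pair_interaction(generate_longitudinal_metabolome(sp), "A", "B")$estimate
  }, 0)
  expect_lt(abs(mean(est) + 0.36), 2 * stats::sd(est) / sqrt(length(est)) + 0.02)
})

test_that("pairs with too few complete cases are skipped, not fatal", {
  tab <- null_table(9)
  tab <- tab[!(tab$metabolite_id == "A" & tab$subject_id != "PD001"), ]
  scr <- interaction_screen(tab, adjust_medication = FALSE)
  expect_true(length(attr(scr, "skipped")) > 0)
})

test_that("medication change models use only consecutive complete waves", {
  tab <- null_table(10, "A")
  # a subject observed once contributes no delta records
  tab <- tab[!(tab$subject_id == "PD001" & tab$wave != "BL"), ]
  med <- medication_change_model(tab, "levodopa")
  dd <- sulfurflux:::make_deltas(
    tab[tab$metabolite_id == "3omd" & tab$group == "PD", ], "levodopa_dose")
  expect_false("PD001" %in% dd$subject_id)
  expect_true(all(c("estimate", "p", "q") %in% names(med)))
  # dose-independent metabolites are null-calibrated
  expect_gt(med$p[med$target_id == "A"], 0.001)
  # 3-OMD slope is strongly positive
  expect_lt(abs(med$estimate[med$target_id == "3omd"] - 0.614), 0.1)
})

test_that("the global medication test detects a single-drug effect", {
  hits <- vapply(1:25, function(s) {
    tab <- null_table(1100 + s, "A")
    idx <- tab$metabolite_id == "A"
    tab$log_concentration[idx] <- tab$log_concentration[idx] +
      0.08 * tab$levodopa_dose[idx]
    g <- medication_global_test(tab, "doses", metabolites = "A")
    g$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
  # duplicated predictors are a singularity error
  tab <- null_table(12, "A")
  tab$equivalent_dose_other <- tab$levodopa_dose
  expect_error(medication_global_test(tab, "doses", metabolites = "A"), "singular")
})

make_updrs <- function(tab, slope = 0, target = "A", seed = 1) {
  set.seed(seed)
  pd <- unique(tab[tab$group == "PD", c("subject_id", "wave")])
  base <- stats::rnorm(nrow(pd), 20, 4)
  y <- tab[tab$metabolite_id == target, ]
  y <- y[match(paste(pd$subject_id, pd$wave), paste(y$subject_id, y$wave)), "log_concentration"]
  sc <- round(pmax(0, base + slope * y))
  data.frame(pd, I = pmin(4, sc %/% 8), II = pmin(4, sc %/% 7), III = sc,
             IV = pmin(4, sc %/% 9), total = sc + sc %/% 5)
}

test_that("UPDRS associations recover an embedded slope and reject constants", {
  tab <- null_table(13)
  up <- make_updrs(tab, slope = 6, target = "A", seed = 3)
  res <- updrs_association(tab, up, scale = "III")
  rowA <- res[res$target_id == "A", ]
  expect_gt(rowA$estimate, 0)
  expect_lt(rowA$p, 0.05)
  reso <- updrs_association(tab, up, scale = "I")
  expect_true(is.finite(reso$estimate[reso$target_id == "A"]))
  up0 <- up; up0$III <- 5
  expect_error(updrs_association(tab, up0, scale = "III"), "no variation")
})

test_that("lagged UPDRS prediction has the declared family structure", {
  tab <- null_table(14)
  up <- make_updrs(tab, slope = 5, target = "A", seed = 4)
  pred <- updrs_prediction(tab, up, metabolites = c("A", "B", "3omd"))
  expect_equal(nrow(pred), 3 * 3)    # metabolites x lags
  expect_true(all(pred$q >= pred$p - 1e-12))
})

test_that("3-OMD separates intake perfectly and AUC is rank-invariant", {
  tab <- null_table(15)
  expect_equal(levodopa_auc(tab), 1.0)
  # identical distributions give AUC near 1/2
  tab0 <- tab
  idx <- tab0$metabolite_id == "3omd"
  set.seed(2); tab0$log_concentration[idx] <- stats::rnorm(sum(idx))
  expect_lt(abs(levodopa_auc(tab0) - 0.5), 0.25)
  # monotone transforms leave the AUC unchanged
  tab2 <- tab0
  tab2$log_concentration[idx] <- exp(tab0$log_concentration[idx] / 2)
  expect_equal(levodopa_auc(tab2), levodopa_auc(tab0))
})

test_that("BH with declared family sizes matches the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # declared family larger than observed tests scales the correction
  expect_equal(bh_fdr(c(0.001, 0.01), family_size = 100),
               pmin(1, c(max(0.001 * 100 / 1, NA, na.rm = TRUE), 0.01 * 100 / 2)),
               tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5), family_size = 0), "family_size")
  expect_error(bh_fdr(1.5), "\\[0, 1\\]")
})
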