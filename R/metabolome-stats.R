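# Longitudinal metabolome analysis suite: preprocessing, trajectory models
# and typing, pairwise metabolite-group interaction screening, medication
# models, UPDRS associations, and levodopa-intake classification by 3-OMD.

eq_dose <- function(d) d$levodopa_dose + d$equivalent_dose_other

# Medication adjustment (dose and dose-by-wave) parametrised as one dose
# slope per wave; structurally zero waves (everyone drug-naive at baseline)
# are dropped so the design stays identified.
add_dose_covariates <- function(d) {
  d$eqdose <- eq_dose(d)
  terms <- character(0)
  for (w in levels(d$wave)) {
    col <- d$eqdose * (as.character(d$wave) == w)
    if (stats::sd(col, na.rm = TRUE) > 0) {
      nm <- paste0("dose_", w)
      d[[nm]] <- col
      terms <- c(terms, nm)
    }
  }
  list(data = d, terms = terms)
}

#' Outlier exclusion on log-concentrations
#'
#' Removes, per metabolite, observations more than `z_max` standard
#' deviations away from that metabolite's full-sample mean. Removal counts are
#' attached as attribute `"n_removed"`. The rule is idempotent in the sense
#' that it always refers to the pre-exclusion mean and SD of the table given.
#'
#' @param table long-format metabolome table.
#' @param z_max exclusion threshold in SD units (default 4).
#' @return filtered table.
#' @export
preprocess_metabolome <- function(table, z_max = 4) {
  keep <- unlist(lapply(split(seq_len(nrow(table)), table$metabolite_id), function(idx) {
    y <- table$log_concentration[idx]
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) return(idx)
    idx[abs(y - mean(y)) <= z_max * s]
  }), use.names = FALSE)
  removed <- table(table$metabolite_id[-keep])
  out <- table[sort(keep), ]
  attr(out, "n_removed") <- if (nrow(out) < nrow(table)) removed else
    stats::setNames(integer(0), character(0))
  out
}

#' Re-classify baseline levodopa intake from 3-OMD
#'
#' Cases whose baseline 3-OMD exceeds 10 times the median of drug-naive cases
#' are flagged as levodopa-treated despite a zero self-reported dose; their
#' dose is set to missing so dose-requiring analyses drop the observation.
#'
#' @param table metabolome table containing metabolite `"3omd"`.
#' @return table with a logical `levodopa_intake` column.
#' @export
reclassify_baseline_levodopa <- function(table) {
  table$levodopa_intake <- table$levodopa_dose > 0
  omd <- table[table$metabolite_id == "3omd", ]
  bl <- omd[omd$wave == "BL" & omd$group == "PD", ]
  naive <- bl$log_concentration[bl$levodopa_dose == 0]
  if (length(naive)) {
    thr <- stats::median(naive) + log(10)
    hot <- bl$subject_id[bl$levodopa_dose == 0 & bl$log_concentration > thr]
    idx <- table$subject_id %in% hot & table$wave == "BL"
    table$levodopa_intake[idx] <- TRUE
    table$levodopa_dose[idx] <- NA
  }
  table
}

traj_terms <- c("groupPD", "groupPD:waveFU1", "groupPD:waveFU2")

prep_groups <- function(d) {
  d$group <- factor(d$group, levels = c("control", "PD"))
  d$wave <- factor(as.character(d$wave), levels = intersect(WAVES, unique(as.character(d$wave))))
  d
}

#' Fit the trajectory model for one metabolite
#'
#' Random-intercept model of log-concentration on group, wave (categorical),
#' group-wave interactions, age and sex, with cluster-robust standard errors.
#' The three group terms are tested jointly on zero (3-df Wald "global test");
#' the group main effect is additionally estimated from a refit without the
#' interaction terms.
#'
#' @param table long-format metabolome table.
#' @param metabolite metabolite id.
#' @param adjust_medication additionally adjust for the levodopa-equivalent
#'   dose and its wave interaction (observations with missing doses dropped).
#' @return object of class `"trajectory_fit"`.
#' @export
fit_trajectory_model <- function(table, metabolite, adjust_medication = FALSE) {
  d <- prep_groups(table[table$metabolite_id == metabolite, ])
  if (nrow(d) == 0L) stopf("no records for metabolite '%s'", metabolite)
  if (nlevels(droplevels(d$wave)) < 2) stopf("need at least 2 waves")
  if (nlevels(droplevels(d$group)) < 2) stopf("singular design: one group absent")
  rhs <- "group * wave + age + sex"
  if (adjust_medication) {
    d <- d[!is.na(eq_dose(d)), ]
    dc <- add_dose_covariates(d)
    d <- dc$data
    if (length(dc$terms)) rhs <- paste(rhs, "+", paste(dc$terms, collapse = " + "))
  }
  f <- stats::as.formula(paste("log_concentration ~", rhs))
  m <- fit_ri_model(f, d)
  terms <- intersect(traj_terms, names(m$beta))
  gw <- robust_wald(m, terms)
  iterms <- setdiff(terms, "groupPD")
  iw <- if (length(iterms)) robust_wald(m, iterms) else list(chi2 = NA, p = NA)
  main <- fit_ri_model(stats::as.formula(paste("log_concentration ~",
                                               sub("group \\* wave", "group + wave", rhs))), d)
  cf <- do.call(rbind, lapply(terms, function(t) cbind(term = t, coef_row(m, t))))
  structure(list(metabolite_id = metabolite,
                 coefficients = cf,
                 beta_group = cf$estimate[cf$term == "groupPD"],
                 beta_gw1 = cf$estimate[match("groupPD:waveFU1", cf$term)],
                 beta_gw2 = cf$estimate[match("groupPD:waveFU2", cf$term)],
                 p_group = cf$p[cf$term == "groupPD"],
                 global_wald_chi2 = gw$chi2, global_df = gw$df, global_p = gw$p,
                 interaction_chi2 = iw$chi2, interaction_p = iw$p,
                 main_effect = coef_row(main, "groupPD"),
                 n_obs = m$n_obs, n_subjects = m$n_subjects),
            class = "trajectory_fit")
}

#' Classify a fitted trajectory
#'
#' Type 1: group main effect significant, interactions not (constant
#' elevation). Type 2: no baseline difference, interactions jointly
#' significant and positive (divergence over time). Type 3: significant
#' positive baseline difference with jointly significant negative
#' interactions (elevated baseline, decline in cases). A non-significant
#' global gate (`global_q`) forces `"none"`.
#'
#' @param fit a `"trajectory_fit"`.
#' @param alpha per-component significance level (default 0.05).
#' @param global_q optional FDR-adjusted global-test q-value gate.
#' @return one of `"type1"`, `"type2"`, `"type3"`, `"none"`.
#' @export
classify_trajectory <- function(fit, alpha = 0.05, global_q = NULL) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!is.null(global_q) && global_q >= 0.05) return("none")
  ints <- c(fit$beta_gw1, fit$beta_gw2)
  int_sig <- is.finite(fit$interaction_p) && fit$interaction_p < alpha
  if (!int_sig && fit$main_effect$p < alpha) return("type1")
  if (int_sig && fit$p_group >= alpha && all(ints > 0)) return("type2")
  if (int_sig && fit$p_group < alpha && fit$beta_group > 0 && all(ints < 0)) return("type3")
  "none"
}

#' Metabolite-pair group-interaction model
#'
#' Random-intercept model of metabolite `a`'s log-concentration on metabolite
#' `b`, a `b` x group interaction (the predictor of interest), group, wave,
#' age, sex and, optionally, medication. A changed `b`-`a` coupling in cases
#' appears as a non-zero interaction coefficient.
#'
#' @param table long-format metabolome table.
#' @param met_a response metabolite.
#' @param met_b predictor metabolite.
#' @param adjust_medication include dose covariates (default TRUE).
#' @param min_complete minimal complete observations (default 10).
#' @return one-row data.frame (target, estimate, se, ci_low, ci_high, p).
#' @export
fit_pair_interaction <- function(table, met_a, met_b,
                                 adjust_medication = TRUE, min_complete = 10) {
  da <- table[table$metabolite_id == met_a, ]
  db <- table[table$metabolite_id == met_b, c("subject_id", "wave", "log_concentration")]
  names(db)[3] <- "x"
  d <- prep_groups(merge(da, db, by = c("subject_id", "wave")))
  rhs <- "x * group + wave + age + sex"
  if (adjust_medication) {
    d <- d[!is.na(eq_dose(d)), ]
    dc <- add_dose_covariates(d)
    d <- dc$data
    if (length(dc$terms)) rhs <- paste(rhs, "+", paste(dc$terms, collapse = " + "))
  }
  d <- d[stats::complete.cases(d[c("log_concentration", "x", "age", "sex")]), ]
  if (nrow(d) < min_complete)
    stopf("pair (%s, %s): fewer than %d complete cases", met_a, met_b, min_complete)
  m <- fit_ri_model(stats::as.formula(paste("log_concentration ~", rhs)), d)
  cbind(data.frame(target_id = paste(met_a, met_b, sep = ":"),
                   stringsAsFactors = FALSE),
        coef_row(m, "x:groupPD"))
}

#' Pairwise metabolite-group interaction screen
#'
#' Fits [fit_pair_interaction()] for every ordered pair of distinct
#' metabolites (or the pairs given) and applies Benjamini-Hochberg correction
#' over the declared family size, which defaults to the number of pairs
#' attempted so that skipped pairs still count against the family.
#'
#' @param table long-format metabolome table.
#' @param pairs optional 2-column matrix/data.frame of (a, b) pairs.
#' @param adjust_medication passed through.
#' @param family_size declared BH family size.
#' @return data.frame of results with `q`; skipped pairs in attribute
#'   `"skipped"`.
#' @export
interaction_screen <- function(table, pairs = NULL, adjust_medication = TRUE,
                               family_size = NULL) {
  mets <- unique(table$metabolite_id)
  if (length(mets) < 2) stopf("need at least 2 metabolites")
  if (is.null(pairs)) {
    pairs <- expand.grid(a = mets, b = mets, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, c("a", "b")]
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(family_size)) family_size <- nrow(pairs)
  skipped <- character(0)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    tryCatch(fit_pair_interaction(table, pairs[i, 1], pairs[i, 2], adjust_medication),
             error = function(e) {
               skipped[[paste(pairs[i, 1], pairs[i, 2], sep = ":")]] <<- conditionMessage(e)
               NULL
             })
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- bh_fdr(out$p, max(family_size, nrow(out)))
  attr(out, "skipped") <- skipped
  out
}

make_deltas <- function(d, dose_col) {
  d <- d[order(d$subject_id, as.integer(factor(as.character(d$wave), levels = WAVES))), ]
  sp <- split(d, d$subject_id)
  do.call(rbind, lapply(sp, function(s) {
    if (nrow(s) < 2) return(NULL)
    i <- seq_len(nrow(s) - 1)
    data.frame(subject_id = s$subject_id[i],
               interval = paste(as.character(s$wave)[i], as.character(s$wave)[i + 1], sep = "-"),
               d_conc = s$log_concentration[i + 1] - s$log_concentration[i],
               d_dose = s[[dose_col]][i + 1] - s[[dose_col]][i],
               age = s$age[i], sex = s$sex[i], disease_length = s$disease_length[i],
               stringsAsFactors = FALSE)
  }))
}

#' Medication change-on-change model
#'
#' For PD cases, regresses the intra-individual change in log-concentration
#' between consecutive waves on the change in dosage, adjusting for age, sex,
#' disease length and the interval, with a random intercept per subject.
#' Observations with missing dose are dropped (not the individual).
#'
#' @param table long-format metabolome table.
#' @param dose_variable `"levodopa"`, `"equivalent_total"` or `"other"`.
#' @param metabolites metabolites to test (default all).
#' @param family_size declared BH family size (default number of metabolites).
#' @return data.frame, one row per metabolite.
#' @export
medication_change_model <- function(table, dose_variable = c("levodopa", "equivalent_total", "other"),
                                    metabolites = NULL, family_size = NULL) {
  dose_variable <- match.arg(dose_variable)
  d <- table[table$group == "PD", ]
  d$dose <- switch(dose_variable,
                   levodopa = d$levodopa_dose,
                   equivalent_total = eq_dose(d),
                   other = d$equivalent_dose_other)
  d <- d[!is.na(d$dose), ]
  if (is.null(metabolites)) metabolites <- unique(d$metabolite_id)
  if (is.null(family_size)) family_size <- length(metabolites)
  rows <- lapply(metabolites, function(met) {
    dd <- make_deltas(d[d$metabolite_id == met, ], "dose")
    if (is.null(dd) || nrow(dd) < 5 || stats::sd(dd$d_dose) == 0) return(NULL)
    rhs <- "d_dose + age + sex + disease_length"
    if (length(unique(dd$interval)) > 1) rhs <- paste(rhs, "+ interval")
    m <- fit_ri_model(stats::as.formula(paste("d_conc ~", rhs)), dd)
    cbind(data.frame(target_id = met, stringsAsFactors = FALSE), coef_row(m, "d_dose"))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- bh_fdr(out$p, max(family_size, nrow(out)))
  out
}

#' Global medication Wald test per metabolite
#'
#' Tests all medication terms (dosages, or intake indicators of the prevalent
#' drugs) simultaneously on zero in a random-intercept model adjusted for
#' age, sex, disease length and wave.
#'
#' @param table long-format metabolome table.
#' @param predictors `"doses"` (levodopa dose + other equivalent dose) or
#'   `"drugs"` (binary intake indicators).
#' @param metabolites metabolites to test (default all).
#' @param family_size declared BH family size.
#' @return data.frame with chi2, df, p, q per metabolite.
#' @export
medication_global_test <- function(table, predictors = c("doses", "drugs"),
                                   metabolites = NULL, family_size = NULL) {
  predictors <- match.arg(predictors)
  d <- table[table$group == "PD", ]
  d <- d[!is.na(d$levodopa_dose), ]
  if (predictors == "doses") {
    d$m1 <- d$levodopa_dose; d$m2 <- d$equivalent_dose_other
  } else {
    d$m1 <- as.numeric(d$levodopa_dose > 0); d$m2 <- as.numeric(d$equivalent_dose_other > 0)
  }
  if (is.null(metabolites)) metabolites <- unique(d$metabolite_id)
  if (is.null(family_size)) family_size <- length(metabolites)
  rows <- lapply(metabolites, function(met) {
    dd <- prep_groups(d[d$metabolite_id == met, ])
    m <- fit_ri_model(log_concentration ~ m1 + m2 + age + sex + disease_length + wave, dd)
    w <- robust_wald(m, c("m1", "m2"))
    data.frame(target_id = met, chi2 = w$chi2, df = w$df, p = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p, max(family_size, nrow(out)))
  out
}

#' Metabolite associations with UPDRS scales
#'
#' Ordered logistic regression for the discrete subscales I, II and IV;
#' random-intercept linear models for subscale III and the total score.
#' Models are fitted on PD cases, adjusted for age, sex, wave, disease length
#' and medication.
#'
#' @param table long-format metabolome table.
#' @param updrs_scores data.frame with subject_id, wave and a column per
#'   scale (`I`, `II`, `III`, `IV`, `total`).
#' @param scale which scale to analyse.
#' @param metabolites metabolites to test (default all).
#' @param family_size declared BH family size.
#' @return data.frame, one row per metabolite.
#' @export
updrs_association <- function(table, updrs_scores,
                              scale = c("total", "I", "II", "III", "IV"),
                              metabolites = NULL, family_size = NULL) {
  scale <- match.arg(scale)
  d <- table[table$group == "PD", ]
  d <- merge(d, updrs_scores, by = c("subject_id", "wave"))
  d$score <- d[[scale]]
  if (length(unique(stats::na.omit(d$score))) < 2) stopf("no variation in UPDRS scale %s", scale)
  d <- d[!is.na(eq_dose(d)), ]
  if (is.null(metabolites)) metabolites <- unique(d$metabolite_id)
  if (is.null(family_size)) family_size <- length(metabolites)
  linear <- scale %in% c("III", "total")
  rows <- lapply(metabolites, function(met) {
    dd <- prep_groups(d[d$metabolite_id == met, ])
    dd$wave <- droplevels(dd$wave)
    dc <- add_dose_covariates(dd)
    dd <- dc$data
    dose_rhs <- if (length(dc$terms)) paste("+", paste(dc$terms, collapse = " + ")) else ""
    if (linear) {
      m <- fit_ri_model(stats::as.formula(paste(
        "score ~ log_concentration + age + sex + wave + disease_length", dose_rhs)), dd)
      row <- coef_row(m, "log_concentration")
    } else {
      dd$score_f <- factor(dd$score, ordered = TRUE)
      fit <- MASS::polr(stats::as.formula(paste(
        "score_f ~ log_concentration + age + sex + wave + disease_length + eqdose")),
        data = dd, Hess = TRUE)
      est <- stats::coef(fit)[["log_concentration"]]
      se <- sqrt(stats::vcov(fit)["log_concentration", "log_concentration"])
      row <- data.frame(estimate = est, se = se, ci_low = est - 1.96 * se,
                        ci_high = est + 1.96 * se, p = 2 * stats::pnorm(-abs(est / se)))
    }
    cbind(data.frame(target_id = met, scale = scale, stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p, max(family_size, nrow(out)))
  out
}

#' Lagged prediction of UPDRS scores by earlier metabolite levels
#'
#' For each metabolite and each lag (BL to FU2, FU1 to FU2, BL to FU1),
#' regresses the later UPDRS score on the earlier log-concentration,
#' adjusting for the earlier score, age, sex, disease length and medication
#' status; heteroscedasticity-robust (HC1) standard errors.
#'
#' @param table long-format metabolome table.
#' @param updrs_scores as in [updrs_association()].
#' @param metabolites metabolites to test (pre-filtered to the
#'   association-significant set).
#' @param scale UPDRS scale column to predict (default `"III"`).
#' @param family_size declared BH family size (default metabolites x lags).
#' @return data.frame, one row per metabolite and lag.
#' @export
updrs_prediction <- function(table, updrs_scores, metabolites, scale = "III",
                             family_size = NULL) {
  lags <- list(c("BL", "FU2"), c("FU1", "FU2"), c("BL", "FU1"))
  d <- table[table$group == "PD", ]
  d <- merge(d, updrs_scores, by = c("subject_id", "wave"))
  d$score <- d[[scale]]
  if (is.null(family_size)) family_size <- length(metabolites) * length(lags)
  rows <- list()
  for (met in metabolites) for (lg in lags) {
    from <- d[d$metabolite_id == met & d$wave == lg[1],
              c("subject_id", "log_concentration", "score", "age", "sex",
                "disease_length", "levodopa_dose")]
    to <- d[d$metabolite_id == met & d$wave == lg[2], c("subject_id", "score")]
    names(to)[2] <- "score_later"
    dd <- stats::na.omit(merge(from, to, by = "subject_id"))
    if (nrow(dd) < 8) next
    fit <- stats::lm(score_later ~ log_concentration + score + age + sex +
                       disease_length + levodopa_dose, data = dd)
    V <- sandwich::vcovHC(fit, type = "HC1")
    est <- stats::coef(fit)[["log_concentration"]]
    se <- sqrt(V["log_concentration", "log_concentration"])
    rows[[paste(met, lg[1], lg[2])]] <-
      data.frame(target_id = met, lag = paste(lg, collapse = "->"),
                 estimate = est, se = se, ci_low = est - 1.96 * se,
                 ci_high = est + 1.96 * se, p = 2 * stats::pnorm(-abs(est / se)),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- bh_fdr(out$p, max(family_size, nrow(out)))
  out
}

#' ROC AUC of 3-OMD for levodopa intake at follow-up
#'
#' Midrank (Mann-Whitney) area under the ROC curve of 3-OMD
#' log-concentration for self-reported levodopa intake among cases at the
#' follow-up waves.
#'
#' @param table long-format metabolome table containing metabolite `"3omd"`.
#' @return AUC in \[0, 1\].
#' @export
levodopa_auc <- function(table) {
  d <- table[table$metabolite_id == "3omd" & table$group == "PD" &
               as.character(table$wave) != "BL", ]
  intake <- if ("levodopa_intake" %in% names(d)) d$levodopa_intake else d$levodopa_dose > 0
  d <- d[!is.na(intake), ]; intake <- intake[!is.na(intake)]
  if (length(unique(intake)) < 2) stopf("need both intake classes at follow-up")
  r <- pROC::roc(response = intake, predictor = d$log_concentration,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}
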