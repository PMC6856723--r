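# Seeded generators for longitudinal case-control metabolome cohorts and for
# incident-disease survival cohorts.

WAVES <- c("BL", "FU1", "FU2")

#' Longitudinal cohort specification
#'
#' Trajectory types are encoded as coefficient templates on
#' (group, group x FU1, group x FU2): type1 = (delta, 0, 0) — constant
#' elevation in cases; type2 = (0, delta, 2 delta) — equal baseline, cases
#' diverge upward; type3 = (delta, -delta, -2 delta) — elevated baseline,
#' cases decline. All effects act on the log-concentration scale.
#'
#' @param n_cases,n_controls subjects per group.
#' @param n_waves number of waves (2 or 3; default 3).
#' @param metabolites character vector of metabolite ids; `"3omd"` is always
#'   included (the levodopa catabolite that carries the dosage signal).
#' @param trajectory_assignments named list/vector metabolite -> one of
#'   `"type1"`, `"type2"`, `"type3"`, `"null"`.
#' @param interaction_effects list of `list(a, b, beta)` triples embedding a
#'   group-dependent slope of metabolite `a` on metabolite `b`.
#' @param delta trajectory template magnitude on the log scale (default 0.4).
#' @param residual_sd,subject_sd noise components on the log scale (default
#'   0.3 each).
#' @param beta_age,beta_sex covariate effects on log-concentrations.
#' @param base_slope group-independent slope used for interaction pairs.
#' @param omd_dose_slope increase in log 3-OMD per unit levodopa dose; the
#'   default 0.614 with doses spanning 3.75-10.4 units yields the 10- to
#'   600-fold 3-OMD elevation in levodopa takers.
#' @param taker_fraction probability that a case takes levodopa per follow-up
#'   wave (FU1, FU2).
#' @param seed integer seed.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cases = 30, n_controls = 30, n_waves = 3,
                        metabolites = paste0("met", sprintf("%02d", 1:10)),
                        trajectory_assignments = list(),
                        interaction_effects = list(),
                        delta = 0.4, residual_sd = 0.3, subject_sd = 0.3,
                        beta_age = 0.005, beta_sex = 0.1, base_slope = 0.5,
                        omd_dose_slope = 0.614,
                        taker_fraction = c(0.55, 0.8),
                        seed = 1L) {
  if (residual_sd <= 0 || subject_sd <= 0) stopf("noise SDs must be > 0")
  if (!n_waves %in% 2:3) stopf("n_waves must be 2 or 3")
  known <- c("type1", "type2", "type3", "null")
  bad <- setdiff(unlist(trajectory_assignments), known)
  if (length(bad)) stopf("unknown trajectory type label(s): %s", paste(bad, collapse = ", "))
  metabolites <- union(metabolites, "3omd")
  for (ie in interaction_effects) {
    if (length(ie) < 3) stopf("interaction effects must be (a, b, beta) triples")
    miss <- setdiff(c(ie[[1]], ie[[2]]), metabolites)
    if (length(miss)) stopf("interaction effect references unknown metabolites: %s",
                            paste(miss, collapse = ", "))
  }
  miss <- setdiff(names(trajectory_assignments), metabolites)
  if (length(miss)) stopf("trajectory assignment for unknown metabolites: %s",
                          paste(miss, collapse = ", "))
  structure(as.list(environment()), class = "cohort_spec")
}

trajectory_template <- function(type, delta) {
  switch(type,
         type1 = c(delta, 0, 0),
         type2 = c(0, delta, 2 * delta),
         type3 = c(delta, -delta, -2 * delta),
         null = c(0, 0, 0),
         stopf("unknown trajectory type label: %s", type))
}

#' Generate a longitudinal case-control metabolome table
#'
#' Log-concentrations follow a random-intercept model with the trajectory
#' templates of the spec, age and sex effects, embedded pairwise
#' metabolite-group interactions, and Gaussian noise. Cases are drug-naive at
#' baseline; at follow-ups a fraction take levodopa with doses drawn so the
#' 3-OMD elevation is 10- to 600-fold (log-uniform).
#'
#' @param spec a [cohort_spec()].
#' @return long-format data.frame with columns subject_id, group, wave, age,
#'   sex, disease_length, levodopa_dose, equivalent_dose_other, metabolite_id,
#'   log_concentration. Doses are in levodopa-equivalent units of 100 mg/day.
#' @export
generate_longitudinal_metabolome <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  waves <- WAVES[seq_len(spec$n_waves)]
  n <- spec$n_cases + spec$n_controls
  subj <- data.frame(
    subject_id = c(sprintf("PD%03d", seq_len(spec$n_cases)),
                   sprintf("C%03d", seq_len(spec$n_controls))),
    group = rep(c("PD", "control"), c(spec$n_cases, spec$n_controls)),
    age = pmin(85, pmax(40, stats::rnorm(n, 65, 8))),
    sex = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE)
  subj$disease_length <- ifelse(subj$group == "PD", stats::runif(n, 0.5, 2), NA)

  # per-subject per-wave medication (levodopa-equivalent units of 100 mg/day)
  dose_range <- c(log(10), log(600)) / spec$omd_dose_slope
  med <- expand.grid(subject_id = subj$subject_id, wave = waves,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  med <- merge(med, subj[c("subject_id", "group")], by = "subject_id")
  med$levodopa_dose <- 0
  med$equivalent_dose_other <- 0
  taker <- stats::setNames(rep(FALSE, n), subj$subject_id)
  for (w in setdiff(waves, "BL")) {
    frac <- spec$taker_fraction[match(w, c("FU1", "FU2"))]
    is_pd <- subj$group == "PD"
    new_taker <- is_pd & (taker[subj$subject_id] |
                            stats::runif(n) < frac)
    taker[subj$subject_id[new_taker]] <- TRUE
    idx <- med$wave == w & med$subject_id %in% subj$subject_id[new_taker]
    med$levodopa_dose[idx] <- stats::runif(sum(idx), dose_range[1], dose_range[2])
    oth <- med$wave == w & med$group == "PD" & stats::runif(nrow(med)) < 0.3
    med$equivalent_dose_other[oth] <- stats::runif(sum(oth), 0.5, 3)
  }

  grid <- merge(med, subj[c("subject_id", "age", "sex", "disease_length")], by = "subject_id")
  grid$disease_length <- grid$disease_length + 2 * (match(grid$wave, WAVES) - 1)
  gi <- as.integer(grid$group == "PD")
  wi <- match(grid$wave, WAVES)

  mets <- spec$metabolites
  ie_targets <- vapply(spec$interaction_effects, function(e) e[[1]], "")
  order_mets <- c(setdiff(mets, ie_targets), intersect(mets, ie_targets))
  ycols <- list()
  for (m in order_mets) {
    type <- spec$trajectory_assignments[[m]] %||% "null"
    tmpl <- trajectory_template(type, spec$delta)
    u <- stats::setNames(stats::rnorm(n, 0, spec$subject_sd), subj$subject_id)
    y <- u[grid$subject_id] +
      spec$beta_age * (grid$age - 65) + spec$beta_sex * grid$sex +
      gi * (tmpl[1] + tmpl[2] * (wi == 2) + tmpl[3] * (wi == 3)) +
      stats::rnorm(nrow(grid), 0, spec$residual_sd)
    if (m == "3omd")
      y <- y + spec$omd_dose_slope * grid$levodopa_dose
    for (ie in spec$interaction_effects) {
      if (ie[[1]] != m) next
      yb <- ycols[[ie[[2]]]]
      if (is.null(yb)) stopf("interaction source '%s' must not itself be a target", ie[[2]])
      y <- y + (spec$base_slope + ie[[3]] * gi) * yb
    }
    ycols[[m]] <- as.numeric(y)
  }

  out <- do.call(rbind, lapply(mets, function(m) {
    cbind(grid[c("subject_id", "group", "wave", "age", "sex", "disease_length",
                 "levodopa_dose", "equivalent_dose_other")],
          data.frame(metabolite_id = m, log_concentration = ycols[[m]],
                     stringsAsFactors = FALSE))
  }))
  out$wave <- factor(out$wave, levels = WAVES[seq_len(spec$n_waves)])
  rownames(out) <- NULL
  out[order(out$metabolite_id, out$subject_id, out$wave), ]
}

#' Survival cohort specification
#'
#' @param n_subjects cohort size.
#' @param target_events expected number of incident events (0 < target <
#'   n_subjects).
#' @param log_hazard_per_sd true log hazard ratio per SD of the exposure.
#' @param max_followup_years administrative end of follow-up.
#' @param covariate_betas log-hazard contributions of the (centred) covariates.
#' @param seed integer seed.
#' @return list of class `"survival_spec"`.
#' @export
survival_spec <- function(n_subjects = 10034, target_events = 157,
                          log_hazard_per_sd = log(0.80),
                          max_followup_years = 24,
                          covariate_betas = c(age = 0.05, sex = -0.1, bmi = 0.01,
                                              smoking = 0.3, crp = 0.05),
                          seed = 1L) {
  if (!(target_events > 0 && target_events < n_subjects))
    stopf("target_events must satisfy 0 < target_events < n_subjects")
  structure(as.list(environment()), class = "survival_spec")
}

#' Generate an incident-disease survival cohort
#'
#' Standard-normal exposure, exponential event times with hazard proportional
#' to `exp(log_hazard_per_sd * exposure + covariate terms)`, and
#' administrative censoring with the baseline hazard calibrated so that the
#' expected event count equals `target_events`.
#'
#' @param spec a [survival_spec()].
#' @return data.frame with subject_id, time (years), event, exposure, age,
#'   sex, bmi, smoking, crp, batch.
#' @export
generate_survival_cohort <- function(spec) {
  stopifnot(inherits(spec, "survival_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  d <- data.frame(
    subject_id = sprintf("E%05d", seq_len(n)),
    exposure = stats::rnorm(n),
    age = stats::rnorm(n, 59.8, 8.9),
    sex = stats::rbinom(n, 1, 0.53),
    bmi = stats::rnorm(n, 26.3, 3.9),
    smoking = stats::rbinom(n, 1, 0.12),
    crp = exp(stats::rnorm(n, 0.6, 0.6)),
    batch = sample(rep(1:2, length.out = n)),
    stringsAsFactors = FALSE)
  b <- spec$covariate_betas
  eta <- spec$log_hazard_per_sd * d$exposure +
    b[["age"]] * (d$age - 59.8) + b[["sex"]] * (d$sex - 0.53) +
    b[["bmi"]] * (d$bmi - 26.3) + b[["smoking"]] * (d$smoking - 0.12) +
    b[["crp"]] * (d$crp - exp(0.6 + 0.18))
  cens <- stats::runif(n, 0.7, 1) * spec$max_followup_years
  expected_events <- function(log_lambda0)
    sum(1 - exp(-exp(log_lambda0 + eta) * cens)) - spec$target_events
  sol <- tryCatch(stats::uniroot(expected_events, c(-25, 5))$root,
                  error = function(e) stopf("infeasible target_events: %s", conditionMessage(e)))
  rate <- exp(sol + eta)
  tt <- stats::rexp(n, rate)
  d$event <- as.integer(tt <= cens)
  d$time <- pmin(tt, cens)
  d$time[d$time <= 0] <- 1e-6
  d
}
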