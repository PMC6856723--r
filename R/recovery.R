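# Parameter-recovery simulation protocols: the package's estimators are run
# against its own generators with a known embedded truth, replicate by
# replicate, and the mean estimate is reported. These are the package's
# calibration experiments.

#' Recovery of a metabolite-group interaction coefficient
#'
#' Simulates replicate 3-wave case-control cohorts embedding a group-
#' dependent slope between two metabolites, fits the pairwise interaction
#' model per replicate and summarises the estimates.
#'
#' @param beta true interaction coefficient embedded in the generator.
#' @param n_reps replicate cohorts (default 200).
#' @param seed integer seed.
#' @param n_cases,n_controls subjects per group (default 30/30).
#' @param adjust_medication include dose covariates in generator use and fit.
#' @return list with `mean`, `mc_se`, `truth`, `estimates`.
#' @export
recover_interaction <- function(beta, n_reps = 200, seed = 1L,
                                n_cases = 30, n_controls = 30,
                                adjust_medication = TRUE) {
  est <- vapply(seq_len(n_reps), function(r) {
    sp <- cohort_spec(n_cases = n_cases, n_controls = n_controls,
                      metabolites = c("A", "B"),
                      interaction_effects = list(list("A", "B", beta)),
                      seed = derive_seed(seed, paste0("ie", r)))
    fit_pair_interaction(generate_longitudinal_metabolome(sp), "A", "B",
                         adjust_medication = adjust_medication)$estimate
  }, 0)
  list(mean = mean(est), mc_se = stats::sd(est) / sqrt(n_reps),
       truth = beta, estimates = est)
}

#' Recovery of the dosage change-on-change slope
#'
#' Simulates replicate PD cohorts whose 3-OMD log-concentration carries the
#' generator's dose slope and refits the change-on-change model.
#'
#' @param n_reps replicate cohorts (default 200).
#' @param seed integer seed.
#' @param slope true slope (default 0.614 per 100 mg/day levodopa).
#' @return list with `mean`, `mc_se`, `truth`, `estimates`.
#' @export
recover_medication_slope <- function(n_reps = 200, seed = 1L, slope = 0.614) {
  est <- vapply(seq_len(n_reps), function(r) {
    sp <- cohort_spec(metabolites = "A", omd_dose_slope = slope,
                      seed = derive_seed(seed, paste0("med", r)))
    med <- medication_change_model(generate_longitudinal_metabolome(sp), "levodopa")
    med$estimate[med$target_id == "3omd"]
  }, 0)
  list(mean = mean(est), mc_se = stats::sd(est) / sqrt(n_reps),
       truth = slope, estimates = est)
}

#' Recovery of a per-SD hazard ratio
#'
#' Simulates replicate survival cohorts with the embedded log hazard per SD
#' and refits the adjusted Cox model.
#'
#' @param n_reps replicate cohorts (default 100).
#' @param seed integer seed.
#' @param hr true hazard ratio per SD (default 0.80).
#' @param n_subjects,target_events cohort design (default 10,034 / 157).
#' @return list with `mean`, `mc_se`, `truth`, `estimates` (HR scale).
#' @export
recover_cox_hr <- function(n_reps = 100, seed = 1L, hr = 0.80,
                           n_subjects = 10034, target_events = 157) {
  est <- vapply(seq_len(n_reps), function(r) {
    sp <- survival_spec(n_subjects = n_subjects, target_events = target_events,
                        log_hazard_per_sd = log(hr),
                        seed = derive_seed(seed, paste0("cox", r)))
    cox_per_sd(generate_survival_cohort(sp))$estimate
  }, 0)
  list(mean = mean(est), mc_se = stats::sd(est) / sqrt(n_reps),
       truth = hr, estimates = est)
}

#' Levodopa-intake classification AUC on a simulated follow-up
#'
#' Generates one cohort (default 30 cases) with the 10- to 600-fold 3-OMD
#' elevation in takers and returns the midrank ROC AUC at the follow-up
#' waves.
#'
#' @param seed integer seed.
#' @param n_cases cases (default 30).
#' @return AUC in \[0, 1\].
#' @export
classification_auc <- function(seed = 1L, n_cases = 30) {
  sp <- cohort_spec(n_cases = n_cases, n_controls = n_cases,
                    metabolites = "A", seed = derive_seed(seed, "auc"))
  levodopa_auc(generate_longitudinal_metabolome(sp))
}
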