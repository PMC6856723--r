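# Greedy recursive-elimination selection of matched case/control subsets
# under a composite deviation score: Kolmogorov-Smirnov distances for age and
# BMI plus normalised flag counts (medication use, risk-allele carriage),
# with balanced sex representation as a hard constraint.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' @param x,y numeric samples.
#' @return sup-norm distance between the empirical CDFs, in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- vapply(v, function(t) mean(x <= t), 0)
  Fy <- vapply(v, function(t) mean(y <= t), 0)
  max(abs(Fx - Fy))
}

flag_columns <- function(candidates)
  setdiff(names(candidates), c("subject_id", "is_case", "age", "bmi", "sex"))

#' Composite deviation score of a case/control selection
#'
#' Sum of the age KS statistic, the BMI KS statistic, and, per flag, the
#' fraction of flagged subjects among the selection (the theoretically
#' achievable optimum for each component being 0); every component lies in
#' \[0, 1\] and enters with equal weight. Sex balance is a hard constraint of
#' the matcher, not a summand.
#'
#' @param cases,controls data.frames of candidates (columns subject_id,
#'   is_case, age, bmi, sex, plus binary flag columns).
#' @param norm_n normalising selection size for the flag counts; defaults to
#'   the current selection size. The matcher passes its target size so the
#'   flag deviations keep a fixed scale throughout the elimination.
#' @return list with `ks_age`, `ks_bmi`, `flag_fractions`, `total`.
#' @export
score_selection <- function(cases, controls, norm_n = nrow(cases) + nrow(controls)) {
  if (nrow(cases) == 0L || nrow(controls) == 0L) stopf("both groups must be non-empty")
  all_sel <- rbind(cases, controls)
  fl <- flag_columns(cases)
  ff <- vapply(fl, function(f) sum(all_sel[[f]]) / norm_n, 0)
  ks_a <- ks_statistic(cases$age, controls$age)
  ks_b <- ks_statistic(cases$bmi, controls$bmi)
  list(ks_age = ks_a, ks_bmi = ks_b, flag_fractions = ff,
       total = ks_a + ks_b + sum(ff))
}

#' Hard pre-filtering on exclusion flags
#'
#' Removes candidates carrying any of the named exclusion flags before
#' optimisation (e.g. known causal PD mutations).
#'
#' @param candidates candidate data.frame.
#' @param exclusion_flags character vector of flag column names.
#' @return filtered data.frame.
#' @export
prefilter <- function(candidates, exclusion_flags) {
  if (length(exclusion_flags) == 0) return(candidates)
  miss <- setdiff(exclusion_flags, names(candidates))
  if (length(miss)) stopf("unknown exclusion flags: %s", paste(miss, collapse = ", "))
  bad <- Reduce(`|`, lapply(exclusion_flags, function(f) candidates[[f]] > 0))
  out <- candidates[!bad, ]
  if (nrow(out) == 0L) warnf("all candidates excluded by hard flags")
  out
}

# Sex matching is feasible iff the attainable per-group male counts overlap:
# group g can select m males with max(0, n_g - females_g) <= m <= min(males_g, n_g).
sex_feasible <- function(d, n_cases, n_controls) {
  rng <- function(sub, target) {
    males <- sum(sub$sex == 1); females <- nrow(sub) - males
    if (nrow(sub) < target) return(NULL)
    c(max(0, target - females), min(males, target))
  }
  rc <- rng(d[d$is_case == 1, ], n_cases)
  rk <- rng(d[d$is_case == 0, ], n_controls)
  if (is.null(rc) || is.null(rk)) return(FALSE)
  max(rc[1], rk[1]) <= min(rc[2], rk[2])
}

#' Greedy recursive-elimination matching
#'
#' Iteratively removes, among the removable candidates (those from
#' oversized groups whose removal keeps matched sex representation
#' attainable), the one whose exclusion minimises the composite deviation
#' score, until the target group sizes are reached. Ties are broken by the
#' lowest subject id, making the procedure deterministic.
#'
#' @param candidates candidate data.frame (after [prefilter()]).
#' @param n_cases,n_controls target sizes.
#' @return list with `selection` (data.frame), `score` (final
#'   [score_selection()]), `trace` (total score after each removal,
#'   non-increasing), `removed` (subject ids in removal order).
#' @export
recursive_match <- function(candidates, n_cases, n_controls) {
  d <- candidates[order(candidates$subject_id), ]
  if (!sex_feasible(d, n_cases, n_controls))
    stopf("infeasible targets: cannot reach %d cases and %d controls with matched sex counts",
          n_cases, n_controls)
  cur_score <- function(dd)
    score_selection(dd[dd$is_case == 1, ], dd[dd$is_case == 0, ],
                    norm_n = n_cases + n_controls)$total
  trace <- cur_score(d)
  removed <- character(0)
  repeat {
    nc <- sum(d$is_case == 1); nk <- sum(d$is_case == 0)
    if (nc == n_cases && nk == n_controls) break
    cand_idx <- which((d$is_case == 1 & nc > n_cases) | (d$is_case == 0 & nk > n_controls))
    best <- NULL; best_score <- Inf
    for (i in cand_idx) {
      dd <- d[-i, ]
      if (!sex_feasible(dd, n_cases, n_controls)) next
      s <- cur_score(dd)
      if (s < best_score - 1e-12 ||
          (s < best_score + 1e-12 && !is.null(best) && d$subject_id[i] < d$subject_id[best])) {
        best <- i; best_score <- s
      }
    }
    if (is.null(best)) stopf("no admissible removal keeps sex matching attainable")
    removed <- c(removed, d$subject_id[best])
    d <- d[-best, ]
    trace <- c(trace, best_score)
  }
  # final sex matching: the greedy keeps it attainable; verify and, if the
  # endpoint is unbalanced across groups, this is a defect worth failing on
  mc <- sum(d$sex[d$is_case == 1] == 1); mk <- sum(d$sex[d$is_case == 0] == 1)
  if (mc != mk) stopf("internal error: sex counts not matched (%d vs %d)", mc, mk)
  list(selection = d,
       score = score_selection(d[d$is_case == 1, ], d[d$is_case == 0, ],
                               norm_n = n_cases + n_controls),
       trace = trace, removed = removed)
}
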