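# Statistics on community models: reaction abundances, fractional (logit)
# regressions with bootstrap standard errors, secretion-potential group
# tests, fractional-polynomial variance explanation, sulfur enrichment.

#' Abundance-weighted reaction presence
#'
#' For each subject and reaction, the sum of the relative abundances of the
#' strains that carry the reaction — a proxy for the community's capacity for
#' that biochemical step.
#'
#' @param panel strain panel (list of reconstructions).
#' @param profiles list of abundance profiles.
#' @param reaction_ids reactions to score (un-prefixed strain reaction ids).
#' @return data.frame with subject_id, reaction_id, abundance.
#' @export
reaction_abundances <- function(panel, profiles, reaction_ids) {
  names(panel) <- vapply(panel, `[[`, "", "strain_id")
  carriers <- lapply(reaction_ids, function(rid)
    names(panel)[vapply(panel, function(r) rid %in% names(r$reactions), FALSE)])
  names(carriers) <- reaction_ids
  empty <- reaction_ids[lengths(carriers) == 0]
  if (length(empty))
    stopf("reaction(s) carried by no strain: %s", paste(empty, collapse = ", "))
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id,
               reaction_id = reaction_ids,
               abundance = vapply(carriers, function(cs)
                 sum(p$abundances[intersect(cs, names(p$abundances))]), 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

boot_stat <- function(stat, data_n, n_boot, seed) {
  set.seed(seed)
  vapply(seq_len(n_boot), function(b) stat(sample.int(data_n, replace = TRUE)), 0)
}

#' Fractional (logit) regression of a proportion on group
#'
#' Quasi-likelihood logit-link fit of a response in \[0, 1\] on a binary
#' group; the coefficient is a log odds ratio. Standard errors and percentile
#' confidence intervals come from a nonparametric bootstrap over subjects;
#' the p-value uses a normal approximation on the bootstrap SE.
#'
#' @param y fractions in \[0, 1\].
#' @param group binary vector (0/1 or logical) of the same length.
#' @param n_boot bootstrap replications (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return one-row data.frame (estimate = log-OR, se, ci_low, ci_high, p,
#'   n_boot).
#' @export
fractional_regression <- function(y, group, n_boot = 2000, seed = 1L) {
  if (any(y < 0 | y > 1)) stopf("fractional response must lie in [0, 1]")
  g <- as.numeric(group)
  if (length(unique(g)) != 2) stopf("both groups must be non-empty")
  if (stats::sd(y) == 0)
    return(data.frame(estimate = 0, se = NA_real_, ci_low = 0, ci_high = 0,
                      p = 1, n_boot = n_boot))
  est_fun <- function(idx) {
    fit <- suppressWarnings(stats::glm(y[idx] ~ g[idx], family = stats::quasibinomial()))
    stats::coef(fit)[2]
  }
  est <- est_fun(seq_along(y))
  bs <- boot_stat(est_fun, length(y), n_boot, seed)
  bs <- bs[is.finite(bs)]
  se <- stats::sd(bs)
  data.frame(estimate = unname(est), se = se,
             ci_low = unname(stats::quantile(bs, 0.025)),
             ci_high = unname(stats::quantile(bs, 0.975)),
             p = 2 * stats::pnorm(-abs(est / se)), n_boot = n_boot)
}

#' Group test of log secretion potentials
#'
#' Per metabolite, a linear regression of log potential on group with
#' bootstrap percentile confidence intervals and BH correction across the
#' tested set. Zero potentials are offset by half the smallest positive value
#' before the log; all-zero metabolites are skipped with a log entry.
#'
#' @param potentials data.frame with subject_id, metabolite, potential (as
#'   from [secretion_screen()] row-bound over subjects).
#' @param groups data.frame with subject_id, group (`"PD"`/`"control"`).
#' @param n_boot bootstrap replications (default 2000).
#' @param seed integer seed.
#' @return data.frame, one row per testable metabolite, with `q`; skipped
#'   metabolites in attribute `"skipped"`.
#' @export
secretion_group_test <- function(potentials, groups, n_boot = 2000, seed = 1L) {
  d <- merge(potentials, groups, by = "subject_id")
  skipped <- character(0)
  rows <- lapply(split(d, d$metabolite), function(dm) {
    met <- dm$metabolite[1]
    v <- dm$potential
    vv <- v[!is.na(v)]
    if (length(vv) < 3 || isTRUE(all(vv == 0)) || isTRUE(stats::sd(vv) == 0)) {
      skipped[[met]] <<- "no variance in secretion potential"
      return(NULL)
    }
    pos <- v[!is.na(v) & v > 0]
    v[!is.na(v) & v == 0] <- min(pos) / 2
    ly <- log(v)
    g <- as.numeric(dm$group == "PD")
    ok <- !is.na(ly)
    ly <- ly[ok]; g <- g[ok]
    est_fun <- function(idx) stats::coef(stats::lm(ly[idx] ~ g[idx]))[2]
    est <- est_fun(seq_along(ly))
    bs <- boot_stat(est_fun, length(ly), n_boot, derive_seed(seed, met))
    bs <- bs[is.finite(bs)]
    se <- stats::sd(bs)
    data.frame(target_id = met, estimate = unname(est), se = se,
               ci_low = unname(stats::quantile(bs, 0.025)),
               ci_high = unname(stats::quantile(bs, 0.975)),
               p = 2 * stats::pnorm(-abs(est / se)), n_boot = n_boot,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$q <- bh_fdr(out$p)
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

fp_basis <- function(x, powers) {
  vapply(seq_along(powers), function(k) {
    p <- powers[k]
    col <- if (p == 0) log(x) else x^p
    if (k > 1 && powers[k] == powers[k - 1]) col <- col * log(x)   # repeated power
    col
  }, numeric(length(x)))
}

#' Variance explained by a fractional-polynomial fit
#'
#' Fits fractional polynomials of degree up to 2 of the log species
#' abundance to the log secretion potential, choosing powers from
#' \{-2, -1, -0.5, 0 (log), 0.5, 1, 2, 3\} by deviance, and reports the R² of
#' the best model together with the chosen powers.
#'
#' @param log_abundance predictor, one value per subject (log scale; shifted
#'   internally to be positive for the power transforms).
#' @param log_potential response.
#' @return list with `r_squared`, `powers`, `fit`.
#' @export
variance_explained <- function(log_abundance, log_potential) {
  ok <- is.finite(log_abundance) & is.finite(log_potential)
  x <- log_abundance[ok]; y <- log_potential[ok]
  if (length(y) < 10) stopf("need at least 10 subjects")
  if (stats::sd(x) == 0) return(list(r_squared = 0, powers = numeric(0), fit = NULL))
  # power transforms need a positive argument; shift-rescale only if needed
  xs <- if (min(x) > 0) x else (x - min(x)) / max(stats::sd(x), 1e-12) + 0.1
  powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  fit_fp <- function(pw) {
    fit <- stats::lm(y ~ fp_basis(xs, pw))
    list(powers = pw, fit = fit, rss = sum(stats::residuals(fit)^2))
  }
  pick <- function(cands) cands[[which.min(vapply(cands, `[[`, 0, "rss"))]]
  best1 <- pick(lapply(powers, fit_fp))
  cand2 <- unlist(lapply(seq_along(powers), function(i)
    lapply(powers[seq(i, length(powers))], function(p2) c(powers[i], p2))),
    recursive = FALSE)
  best2 <- pick(lapply(cand2, fit_fp))
  # closed-test selection: keep degree 2 only if it improves significantly
  # over the best degree-1 model (2 df for the extra power term)
  n <- length(y)
  df2 <- n - 3
  best <- best1
  if (best1$rss > 1e-12 && df2 > 0) {
    fstat <- (best1$rss - best2$rss) / 2 / (best2$rss / df2)
    if (is.finite(fstat) && stats::pf(fstat, 2, df2, lower.tail = FALSE) < 0.05)
      best <- best2
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else max(0, min(1, 1 - best$rss / tss))
  list(r_squared = r2, powers = best$powers, fit = best$fit)
}

#' Sulfur enrichment among significant secretion changes
#'
#' Cross-tabulates sulfur-containing versus other metabolites against
#' significance at `alpha` and computes the two-sided Fisher exact p-value by
#' hypergeometric enumeration.
#'
#' @param p_values named numeric of per-metabolite p-values.
#' @param is_sulfur named logical, same names.
#' @param alpha significance threshold (default 0.01).
#' @return list with `table` (2x2), `p`.
#' @export
sulfur_enrichment <- function(p_values, is_sulfur, alpha = 0.01) {
  if (length(p_values) == 0) stopf("empty input")
  if (!setequal(names(p_values), names(is_sulfur)))
    stopf("p_values and is_sulfur must share keys")
  s <- is_sulfur[names(p_values)]
  sig <- p_values < alpha
  tab <- matrix(c(sum(s & sig), sum(s & !sig), sum(!s & sig), sum(!s & !sig)),
                2, 2, byrow = TRUE,
                dimnames = list(c("sulfur", "non_sulfur"), c("significant", "not")))
  list(table = tab, p = fisher_exact_p(tab))
}

#' Two-sided Fisher exact p for a 2x2 table by enumeration
#'
#' Enumerates all tables with the observed margins and sums the
#' hypergeometric probabilities not exceeding that of the observed table.
#'
#' @param tab 2x2 integer matrix.
#' @return p-value.
#' @export
fisher_exact_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
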