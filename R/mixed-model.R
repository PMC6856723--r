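# Random-intercept linear models with cluster-robust (sandwich) covariance.
#
# Estimation is REML via lme4; the heteroscedasticity-robust covariance is
# computed from the marginal GLS representation with the compound-symmetry
# V_i implied by the fitted variance components:
#   bread A = sum_i X_i' V_i^-1 X_i,  meat M = sum_i X_i'V_i^-1 r_i r_i'V_i^-1 X_i,
#   vcov   = A^-1 M A^-1.

fit_ri_model <- function(formula, data, subject = "subject_id") {
  mf <- stats::model.frame(stats::update(formula, . ~ .), data = data)
  X <- stats::model.matrix(formula, mf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stopf("singular design: column(s) %s are collinear",
          paste(colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]], collapse = ", "))
  f <- stats::as.formula(paste(deparse(formula[[2]]), "~",
                               paste(deparse(formula[[3]], width.cutoff = 500), collapse = ""),
                               "+ (1 |", subject, ")"))
  fit <- suppressMessages(lme4::lmer(
    f, data = data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                check.conv.grad = "ignore",
                                calc.derivs = FALSE)))
  beta <- lme4::fixef(fit)
  Xf <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  cl <- lme4::getME(fit, "flist")[[1]]
  s2e <- stats::sigma(fit)^2
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp != "Residual"][1]
  rho <- s2b / s2e
  r <- y - drop(Xf %*% beta)

  p <- ncol(Xf)
  A <- matrix(0, p, p); M <- matrix(0, p, p)
  for (idx in split(seq_along(cl), cl)) {
    ni <- length(idx)
    if (ni == 0L) next
    Xi <- Xf[idx, , drop = FALSE]; ri <- r[idx]
    shr <- rho / (1 + ni * rho)
    cX <- colSums(Xi)
    A <- A + (crossprod(Xi) - shr * tcrossprod(cX)) / s2e
    gi <- (crossprod(Xi, ri) - shr * cX * sum(ri)) / s2e
    M <- M + tcrossprod(gi)
  }
  Ainv <- solve(A)
  m_cl <- nlevels(droplevels(cl))
  # CR1-style small-sample factor, as is conventional for cluster sandwiches
  vc_rob <- Ainv %*% M %*% Ainv * m_cl / max(1, m_cl - 1)
  dimnames(vc_rob) <- list(names(beta), names(beta))
  list(beta = beta, vcov_robust = vc_rob, vcov_model = Ainv,
       sigma_e2 = s2e, sigma_b2 = s2b, n_obs = length(y),
       n_subjects = nlevels(droplevels(cl)), fit = fit)
}

# Joint robust Wald test of the named coefficients being zero.
robust_wald <- function(m, terms) {
  miss <- setdiff(terms, names(m$beta))
  if (length(miss)) stopf("coefficients not in model: %s", paste(miss, collapse = ", "))
  b <- m$beta[terms]
  V <- m$vcov_robust[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  list(chi2 = stat, df = length(terms),
       p = stats::pchisq(stat, length(terms), lower.tail = FALSE))
}

coef_row <- function(m, term) {
  se <- sqrt(m$vcov_robust[term, term])
  est <- m$beta[[term]]
  z <- est / se
  data.frame(estimate = est, se = se,
             ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}
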