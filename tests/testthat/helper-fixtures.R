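# Shared fixtures and independent oracles.

# Linear chain A -> B -> C with an uptake exchange for A and a secretion
# exchange for C; max EX_C equals the uptake bound.
toy_chain_recon <- function(uptake = 10) {
  mets <- do.call(rbind, lapply(c("A", "B", "C", "biomass"), function(m)
    metabolite(m, "c", m, FALSE)))
  rxns <- list(
    reaction("EX_A", c("A[c]" = -1), -uptake, 1000),
    reaction("R1", c("A[c]" = -1, "B[c]" = 1), 0, 1000),
    reaction("R2", c("B[c]" = -1, "C[c]" = 1), 0, 1000),
    reaction("EX_C", c("C[c]" = -1), 0, 1000),
    reaction("BIO", c("A[c]" = -0.1, "biomass[c]" = 1), 0, 1000),
    reaction("SK_biomass", c("biomass[c]" = -1), 0, 1000))
  reconstruction("chain", mets, rxns, "BIO")
}

# Dense brute-force LP oracle: enumerate all bases and bound assignments of
# the nonbasic variables; independent of the simplex implementation.
brute_lp <- function(S, b, lb, ub, obj, maximize = TRUE, tol = 1e-7) {
  A <- as.matrix(S)
  m <- nrow(A); n <- ncol(A)
  best <- if (maximize) -Inf else Inf
  found <- FALSE
  for (bset in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, bset, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nb <- setdiff(seq_len(n), bset)
    for (mask in 0:(2^length(nb) - 1)) {
      xN <- lb[nb]
      if (length(nb)) {
        at_ub <- bitwAnd(mask, 2^(seq_along(nb) - 1)) > 0
        xN[at_ub] <- ub[nb][at_ub]
      }
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% xN else 0
      xB <- drop(solve(B, rhs))
      if (any(xB < lb[bset] - tol) || any(xB > ub[bset] + tol)) next
      x <- numeric(n); x[bset] <- xB; x[nb] <- xN
      found <- TRUE
      val <- sum(obj * x)
      best <- if (maximize) max(best, val) else min(best, val)
    }
  }
  if (!found) return(list(status = "infeasible", objective = NA_real_))
  list(status = "optimal", objective = best)
}

# Random small network-shaped LP that is feasible at v = 0.
rand_toy_lp <- function(seed, m = 4, n = 8) {
  set.seed(seed)
  S <- matrix(0, m, n)
  nz <- matrix(runif(m * n) < 0.4, m, n)
  S[nz] <- sample(c(-1, 1, -2, 2), sum(nz), replace = TRUE)
  lb <- ifelse(runif(n) < 0.5, -runif(n, 0, 5), 0)
  ub <- runif(n, 0, 5)
  obj <- round(rnorm(n), 2)
  list(S = S, b = rep(0, m), lb = lb, ub = ub, obj = obj)
}

# Candidate table for the matcher.
make_candidates <- function(n_cases, n_controls, n_flagged = 0, seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  d <- data.frame(
    subject_id = sprintf("M%03d", seq_len(n)),
    is_case = rep(c(1, 0), c(n_cases, n_controls)),
    age = round(rnorm(n, 65, 7), 1),
    bmi = round(rnorm(n, 26, 3), 1),
    sex = c(rep_len(c(1, 0), n_cases), rep_len(c(1, 0), n_controls)),
    med_flag = 0,
    stringsAsFactors = FALSE)
  if (n_flagged > 0) d$med_flag[sample.int(n, n_flagged)] <- 1
  d
}

# Exhaustive matching oracle: best achievable total score over all
# sex-matched selections of the target sizes.
exhaustive_match_score <- function(candidates, n_cases, n_controls) {
  cases <- candidates[candidates$is_case == 1, ]
  ctrls <- candidates[candidates$is_case == 0, ]
  best <- Inf
  for (ci in utils::combn(nrow(cases), n_cases, simplify = FALSE)) {
    sc <- cases[ci, ]
    for (ki in utils::combn(nrow(ctrls), n_controls, simplify = FALSE)) {
      sk <- ctrls[ki, ]
      if (sum(sc$sex == 1) != sum(sk$sex == 1)) next
      best <- min(best, score_selection(sc, sk)$total)
    }
  }
  best
}
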