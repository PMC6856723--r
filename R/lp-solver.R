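# Bounded-variable two-phase primal simplex.
#
# Solves   max/min  obj' v   s.t.  S v = b,  lb <= v <= ub  (all bounds finite).
#
# Bland's rule is used for both the entering and the leaving choice, which
# guarantees termination on the degenerate bases that metabolic networks
# produce routinely. The basis inverse is kept up to date by pivot updates and
# refactorised periodically for numerical hygiene. Problem sizes here are tiny
# (tens of rows), so the dense representation is deliberate.

solve_lp <- function(S, b, lb, ub, obj, maximize = TRUE,
                     tol = 1e-9, max_iter = 50000L) {
  A <- as.matrix(S)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n, length(obj) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds", call. = FALSE)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", objective = NA_real_, x = NULL))
  cvec <- if (maximize) obj else -obj

  # start every structural variable at the bound nearer zero
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_ub <- abs(lb) > abs(ub)
  r <- b - drop(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  big <- max(1, sum(abs(r))) * 1e6
  Afull <- cbind(A, diag(sgn, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(big, m))
  nf <- n + m

  state <- list(
    basis = n + seq_len(m),
    at_ub = c(at_ub, rep(FALSE, m)),           # status of nonbasic vars
    x = c(x0, abs(r)),
    Binv = diag(1 / sgn, m)
  )

  run <- function(state, cost, max_iter) {
    basis <- state$basis; at_ub <- state$at_ub; x <- state$x; Binv <- state$Binv
    in_basis <- logical(nf); in_basis[basis] <- TRUE
    since_refactor <- 0L
    for (iter in seq_len(max_iter)) {
      cB <- cost[basis]
      y <- drop(crossprod(Binv, cB))
      nonbasic <- which(!in_basis)
      zN <- cost[nonbasic] - drop(y %*% Afull[, nonbasic, drop = FALSE])
      up <- !at_ub[nonbasic] & zN > tol     # at lb, profitable to increase
      dn <- at_ub[nonbasic] & zN < -tol     # at ub, profitable to decrease
      elig <- nonbasic[up | dn]
      if (length(elig) == 0L)
        return(list(status = "optimal", basis = basis, at_ub = at_ub, x = x, Binv = Binv))
      q <- min(elig)                         # Bland: smallest index enters
      dirq <- if (at_ub[q]) -1 else 1
      d <- drop(Binv %*% Afull[, q])
      # basic variables move by -dirq * d * t as the entering var moves by dirq * t
      delta <- -dirq * d
      tmax <- ubf[q] - lbf[q]; leave <- 0L   # 0 means bound flip of q
      for (k in seq_len(m)) {
        if (delta[k] > tol) {
          tk <- (ubf[basis[k]] - x[basis[k]]) / delta[k]
        } else if (delta[k] < -tol) {
          tk <- (x[basis[k]] - lbf[basis[k]]) / (-delta[k])
        } else next
        if (tk < tmax - 1e-12 ||
            (tk < tmax + 1e-12 && leave != 0L && basis[k] < basis[leave])) {
          tmax <- tk; leave <- k
        }
      }
      if (!is.finite(tmax))
        return(list(status = "unbounded", basis = basis, at_ub = at_ub, x = x, Binv = Binv))
      tmax <- max(tmax, 0)
      x[q] <- x[q] + dirq * tmax
      x[basis] <- x[basis] + delta * tmax
      if (leave == 0L) {                     # entering variable flips bound
        at_ub[q] <- !at_ub[q]
        x[q] <- if (at_ub[q]) ubf[q] else lbf[q]
      } else {
        lv <- basis[leave]
        # leaving variable snaps to the bound it hit
        x[lv] <- if (delta[leave] > 0) ubf[lv] else lbf[lv]
        at_ub[lv] <- delta[leave] > 0
        in_basis[lv] <- FALSE; in_basis[q] <- TRUE
        basis[leave] <- q
        since_refactor <- since_refactor + 1L
        if (since_refactor >= 100L || abs(d[leave]) < 1e-8) {
          Binv <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                           error = function(e) NULL)
          if (is.null(Binv))
            return(list(status = "singular", basis = basis, at_ub = at_ub, x = x, Binv = NULL))
          since_refactor <- 0L
        } else {
          piv <- d[leave]
          Brow <- Binv[leave, ] / piv
          Binv <- Binv - outer(d, Brow)
          Binv[leave, ] <- Brow
        }
        x[basis] <- drop(Binv %*% (b - Afull[, !in_basis, drop = FALSE] %*% x[!in_basis]))
      }
    }
    list(status = "iteration_limit", basis = basis, at_ub = at_ub, x = x, Binv = Binv)
  }

  # Phase I: drive artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  s1 <- run(state, cost1, max_iter)
  if (s1$status %in% c("singular", "iteration_limit"))
    stop("LP solver failed in phase I: ", s1$status, call. = FALSE)
  if (sum(s1$x[n + seq_len(m)]) > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  # Phase II: pin artificials at zero and optimise the real objective
  ubf[n + seq_len(m)] <- 0
  s1$x[n + seq_len(m)] <- pmin(s1$x[n + seq_len(m)], 0)
  s1$x[n + seq_len(m)][s1$x[n + seq_len(m)] < 0] <- 0
  cost2 <- c(cvec, rep(0, m))
  s2 <- run(s1, cost2, max_iter)
  if (s2$status %in% c("singular", "iteration_limit"))
    stop("LP solver failed in phase II: ", s2$status, call. = FALSE)
  if (s2$status == "unbounded")
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  v <- s2$x[seq_len(n)]
  list(status = "optimal",
       objective = sum(obj * v),
       x = v)
}
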