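# Bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
#
# Metabolic steady-state problems are heavily degenerate (many reactions sit
# at a zero bound at the optimum), so the pivot rule matters more than speed:
# we use Bland's smallest-index rule throughout, which guarantees finite
# termination without anti-cycling perturbations.  Problem sizes in this
# package are tens of reactions, so a dense implementation with a fresh basis
# factorization per iteration is entirely adequate.

#' Solve a bounded linear program
#'
#' @param obj objective coefficient vector (length `n`).
#' @param A constraint matrix (`m` x `n`) of the equality system `A x = b`.
#' @param b right-hand side (length `m`).
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize maximize (default) or minimize the objective.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), the optimal `x` and the `objective` value (on the
#'   original max/min scale; `NA` unless optimal).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  A <- matrix(as.numeric(A), ncol = n)
  m <- nrow(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  cc <- if (maximize) obj else -obj

  if (m == 0L) {
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, pmax(pmin(0, ub), lb)))
    if (any(!is.finite(x) & cc != 0)) {
      return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
    }
    x[!is.finite(x)] <- 0
    val <- sum(cc * x)
    return(list(status = "optimal", x = x,
                objective = if (maximize) val else -val))
  }

  # Initial nonbasic point: each structural variable at its finite bound
  # nearest zero (free variables at 0); artificials absorb the residual.
  x0 <- numeric(n)
  stat0 <- integer(n)  # -1 at lower, +1 at upper, 0 free, 2 fixed (lb == ub)
  for (j in seq_len(n)) {
    if (lb[j] == ub[j]) { x0[j] <- lb[j]; stat0[j] <- 2L }
    else if (is.finite(lb[j]) && (!is.finite(ub[j]) || abs(lb[j]) <= abs(ub[j]))) {
      x0[j] <- lb[j]; stat0[j] <- -1L
    } else if (is.finite(ub[j])) { x0[j] <- ub[j]; stat0[j] <- 1L }
    else { x0[j] <- 0; stat0[j] <- 0L }
  }
  r <- b - as.numeric(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  xf <- c(x0, abs(r))
  statf <- c(stat0, rep(NA_integer_, m))  # NA = basic
  basis <- n + seq_len(m)

  run_phase <- function(cvec, basis, xf, statf, ubf, iter_left) {
    repeat {
      if (iter_left <= 0L) stop_catapot("simplex iteration limit reached")
      iter_left <- iter_left - 1L
      B <- Afull[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y)) stop_catapot("singular basis in simplex (numerical failure)")
      nonbasic <- which(!is.na(statf) & statf != 2L)
      zn <- cvec[nonbasic] - as.numeric(y %*% Afull[, nonbasic, drop = FALSE])
      stn <- statf[nonbasic]
      up_ok <- (stn == -1L | stn == 0L) & zn > tol
      dn_ok <- (stn == 1L | stn == 0L) & zn < -tol
      elig <- which(up_ok | dn_ok)
      if (!length(elig)) {
        return(list(basis = basis, xf = xf, statf = statf,
                    status = "optimal", iter_left = iter_left))
      }
      k <- elig[which.min(nonbasic[elig])]  # Bland: smallest variable index
      j <- nonbasic[k]
      s <- if (up_ok[k]) 1 else -1
      w <- solve(B, Afull[, j])
      d <- -s * w
      # Ratio test: own bound span, then basic variables hitting a bound.
      t_own <- if (s > 0) ubf[j] - xf[j] else xf[j] - lbf[j]
      t_bas <- rep(Inf, m)
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (d[i] > tol && is.finite(ubf[bi])) t_bas[i] <- (ubf[bi] - xf[bi]) / d[i]
        else if (d[i] < -tol && is.finite(lbf[bi])) t_bas[i] <- (xf[bi] - lbf[bi]) / (-d[i])
      }
      t_bas <- pmax(t_bas, 0)
      tmin_bas <- if (m) min(t_bas) else Inf
      tstar <- min(t_own, tmin_bas)
      if (!is.finite(tstar)) {
        return(list(basis = basis, xf = xf, statf = statf,
                    status = "unbounded", iter_left = iter_left))
      }
      if (t_own <= tmin_bas + tol && is.finite(t_own)) {
        # Bound flip: j stays nonbasic at its opposite bound.
        xf[j] <- xf[j] + s * t_own
        xf[basis] <- xf[basis] + d * t_own
        statf[j] <- if (s > 0) 1L else -1L
      } else {
        cand <- which(t_bas <= tstar + tol)
        rleave <- cand[which.min(basis[cand])]  # Bland on leaving variable
        lv <- basis[rleave]
        xf[j] <- xf[j] + s * tstar
        xf[basis] <- xf[basis] + d * tstar
        statf[lv] <- if (d[rleave] > 0) 1L else -1L
        xf[lv] <- if (d[rleave] > 0) ubf[lv] else lbf[lv]
        statf[j] <- NA_integer_
        basis[rleave] <- j
      }
    }
  }

  # Phase 1: drive the artificials to zero.
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, basis, xf, statf, ubf, max_iter)
  if (ph1$status != "optimal" || sum(ph1$xf[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  # Freeze artificials at zero (they may linger in a degenerate basis).
  ubf[n + seq_len(m)] <- 0
  statf <- ph1$statf
  statf[n + seq_len(m)][!is.na(statf[n + seq_len(m)])] <- 2L
  ph2 <- run_phase(c(cc, rep(0, m)), ph1$basis, ph1$xf, statf, ubf, ph1$iter_left)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }
  # Re-derive the basic values from scratch to wash out incremental drift.
  basis <- ph2$basis
  xf <- ph2$xf
  nb <- setdiff(seq_len(n + m), basis)
  rhs <- b - as.numeric(Afull[, nb, drop = FALSE] %*% xf[nb])
  xf[basis] <- solve(Afull[, basis, drop = FALSE], rhs)
  x <- xf[seq_len(n)]
  val <- sum(cc * x)
  list(status = "optimal", x = x, objective = if (maximize) val else -val)
}

#' Enumerate the vertices of a bounded LP and return the exact optimum
#'
#' Independent oracle for [lp_solve()]: walks every assignment of variables
#' to \{lower bound, upper bound, free\}, solves the equality system for the
#' free block, and keeps feasible solutions.  Exponential in the number of
#' variables, so only usable on toy problems (the test suite keeps
#' `n <= 8`).  All bounds must be finite.
#'
#' @inheritParams lp_solve
#' @return list with `objective` (best vertex value, `-Inf` if infeasible)
#'   and the attaining `x`.
#' @keywords internal
lp_enumerate_optimum <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- length(obj)
  A <- matrix(as.numeric(A), ncol = n)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  cc <- if (maximize) obj else -obj
  best <- -Inf
  bestx <- rep(NA_real_, n)
  codes <- rep(list(0:2), n)  # 0 lower, 1 upper, 2 free
  grid <- as.matrix(expand.grid(codes))
  for (g in seq_len(nrow(grid))) {
    asg <- grid[g, ]
    x <- ifelse(asg == 0L, lb, ifelse(asg == 1L, ub, NA_real_))
    fr <- which(asg == 2L)
    fx <- which(asg != 2L)
    rhs <- b - if (length(fx)) as.numeric(A[, fx, drop = FALSE] %*% x[fx]) else b * 0
    if (length(fr)) {
      Af <- A[, fr, drop = FALSE]
      qrA <- qr(Af)
      if (qrA$rank < length(fr)) next  # not a vertex: underdetermined block
      sol <- qr.coef(qrA, rhs)
      if (anyNA(sol)) next
      x[fr] <- sol
    }
    if (max(abs(as.numeric(A %*% x) - b)) > 1e-7) next
    if (any(x < lb - 1e-9) || any(x > ub + 1e-9)) next
    v <- sum(cc * x)
    if (v > best + 1e-12) { best <- v; bestx <- x }
  }
  list(objective = if (maximize) best else -best, x = bestx)
}
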