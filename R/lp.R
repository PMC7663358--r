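# Bounded-variable two-phase primal simplex.
#
# Solves min c'x s.t. A x = b, l <= x <= u with finite bounds. Written for the
# dense, modestly sized programs arising from toy and curated metabolic
# networks (up to a few hundred variables); callers encode unbounded fluxes as
# the LP_INF sentinel so programs are never truly unbounded.

# Magnitude used to encode an unbounded flux in LP form. I/O keeps true Inf;
# only the solver layer substitutes the sentinel.
LP_INF <- 1e6

#' Solve a bounded linear program
#'
#' Minimizes \code{sum(obj * x)} subject to \code{mat \%*\% x == rhs} and
#' \code{lb <= x <= ub}, using a two-phase primal simplex with lower/upper
#' bounded variables (Dantzig pricing, switching to Bland's rule after a run
#' of degenerate pivots). All bounds must be finite.
#'
#' @param obj numeric objective coefficients, length n.
#' @param mat numeric constraint matrix, m x n.
#' @param rhs numeric right-hand side, length m.
#' @param lb,ub numeric variable bounds, length n, all finite.
#' @param maximize if \code{TRUE} maximize instead of minimize.
#' @param tol reduced-cost optimality tolerance.
#' @param max_iter iteration cap across both phases.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"iteration_limit"}, \code{"singular"} or \code{"unbounded"}),
#'   the solution \code{x} and \code{objval} (on the original min/max scale;
#'   \code{NA} unless optimal).
#' @export
solve_lp <- function(obj, mat, rhs, lb, ub, maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  mat <- as.matrix(mat)
  m <- nrow(mat)
  n <- ncol(mat)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds; encode infinity as a sentinel")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  cvec <- if (maximize) -obj else obj

  ntot <- n + m
  # start nonbasic structural variables at the bound closer to zero
  start_at_lb <- abs(lb) <= abs(ub)
  x0 <- ifelse(start_at_lb, lb, ub)
  resid <- rhs - as.vector(mat %*% x0)
  art_sign <- ifelse(resid >= 0, 1, -1)
  A <- cbind(mat, diag(art_sign, m, m))
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(LP_INF * max(1, max(abs(rhs), 1)), m))
  xfull <- c(x0, abs(resid))
  basis <- (n + 1L):ntot

  run <- simplex_run(A, rhs, LB, UB, n, m, cvec, tol, max_iter,
                     xfull, basis, at_upper_init = c(!start_at_lb))
  if (run$status != "optimal")
    return(list(status = run$status, x = rep(NA_real_, n), objval = NA_real_))
  xsol <- run$x[seq_len(n)]
  list(status = "optimal", x = xsol, objval = sum(obj * xsol))
}

# Simplex driver. Nonbasic status vectors are indexed by variable id (not by
# position within the nonbasic set), which keeps pivot bookkeeping simple.
simplex_run <- function(A, rhs, LB, UB, n, m, cvec, tol, max_iter,
                        xfull, basis, at_upper_init) {
  ntot <- n + m
  is_basic <- rep(FALSE, ntot)
  is_basic[basis] <- TRUE
  at_up <- rep(FALSE, ntot)
  at_up[seq_len(n)] <- at_upper_init

  phase_costs <- list(c(rep(0, n), rep(1, m)), c(cvec, rep(0, m)))
  iters <- max_iter

  for (phase in 1:2) {
    costs <- phase_costs[[phase]]
    if (phase == 2L) UB[(n + 1L):ntot] <- 0  # artificials pinned at zero
    degen_run <- 0L
    repeat {
      if (iters <= 0L) return(list(status = "iteration_limit", x = xfull))
      iters <- iters - 1L
      Bidx <- which(is_basic)
      Nidx <- which(!is_basic)
      Bmat <- A[, Bidx, drop = FALSE]
      xfull[Nidx] <- ifelse(at_up[Nidx], UB[Nidx], LB[Nidx])
      xB <- tryCatch(
        as.vector(solve(Bmat, rhs - A[, Nidx, drop = FALSE] %*% xfull[Nidx])),
        error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular", x = xfull))
      xfull[Bidx] <- xB
      y <- tryCatch(as.vector(solve(t(Bmat), costs[Bidx])),
                    error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular", x = xfull))
      d <- costs[Nidx] - as.vector(crossprod(A[, Nidx, drop = FALSE], y))
      movable <- UB[Nidx] - LB[Nidx] > tol
      eligible <- movable &
        ((!at_up[Nidx] & d < -tol) | (at_up[Nidx] & d > tol))
      if (!any(eligible)) break
      cand <- Nidx[eligible]
      if (degen_run > 60L) {
        j <- min(cand)                                 # Bland: anti-cycling
      } else {
        j <- cand[which.max(abs(d[eligible]))]         # Dantzig pricing
      }
      s <- if (at_up[j]) -1 else 1
      w <- tryCatch(as.vector(solve(Bmat, A[, j])), error = function(e) NULL)
      if (is.null(w)) return(list(status = "singular", x = xfull))
      rate <- -s * w                                   # d x_B / d t
      t_best <- UB[j] - LB[j]
      leave_pos <- 0L
      leave_up <- FALSE
      for (i in seq_along(Bidx)) {
        bi <- Bidx[i]
        if (rate[i] < -tol) {
          ti <- max(0, (xfull[bi] - LB[bi]) / (-rate[i]))
          to_up <- FALSE
        } else if (rate[i] > tol) {
          ti <- max(0, (UB[bi] - xfull[bi]) / rate[i])
          to_up <- TRUE
        } else next
        take <- if (leave_pos == 0L) ti < t_best - 1e-12 || ti <= t_best
          else ti < t_best - 1e-12 || (ti <= t_best + 1e-12 && bi < Bidx[leave_pos])
        if (take) {
          t_best <- min(t_best, ti)
          leave_pos <- i
          leave_up <- to_up
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded", x = xfull))
      degen_run <- if (t_best < 1e-11) degen_run + 1L else 0L
      if (leave_pos == 0L) {
        at_up[j] <- !at_up[j]                          # bound flip
      } else {
        lv <- Bidx[leave_pos]
        is_basic[lv] <- FALSE
        is_basic[j] <- TRUE
        at_up[lv] <- leave_up
        at_up[j] <- FALSE
      }
    }
    if (phase == 1L) {
      Bidx <- which(is_basic)
      Nidx <- which(!is_basic)
      xfull[Nidx] <- ifelse(at_up[Nidx], UB[Nidx], LB[Nidx])
      xB <- tryCatch(
        as.vector(solve(A[, Bidx, drop = FALSE],
                        rhs - A[, Nidx, drop = FALSE] %*% xfull[Nidx])),
        error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular", x = xfull))
      xfull[Bidx] <- xB
      art_val <- sum(xfull[(n + 1L):ntot])
      if (art_val > 1e-7 * max(1, max(abs(rhs))))
        return(list(status = "infeasible", x = xfull))
    }
  }
  list(status = "optimal", x = xfull)
}
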