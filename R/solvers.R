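#' @include AllClasses.R
NULL

#' Non-negative least squares (Lawson--Hanson active set)
#'
#' Solves \eqn{\min_x \|Ax - b\|_2^2} subject to \eqn{x \ge 0}. Written
#' here because no NNLS/quadratic-programming package is available in the
#' target environment; the classic active-set algorithm is exact at the
#' scale used (tens of columns).
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param maxit iteration cap; exceeding it is reported as
#'   \code{converged = FALSE} (callers treat that as a solver failure).
#' @param wtol dual (optimality) tolerance on the projected gradient;
#'   defaults to a scale-relative value. Callers embedding penalty rows
#'   must supply a tolerance on the scale of the *unaugmented* gradient.
#' @return list: \code{x} (solution), \code{deviance}
#'   (\eqn{\|Ax-b\|_2^2}), \code{converged}, \code{iterations}.
#' @export
nnls <- function(A, b, maxit = 30L * ncol(A) + 100L, wtol = NULL) {
  A <- as.matrix(A); b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  # primal feasibility tolerance is absolute -- solutions live on O(1) scale
  if (is.null(wtol)) wtol <- 1e-10 * max(1, max(abs(w)))
  eps <- 1e-11
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > wtol) {
    iter <- iter + 1L
    if (iter > maxit)
      return(list(x = x, deviance = sum((A %*% x - b)^2),
                  converged = FALSE, iterations = iter))
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      cf <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      cf[is.na(cf)] <- 0
      s[passive] <- cf
      if (min(s[passive]) > eps) { x <- s; break }
      q <- passive & (s <= eps)
      ratio <- x[q] / (x[q] - s[q])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (s - x)
      passive <- passive & (x > eps)
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, deviance = sum((A %*% x - b)^2), converged = TRUE,
       iterations = iter)
}

# Bounded-simplex least squares:
#   min ||Ax - b||^2  s.t.  0 <= x_i <= 1,  sum(x) <= 1.
# The upper bounds are implied by the simplex inequality, which is reduced
# to NNLS with a slack column s >= 0 and a heavily weighted equality row
# sum(x) + s = 1 (Lawson-Hanson penalty trick for equality constraints).
.boundedSimplexLS <- function(A, b, penalty = 1e4) {
  A <- as.matrix(A); b <- as.numeric(b)
  Tn <- ncol(A)
  # penalty weight balances constraint violation (~ grad / lam^2, must stay
  # < 1e-8) against float cancellation noise in the gradient (~ lam^2 * eps)
  lam <- penalty * max(1, max(abs(A)))
  Aa <- rbind(cbind(A, 0), lam * rep(1, Tn + 1L))
  ba <- c(b, lam)
  fit <- nnls(Aa, ba,
              wtol = 1e-7 * max(1, max(abs(crossprod(A, b)))))
  if (!fit$converged)
    stop("bounded least-squares solver failed to converge (",
         fit$iterations, " iterations)")
  x <- fit$x[seq_len(Tn)]
  viol <- sum(fit$x) - 1
  if (abs(viol) > 1e-6)
    stop(sprintf("solver returned infeasible solution (sum + slack = %.8f)",
                 sum(fit$x)))
  x <- pmin(x, 1)
  list(x = x, residual = sum((A %*% x - b)^2),
       undetermined = max(0, 1 - sum(x)))
}
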