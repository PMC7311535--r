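#' Non-negative least squares (Lawson–Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the classical
#' Lawson–Hanson active-set algorithm: starting from the all-zero solution,
#' repeatedly move the variable with the largest positive gradient of the
#' dual (`w = A'(b - A x)`) into the passive set, solve the unconstrained
#' least-squares problem on the passive set, and back-track along the line
#' segment towards feasibility whenever that solution leaves the
#' non-negative orthant. Terminates at the KKT point, which is the unique
#' global minimum when `A` has full column rank on the passive set.
#'
#' @param A numeric matrix (m x n), `m >= 1`.
#' @param b numeric vector of length m.
#' @param tol tolerance on the dual vector used for the stopping test;
#'   default `10 * .Machine$double.eps * max(abs(A)) * max(dim(A))`.
#' @param max_iter safety cap on outer iterations (default `3 * n`).
#' @return list with `x` (the solution, length n), `residual` (the
#'   Euclidean norm of `b - A x`) and `iterations`.
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 3)
#' nnls_fit(A, c(2, 1, 1))$x
#' @export
nnls_fit <- function(A, b, tol = NULL, max_iter = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  if (is.null(max_iter)) max_iter <- max(30L, 3L * n)

  x <- numeric(n)
  passive <- logical(n)
  iter <- 0L
  w <- crossprod(A, b - A %*% x)[, 1L]

  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE

    repeat {
      # unconstrained LS on the passive set (rank-deficiency guarded by qr)
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      # back-track to the boundary and drop the variable(s) hitting zero
      viol <- passive & z <= tol
      alpha <- min(x[viol] / (x[viol] - z[viol]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)[, 1L]
  }

  r <- b - A %*% x
  list(x = x, residual = sqrt(sum(r^2)), iterations = iter)
}
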