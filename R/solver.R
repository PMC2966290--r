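#' Soft-thresholding operator
#'
#' `sign(v) * max(|v| - t, 0)`, the proximal operator of the l1 penalty and
#' the elementwise shrinkage step of the iterative thresholding solver.
#'
#' @param v numeric vector.
#' @param t non-negative threshold.
#' @return Numeric vector of the same length as `v`.
#' @export
soft_threshold <- function(v, t) {
  stopifnot(t >= 0)
  sign(v) * pmax(abs(v) - t, 0)
}

#' Solve the naive elastic net by iterative soft-thresholding
#'
#' Minimizes
#' \deqn{\frac{1}{n}\|y - Xw\|_2^2 + \mu\|w\|_2^2 + \tau\|w\|_1}
#' by proximal gradient descent (ISTA): a gradient step on the smooth part
#' followed by soft-thresholding.  With `step_size = "auto"` the step is
#' `1/L` with `L` the largest eigenvalue of `(2/n) X'X + 2 mu I` (power
#' iteration), which guarantees a non-increasing objective.  Optional
#' Nesterov acceleration (`accelerate = TRUE`) uses a monotone safeguard so
#' the objective trace remains non-increasing.
#'
#' The function operates on the matrix it is given; for penalties to be
#' comparable across features the caller standardizes columns and centers
#' `y` (as [l1l2()] does).
#'
#' @param X numeric matrix, `n x p`.
#' @param y numeric response vector of length `n`, centered.
#' @param mu non-negative l2 (ridge) penalty.
#' @param tau non-negative l1 penalty; `tau > 0` yields sparsity.
#' @param tolerance relative l2 change of `w` at which to stop.
#' @param max_iterations iteration cap; reaching it sets
#'   `converged = FALSE` with a warning rather than an error.
#' @param step_size `"auto"` or a positive step.
#' @param accelerate use safeguarded Nesterov acceleration.
#' @param w_init optional warm start (defaults to zero).
#' @param keep_trace record the per-iteration objective values.
#' @return List with `w`, `iterations`, `converged`, `objective` and,
#'   when requested, `trace`.
#' @export
fit_naive_elastic_net <- function(X, y, mu, tau,
                                  tolerance = 1e-6, max_iterations = 10000L,
                                  step_size = "auto", accelerate = FALSE,
                                  w_init = NULL, keep_trace = FALSE) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    l1l2_stop("length(y) must equal nrow(X)", "l1l2dap_structural_error")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    l1l2_stop("X and y must be finite (impute missing genotypes first)",
              "l1l2dap_data_error")
  stopifnot(mu >= 0, tau >= 0, tolerance > 0, max_iterations >= 1)
  step <- if (identical(step_size, "auto")) {
    1 / lipschitz_constant(X, mu)
  } else {
    stopifnot(is.numeric(step_size), step_size > 0)
    step_size
  }
  if (is.null(w_init)) w_init <- numeric(ncol(X))
  res <- l1l2_ista(X, y, mu, tau, step, tolerance,
                   as.integer(max_iterations), isTRUE(accelerate),
                   isTRUE(keep_trace), as.numeric(w_init))
  res$w <- as.numeric(res$w)
  if (!res$converged)
    warning(sprintf("elastic-net solver stopped at max_iterations = %d",
                    max_iterations), call. = FALSE)
  res
}

#' Indices of the selected support
#'
#' @param w weight vector.
#' @param zero_tol entries with `|w| > zero_tol` are selected.  The solver's
#'   thresholding produces exact zeros, so the default 0 suffices on its
#'   output.
#' @return Integer index vector (1-based).
#' @export
select_support <- function(w, zero_tol = 0) {
  which(abs(w) > zero_tol)
}

#' Regularized least squares refit on a selected support
#'
#' Ridge regression restricted to the selected columns,
#' \deqn{\tilde w = (X_S' X_S + \lambda n I)^{-1} X_S' y,}
#' which corrects the shrinkage bias of the naive elastic-net weights.  The
#' `lambda * n` scaling matches the `1/n` loss convention, so `lambda` is
#' comparable across sample sizes.
#'
#' @param X_sub numeric matrix restricted to the support columns.
#' @param y response vector.
#' @param lambda non-negative ridge penalty.
#' @return Corrected weight vector of length `ncol(X_sub)`; length zero for
#'   an empty support.
#' @export
rls_debias <- function(X_sub, y, lambda) {
  X_sub <- as.matrix(X_sub)
  stopifnot(lambda >= 0)
  if (ncol(X_sub) == 0L) return(numeric(0))
  n <- nrow(X_sub)
  A <- crossprod(X_sub) + diag(lambda * n, ncol(X_sub))
  as.numeric(solve(A, crossprod(X_sub, y)))
}
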