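#' Fit an L1L2 regression model
#'
#' The two-stage L1L2 estimator for quantitative traits: first the naive
#' elastic net
#' \deqn{\hat w = \arg\min_w \frac{1}{n}\|y - Xw\|_2^2 + \mu\|w\|_2^2 +
#'   \tau\|w\|_1}
#' is solved by iterative soft-thresholding, selecting a sparse support;
#' then the weights on that support are corrected by a regularized least
#' squares (ridge) refit, since the naive solution selects the relevant
#' features but shrinks their weights.  `mu` and `tau` control feature
#' selection; `lambda` controls the bias of the corrected weights.
#'
#' Columns of `X` are standardized to zero mean and unit variance and `y`
#' is centered before solving (the penalties are scale-sensitive); the
#' returned weights and intercept are mapped back to the original scale,
#' so `predict()` works on raw encoded genotypes.  Constant columns get a
#' zero weight.  An empty support (large `tau`) yields a degenerate model
#' that predicts the training mean rather than an error, so wide grids can
#' be swept safely.
#'
#' @param X numeric matrix (`n x p`) or a fully imputed [genotype_matrix()].
#' @param y numeric trait vector of length `n`.
#' @param mu non-negative l2 penalty of the selection stage.
#' @param tau non-negative l1 penalty of the selection stage.
#' @param lambda non-negative ridge penalty of the correction stage.
#' @param tolerance,max_iterations,step_size,accelerate solver settings,
#'   see [fit_naive_elastic_net()].
#' @return An object of class `l1l2`: a list with components `weights`
#'   (named, original scale, exact zeros off support), `naive_weights`
#'   (uncorrected, original scale), `support` (integer indices),
#'   `intercept`, the hyperparameters, standardization statistics,
#'   `fitted.values`, `residuals` and solver metadata (`iterations`,
#'   `converged`).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100 * 20), 100, 20)
#' y <- X[, 1] - 2 * X[, 5] + rnorm(100, sd = 0.1)
#' fit <- l1l2(X, y, mu = 1e-3, tau = 0.5, lambda = 1e-3)
#' fit
#' head(ranked_features(fit)$items)
#' @seealso [predict.l1l2()], [ranked_features()], [l1l2_dap()]
#' @export
l1l2 <- function(X, y, mu, tau, lambda = 0,
                 tolerance = 1e-6, max_iterations = 10000L,
                 step_size = "auto", accelerate = FALSE) {
  if (inherits(X, "genotype_matrix")) {
    if (any(X$missing_mask))
      l1l2_stop("genotype matrix has missing calls; run impute_genotypes()",
                "l1l2dap_data_error")
    X <- X$values
  }
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n)
    l1l2_stop("length(y) must equal nrow(X)", "l1l2dap_structural_error")
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))

  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  degenerate <- !is.finite(scale) | scale <= 0
  scale[degenerate] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  net <- fit_naive_elastic_net(Xs, yc, mu, tau,
                               tolerance = tolerance,
                               max_iterations = max_iterations,
                               step_size = step_size,
                               accelerate = accelerate)
  support <- select_support(net$w)
  w_std <- numeric(p)
  if (length(support)) {
    w_std[support] <- rls_debias(Xs[, support, drop = FALSE], yc, lambda)
  }
  weights <- w_std / scale
  naive <- net$w / scale
  intercept <- y_mean - sum(weights * center)
  fitted <- as.numeric(X %*% weights + intercept)

  structure(list(mu = mu, tau = tau, lambda = lambda,
                 weights = stats::setNames(weights, nm),
                 naive_weights = stats::setNames(naive, nm),
                 support = support,
                 intercept = intercept,
                 center = stats::setNames(center, nm),
                 scale = stats::setNames(scale, nm),
                 y_mean = y_mean,
                 feature_names = nm,
                 fitted.values = fitted,
                 residuals = y - fitted,
                 iterations = net$iterations,
                 converged = net$converged,
                 objective = net$objective),
            class = "l1l2")
}

#' @export
print.l1l2 <- function(x, ...) {
  cat(sprintf("L1L2 model (mu = %g, tau = %g, lambda = %g)\n",
              x$mu, x$tau, x$lambda))
  cat(sprintf("  %d of %d features selected; intercept = %.4g\n",
              length(x$support), length(x$weights), x$intercept))
  if (!is.na(x$converged))
    cat(sprintf("  solver: %d iterations, %s\n", x$iterations,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.l1l2 <- function(object, ...) {
  s <- object$support
  tab <- data.frame(feature = object$feature_names[s],
                    weight = unname(object$weights[s]),
                    naive_weight = unname(object$naive_weights[s]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$weight), tab$feature), , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(model = object, coefficients = tab,
              n_selected = length(s), p = length(object$weights),
              train_rmse = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.l1l2"
  out
}

#' @export
print.summary.l1l2 <- function(x, n = 10L, ...) {
  print(x$model)
  cat(sprintf("  training RMSE: %.4g\n", x$train_rmse))
  if (x$n_selected > 0) {
    cat(sprintf("  top selected features (of %d):\n", x$n_selected))
    print(head(x$coefficients, n), digits = 4)
  } else {
    cat("  empty support: model predicts the training mean\n")
  }
  invisible(x)
}

#' @export
coef.l1l2 <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' @export
fitted.l1l2 <- function(object, ...) object$fitted.values

#' @export
residuals.l1l2 <- function(object, ...) object$residuals

#' Predict phenotypes from a fitted L1L2 model
#'
#' @param object an `l1l2` fit.
#' @param newdata numeric matrix or [genotype_matrix()] with the same
#'   columns (in the same order, and with matching names when present) as
#'   the training data.
#' @param ... ignored.
#' @return Numeric vector of predicted trait values on the original scale.
#' @export
predict.l1l2 <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  if (inherits(newdata, "genotype_matrix")) {
    if (any(newdata$missing_mask))
      l1l2_stop("genotype matrix has missing calls; run impute_genotypes()",
                "l1l2dap_data_error")
    newdata <- newdata$values
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights))
    l1l2_stop("newdata column count does not match the fitted model",
              "l1l2dap_structural_error")
  nm <- colnames(newdata)
  if (!is.null(nm) && !identical(nm, object$feature_names))
    l1l2_stop("newdata column names do not match the fitted model",
              "l1l2dap_structural_error")
  as.numeric(newdata %*% object$weights + object$intercept)
}

#' Weight-profile plot of a fitted model
#'
#' Plots |weight| against feature index, highlighting the selected support;
#' a quick visual of the sparsity pattern.
#'
#' @param x an `l1l2` fit.
#' @param ... passed to [plot()].
#' @export
plot.l1l2 <- function(x, ...) {
  p <- length(x$weights)
  plot(seq_len(p), abs(x$weights), type = "h", col = "grey70",
       xlab = "feature index", ylab = "|debiased weight|",
       main = sprintf("L1L2 support: %d / %d", length(x$support), p), ...)
  if (length(x$support))
    points(x$support, abs(x$weights[x$support]), pch = 16, col = "firebrick")
  invisible(x)
}

#' Rank selected features by weight magnitude
#'
#' Features on the support, ordered by decreasing |debiased weight|; ties
#' broken lexicographically by feature name.  Features off the support are
#' excluded, so the result is a partial list over the feature universe —
#' the input the Canberra stability machinery expects.
#'
#' @param m an `l1l2` fit, or any object with `weights` and
#'   `feature_names`.
#' @return A [ranked_list()] over the model's feature universe, with the
#'   corresponding weights attached as attribute `"weights"`.
#' @export
ranked_features <- function(m) {
  w <- m$weights
  nm <- m$feature_names
  on <- which(w != 0)
  ord <- on[order(-abs(w[on]), nm[on])]
  rl <- ranked_list(nm[ord], nm)
  attr(rl, "weights") <- unname(w[ord])
  rl
}

#' Hyperparameter grid for the L1L2 selection stage
#'
#' Builds a (mu, tau, lambda) grid with tau values log-spaced as fractions
#' of `tau_max = 2 max_j |x_j' y| / n` computed on the standardized data —
#' the smallest tau at which the naive elastic-net solution is identically
#' zero — so the grid spans supports from near-dense down to a handful of
#' features regardless of scale.
#'
#' @param X matrix or [genotype_matrix()] (fully imputed).
#' @param y trait vector.
#' @param mu l2 penalties to cross.
#' @param tau_fractions fractions of `tau_max` to use as tau values.
#' @param lambda ridge penalties of the correction stage to cross.
#' @return A `data.frame` with columns `mu`, `tau`, `lambda`, one row per
#'   grid point.
#' @export
l1l2_grid <- function(X, y,
                      mu = c(1e-3, 1e-2, 1e-1),
                      tau_fractions = exp(seq(log(0.02), log(0.5),
                                              length.out = 5)),
                      lambda = c(1e-2, 1, 1e2)) {
  if (inherits(X, "genotype_matrix")) X <- X$values
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0
  yc <- y - mean(y)
  tau_max <- 2 * max(abs(crossprod(Xs, yc))) / nrow(Xs)
  g <- expand.grid(mu = mu, tau = tau_fractions * tau_max, lambda = lambda,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(g$mu, g$tau, g$lambda), , drop = FALSE]
}
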