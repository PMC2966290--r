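test_that("soft thresholding shrinks towards zero", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  v <- c(-2.3, 0, 4.1, 0.01)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(c(-3, 3), 1), c(-2, 2))
})

test_that("with no penalties the solver agrees with ordinary least squares", {
  set.seed(21)
  X <- matrix(rnorm(50 * 6), 50, 6)
  beta <- rnorm(6)
  y <- as.numeric(X %*% beta + rnorm(50, sd = 0.2))
  yc <- y - mean(y)
  w <- fit_naive_elastic_net(X, yc, mu = 0, tau = 0, tolerance = 1e-10)$w
  w_ols <- as.numeric(solve(crossprod(X), crossprod(X, yc)))
  expect_lt(max(abs(w - w_ols)), 1e-6)
})

test_that("orthonormal design reproduces the soft-threshold closed form", {
  set.seed(22)
  n <- 60; p <- 10
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # Q'Q / n = I
  yc <- rnorm(n)
  for (h in list(c(0, 0.2), c(0.3, 0.1), c(1, 0.8))) {
    mu <- h[1]; tau <- h[2]
    w <- fit_naive_elastic_net(Q, yc, mu, tau, tolerance = 1e-10)$w
    closed <- soft_threshold(as.numeric(crossprod(Q, yc)) / n, tau / 2) /
      (1 + mu)
    expect_lt(max(abs(w - closed)), 1e-6)
  }
})

test_that("tau at or above the subgradient bound gives the all-zero solution", {
  set.seed(23)
  X <- matrix(rnorm(40 * 8), 40, 8)
  yc <- rnorm(40)
  tau_max <- 2 * max(abs(crossprod(X, yc))) / nrow(X)
  w <- fit_naive_elastic_net(X, yc, mu = 0.01, tau = tau_max * 1.0001)$w
  expect_equal(w, numeric(8))
})

test_that("objective is non-increasing over iterations, plain and accelerated", {
  set.seed(24)
  X <- matrix(rnorm(80 * 30), 80, 30)
  yc <- as.numeric(X[, 1] - X[, 2] + rnorm(80))
  for (acc in c(FALSE, TRUE)) {
    r <- fit_naive_elastic_net(X, yc, mu = 0.01, tau = 0.2,
                               accelerate = acc, keep_trace = TRUE)
    expect_true(all(diff(r$trace) <= 1e-12))
    expect_true(r$converged)
  }
  # both modes reach the same minimizer
  w1 <- fit_naive_elastic_net(X, yc, 0.01, 0.2, tolerance = 1e-10)$w
  w2 <- fit_naive_elastic_net(X, yc, 0.01, 0.2, tolerance = 1e-10,
                              accelerate = TRUE)$w
  expect_lt(max(abs(w1 - w2)), 1e-6)
})

test_that("sparsity is non-decreasing in tau at fixed mu", {
  set.seed(25)
  X <- matrix(rnorm(60 * 25), 60, 25)
  yc <- as.numeric(X %*% c(rep(1, 3), rep(0, 22)) + rnorm(60, sd = 0.5))
  taus <- exp(seq(log(0.01), log(2), length.out = 8))
  sizes <- vapply(taus, function(t)
    length(select_support(fit_naive_elastic_net(X, yc, 0.05, t)$w)),
    integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("solver output is exactly sparse so zero_tol hardly matters", {
  set.seed(26)
  X <- matrix(rnorm(50 * 12), 50, 12)
  yc <- as.numeric(X[, 3] * 2 + rnorm(50, sd = 0.3))
  w <- fit_naive_elastic_net(X, yc, 0.01, 0.5)$w
  expect_identical(select_support(w, 0), select_support(w, 1e-12))
  expect_equal(select_support(c(0, 0.3, -0.001), 1e-8), c(2L, 3L))
  expect_equal(select_support(numeric(4)), integer(0))
})

test_that("RLS debiasing matches its closed forms", {
  set.seed(27)
  # single unit-norm column, lambda = 0: univariate OLS
  x <- rnorm(30); x <- x / sqrt(sum(x^2))
  y <- 3 * x + rnorm(30, sd = 0.1)
  expect_equal(rls_debias(matrix(x), y, 0), sum(x * y) / sum(x * x))
  # lambda = 0, independent columns: OLS on the support
  X <- matrix(rnorm(60 * 4), 60, 4)
  y2 <- as.numeric(X %*% c(1, -2, 0.5, 0) + rnorm(60, sd = 0.2))
  expect_equal(rls_debias(X, y2, 0),
               as.numeric(solve(crossprod(X), crossprod(X, y2))))
  # identity X with lambda * n = 1: (I + I)^{-1} y = y / 2
  n <- 5
  expect_equal(rls_debias(diag(n), 1:5, 1 / n), (1:5) / 2)
  expect_equal(rls_debias(matrix(numeric(0), 3, 0), 1:3, 0), numeric(0))
})

test_that("debiased norm shrinks to zero as lambda grows", {
  set.seed(28)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- as.numeric(X %*% c(1, 2, -1))
  norms <- vapply(c(0, 0.1, 1, 10, 1e3), function(l)
    sqrt(sum(rls_debias(X, y, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("solver solution is at least as good as glmnet's on the shared objective", {
  skip_if_not_installed("glmnet")
  set.seed(29)
  n <- 50; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  yc <- as.numeric(X[, 1] * 2 - X[, 4] + rnorm(n, sd = 0.5))
  yc <- yc - mean(yc)
  for (h in list(c(0.05, 0.4), c(0.01, 0.1), c(0.2, 0.8))) {
    mu <- h[1]; tau <- h[2]
    w <- fit_naive_elastic_net(X, yc, mu, tau, tolerance = 1e-10)$w
    lam <- tau / 2 + mu
    wg <- as.numeric(stats::coef(glmnet::glmnet(
      X, yc, alpha = (tau / 2) / lam, lambda = lam,
      standardize = FALSE, intercept = FALSE, thresh = 1e-14)))[-1]
    expect_lte(l1l2_objective(X, yc, w, mu, tau),
               l1l2_objective(X, yc, wg, mu, tau) + 1e-8)
  }
})

test_that("non-finite inputs and dimension mismatches are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_naive_elastic_net(X, rnorm(9), 0, 0),
               class = "l1l2dap_structural_error")
  X[1, 1] <- NA
  expect_error(fit_naive_elastic_net(X, rnorm(10), 0, 0),
               class = "l1l2dap_data_error")
})

test_that("hitting max_iterations warns and flags instead of failing", {
  set.seed(30)
  X <- matrix(rnorm(40 * 10), 40, 10)
  yc <- rnorm(40)
  expect_warning(
    r <- fit_naive_elastic_net(X, yc, 0.01, 0.01, tolerance = 1e-14,
                               max_iterations = 3L),
    "max_iterations")
  expect_false(r$converged)
})
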