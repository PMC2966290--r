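# Independent oracles and small fixture builders used across the suite.

# Full naive elastic-net objective.
l1l2_objective <- function(X, y, w, mu, tau) {
  sum((y - X %*% w)^2) / nrow(X) + mu * sum(w^2) + tau * sum(abs(w))
}

# Exact global support by exhaustive enumeration: iterate supports by size
# and sign patterns within each support, solve the stationarity system
#   (2/n X_S'X_S + 2 mu I) w = 2/n X_S'y - tau * sign,
# and accept the first point satisfying full KKT (sign consistency plus
# |(2/n) x_j'(y - Xw)| <= tau on the zero coordinates).  For mu > 0 the
# problem is strictly convex, so the KKT-consistent point is the unique
# global minimizer.
oracle_support_exact <- function(X, y, mu, tau, tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  G <- crossprod(X) * (2 / n)
  b <- as.numeric(crossprod(X, y)) * (2 / n)
  for (k in 0:p) {
    supports <- if (k == 0) list(integer(0)) else asplit(utils::combn(p, k), 2)
    for (S in supports) {
      S <- as.integer(S)
      w <- numeric(0)
      if (k > 0) {
        A <- G[S, S, drop = FALSE] + diag(2 * mu, k)
        found <- FALSE
        for (m in 0:(2^k - 1)) {
          sg <- 1 - 2 * as.integer(intToBits(m))[1:k]
          w <- solve(A, b[S] - tau * sg)
          if (all(sign(w) == sg)) { found <- TRUE; break }
        }
        if (!found) next
      }
      r <- if (k == 0) y else as.numeric(y - X[, S, drop = FALSE] %*% w)
      others <- setdiff(seq_len(p), S)
      if (length(others)) {
        grad0 <- abs((2 / n) * as.numeric(crossprod(X[, others, drop = FALSE], r)))
        if (max(grad0) > tau + tol) next
      }
      return(list(support = S, w = w))
    }
  }
  stop("exhaustive oracle found no KKT-consistent support")
}

# Upper bound per support: ridge fit restricted to S, then charge the l1
# cost of that ridge solution; minimized over all 2^p supports.
ridge_support_min_objective <- function(X, y, mu, tau) {
  n <- nrow(X); p <- ncol(X)
  best <- sum(y^2) / n
  for (m in 1:(2^p - 1)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) > 0)
    Xs <- X[, S, drop = FALSE]
    w <- solve(crossprod(Xs) / n + diag(mu, length(S)),
               crossprod(Xs, y) / n)
    obj <- sum((y - Xs %*% w)^2) / n + mu * sum(w^2) + tau * sum(abs(w))
    if (obj < best) best <- obj
  }
  best
}

# Random partial ranked list over a universe of p features.
random_partial_list <- function(p, k = sample.int(p, 1)) {
  u <- paste0("f", seq_len(p))
  ranked_list(sample(u, k), u)
}

# Small deterministic cohort for pipeline tests.
small_cohort <- function(seed = 42, n_families = 30L, n_snps = 200L,
                         n_causal = 4L, heritability = 0.5, ...) {
  simulate_cohort(cohort_spec(n_families = n_families, n_snps = n_snps,
                              n_causal = n_causal,
                              heritability = heritability, seed = seed, ...))
}
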