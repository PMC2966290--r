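test_that("interfamily splits keep families whole and hit the dev fraction", {
  fam <- rep(paste0("f", 1:10), each = 6)
  plan <- interfamily_splits(fam, n_resamplings = 8, dev_fraction = 0.7,
                             k_folds = 5, seed = 2)
  for (sp in plan$resamplings) {
    expect_length(intersect(sp$dev, sp$val), 0)
    expect_setequal(c(sp$dev, sp$val), seq_along(fam))
    # equal family sizes: exactly 7 of 10 families in development
    expect_length(unique(fam[sp$dev]), 7)
    # no family straddles the boundary
    expect_length(intersect(unique(fam[sp$dev]), unique(fam[sp$val])), 0)
    # folds partition the development set, at family level
    expect_length(sp$folds, length(sp$dev))
    fold_by_fam <- tapply(sp$folds, fam[sp$dev], function(v)
      length(unique(v)))
    expect_true(all(fold_by_fam == 1))
  }
})

test_that("split plans are deterministic in the seed", {
  fam <- rep(paste0("f", 1:12), times = sample(3:7, 12, replace = TRUE))
  p1 <- interfamily_splits(fam, 5, 0.6, 4, seed = 77)
  p2 <- interfamily_splits(fam, 5, 0.6, 4, seed = 77)
  p3 <- interfamily_splits(fam, 5, 0.6, 4, seed = 78)
  expect_identical(p1, p2)
  expect_false(identical(p1$resamplings, p3$resamplings))
})

test_that("degenerate family structures are rejected", {
  expect_error(interfamily_splits(rep("f1", 10)),
               class = "l1l2dap_precondition_error")
  expect_error(interfamily_splits(c(rep("big", 90), rep("small", 10)),
                                  dev_fraction = 0.7),
               class = "l1l2dap_precondition_error")
})

test_that("squared correlation conventions", {
  y <- c(1, 2, 3, 5)
  expect_equal(squared_correlation(y, y), 1)
  expect_equal(squared_correlation(y, -y + 10), 1)
  expect_equal(squared_correlation(y, rep(2, 4)), 0)
  expect_error(squared_correlation(1, 1), class = "l1l2dap_precondition_error")
})

test_that("internal CV reproduces a hand-run fold loop for one grid point", {
  set.seed(51)
  n <- 60; p <- 15
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("snp", 1:p)))
  y <- as.numeric(X[, 2] - X[, 9] + rnorm(n, sd = 0.4))
  folds <- rep(1:3, each = 20)
  grid <- data.frame(mu = 0.01, tau = 0.2, lambda = 0.01)
  got <- run_internal_cv(X, y, folds, grid)
  # manual loop with the same plugin settings
  plugin <- l1l2_plugin()
  mses <- numeric(3); lists <- vector("list", 3)
  for (f in 1:3) {
    fit <- plugin$fit(X[folds != f, ], y[folds != f], as.list(grid))
    pred <- predict(fit, X[folds == f, ])
    mses[f] <- mean((y[folds == f] - pred)^2)
    lists[[f]] <- ranked_features(fit)
  }
  expect_equal(got$cv_mse, mean(mses))
  expect_equal(got$cv_stability, stability_indicator(lists)$mean_distance)
  expect_error(run_internal_cv(X, y, rep(1, n), grid),
               class = "l1l2dap_precondition_error")
})

test_that("model selection follows the MSE-tolerance-then-stability rule", {
  gp <- data.frame(mu = c(0.1, 0.1, 0.1), tau = c(0.1, 0.2, 0.3),
                   lambda = 1,
                   cv_mse = c(1.00, 1.02, 1.30),
                   cv_stability = c(0.5, 0.2, 0.01))
  # 5% tolerance admits the first two; the more stable second wins
  expect_equal(select_model(gp, 0.05)$tau, 0.2)
  # zero tolerance: pure argmin MSE
  expect_equal(select_model(gp, 0)$tau, 0.1)
  # single grid point returns itself
  expect_equal(select_model(gp[3, , drop = FALSE], 0.05)$tau, 0.3)
  # equal MSE, stabilities 0.2 vs 0.5: the 0.2 point
  gp2 <- data.frame(mu = 0.1, tau = c(0.1, 0.2), lambda = 1,
                    cv_mse = c(1, 1), cv_stability = c(0.5, 0.2))
  expect_equal(select_model(gp2, 0)$tau, 0.2)
  # stability ties break towards larger tau (sparser model)
  gp3 <- data.frame(mu = 0.1, tau = c(0.1, 0.4), lambda = 1,
                    cv_mse = c(1, 1), cv_stability = c(0.2, 0.2))
  expect_equal(select_model(gp3, 0)$tau, 0.4)
})

test_that("model selection is invariant to grid-point order", {
  set.seed(52)
  gp <- data.frame(mu = runif(12), tau = runif(12), lambda = runif(12),
                   cv_mse = sample(c(1, 1.01, 1.2), 12, replace = TRUE),
                   cv_stability = sample(c(0.1, 0.2, 0.3), 12,
                                         replace = TRUE))
  ref <- select_model(gp)
  for (i in 1:10) {
    perm <- gp[sample.int(12), , drop = FALSE]
    expect_equal(select_model(perm), ref, ignore_attr = TRUE)
  }
})

test_that("the full protocol runs deterministically on a small cohort", {
  cohort <- small_cohort(seed = 53, n_families = 25L, n_snps = 120L,
                         n_causal = 3L, heritability = 0.6)
  g <- impute_genotypes(cohort$genotypes, 1)
  y <- cohort$phenotype
  plan <- interfamily_splits(g$family_ids, n_resamplings = 3, k_folds = 3,
                             seed = 54)
  grid <- l1l2_grid(g$values, y, mu = 1e-2, tau_fractions = c(0.1, 0.3),
                    lambda = c(1e-2, 1))
  r1 <- l1l2_dap(g, y, plan, grid)
  r2 <- l1l2_dap(g, y, plan, grid)
  expect_identical(r1[c("r2", "mean_r2", "accuracy_stability")],
                   r2[c("r2", "mean_r2", "accuracy_stability")])
  expect_true(all(r1$r2 >= 0 & r1$r2 <= 1))
  expect_equal(nrow(r1$accuracy_stability), 3 * nrow(grid))
  # a heritable trait with strong signal should beat chance on average
  expect_gt(r1$mean_r2, 0.1)
  # weights matrix shape for downstream saturation
  W <- dap_weights(r1)
  expect_equal(dim(W), c(120L, 3L))
})

test_that("breaking family boundaries inflates validation accuracy", {
  cohort <- small_cohort(seed = 55, n_families = 30L, n_snps = 100L,
                         n_causal = 3L, heritability = 0.4,
                         samples_per_family = 8L)
  g <- impute_genotypes(cohort$genotypes, 1)
  y <- cohort$phenotype
  plan <- interfamily_splits(g$family_ids, n_resamplings = 4, k_folds = 3,
                             seed = 56)
  grid <- data.frame(mu = 1e-2, tau = l1l2_grid(g$values, y,
                                                mu = 1e-2,
                                                tau_fractions = 0.2,
                                                lambda = 1e-2)$tau,
                     lambda = 1e-2)
  clean <- l1l2_dap(g, y, plan, grid)
  # corrupt the plan: move half of each validation family's samples into
  # development, so relatives straddle the split
  leaky <- plan
  for (r in seq_along(leaky$resamplings)) {
    sp <- leaky$resamplings[[r]]
    val_fams <- unique(g$family_ids[sp$val])
    steal <- unlist(lapply(val_fams, function(f) {
      idx <- sp$val[g$family_ids[sp$val] == f]
      idx[seq_len(floor(length(idx) / 2))]
    }))
    sp$dev <- c(sp$dev, steal)
    sp$val <- setdiff(sp$val, steal)
    sp$folds <- c(sp$folds, rep(1L, length(steal)))
    leaky$resamplings[[r]] <- sp
  }
  leaked <- l1l2_dap(g, y, leaky, grid)
  expect_gt(leaked$mean_r2, clean$mean_r2)
})

test_that("bootstrap baseline protocol selects, evaluates and flags bias", {
  set.seed(57)
  n <- 120; p <- 30
  fam <- rep(paste0("f", 1:20), each = 6)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("snp", 1:p)))
  y <- as.numeric(2 * X[, 3] - 1.5 * X[, 17])  # noiseless 2-sparse
  g <- genotype_matrix((X > 0) + (X > 1), snp_records(colnames(X), "1",
                                                      seq_len(p) * 100),
                       paste0("s", 1:n), fam)
  # single parameter set: trivially selected, evaluated on all resamplings
  res1 <- bootstrap_dap(X_or_g <- X, y, svr_plugin("linear"),
                        data.frame(cost = 1), n_grid_bootstraps = 3,
                        n_eval_bootstraps = 5, seed = 58)
  expect_length(res1$r2, 5)
  expect_true(isTRUE(attr(res1, "selection_bias_prone")))
  expect_output(print(res1), "over-optimistic")
  # linear plugin on noiseless 2-sparse data predicts almost perfectly
  expect_gt(res1$mean_r2, 0.95)
  # determinism
  res2 <- bootstrap_dap(X, y, svr_plugin("linear"), data.frame(cost = 1),
                        n_grid_bootstraps = 3, n_eval_bootstraps = 5,
                        seed = 58)
  expect_equal(res1$r2, res2$r2)
})

test_that("bootstrap grid search picks the better parameter set", {
  set.seed(59)
  n <- 100; p <- 10
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("s", 1:p)))
  y <- as.numeric(X[, 1] + rnorm(n, sd = 0.1))
  res <- bootstrap_dap(X, y, svr_plugin("radial"),
                       data.frame(gamma = c(2.5e-4, 0.1), cost = 1),
                       n_grid_bootstraps = 4, n_eval_bootstraps = 4,
                       seed = 60)
  expect_true(res$selected$gamma %in% c(2.5e-4, 0.1))
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
})
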