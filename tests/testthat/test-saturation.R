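test_that("top-ranked qualification uses the nonzero-weight percentile", {
  # one resampling: |w| = 9..1 on nine SNPs, 91 exact zeros
  w <- c(9:1, rep(0, 91))
  W <- matrix(w, ncol = 1,
              dimnames = list(paste0("snp", 1:100), NULL))
  top <- find_top_ranked(W, percentile = 10, min_runs = 1)
  # ceiling of 10% of 9 nonzero weights -> exactly the largest one
  expect_equal(top$name, "snp1")

  # a SNP qualifying in 13 of 15 runs is excluded at min_runs = 14
  W15 <- matrix(0, 3, 15, dimnames = list(c("a", "b", "c"), NULL))
  W15["a", ] <- 5                      # qualifies everywhere
  W15["b", 1:13] <- 5                  # 13 runs only
  W15["c", ] <- 0.1                    # never in top decile when a present
  top15 <- find_top_ranked(W15, 10, 14)
  expect_true("a" %in% top15$name)
  expect_false("b" %in% top15$name)

  # identical weight vectors: the multi-run top set equals the single-run set
  Wrep <- W[, rep(1, 15), drop = FALSE]
  for (mr in c(1L, 8L, 15L))
    expect_equal(find_top_ranked(Wrep, 10, mr)$name, top$name)

  expect_error(find_top_ranked(W, 10, min_runs = 2),
               class = "l1l2dap_precondition_error")
})

test_that("duplicated genotype columns are always top-correlated", {
  set.seed(61)
  n <- 80
  base <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  vals <- cbind(base, base, sample(0:2, n, replace = TRUE))
  g <- genotype_matrix(vals,
                       snp_records(c("dup1", "dup2", "other"),
                                   c("1", "1", "2"), c(100, 5000, 300)),
                       paste0("s", 1:n), rep("f", n))
  sat <- find_top_correlated(g, "dup1", threshold = 1.0)
  expect_equal(sat$snp, "dup2")
  expect_equal(sat$correlation, 1)
  expect_equal(sat$distance_bp, 4900)
  # flipping the encoding (2 - x) flips the sign, not the inclusion
  vals2 <- vals; vals2[, 2] <- 2 - vals2[, 2]
  g2 <- genotype_matrix(vals2, g$snps, g$sample_ids, g$family_ids)
  sat2 <- find_top_correlated(g2, "dup1", threshold = 1.0)
  expect_equal(sat2$snp, "dup2")
  expect_equal(sat2$correlation, -1)
})

test_that("a noisy matrix with no duplicates has no hits at threshold 1", {
  set.seed(62)
  vals <- matrix(sample(0:2, 300, replace = TRUE), 50, 6)
  g <- genotype_matrix(vals, snp_records(paste0("x", 1:6), "1",
                                         1:6 * 1000),
                       paste0("s", 1:50), rep("f", 50))
  stopifnot(max(abs(cor(vals)[upper.tri(diag(6))])) < 1)
  sat <- find_top_correlated(g, "x1", threshold = 1.0)
  expect_equal(nrow(sat), 0)
})

test_that("raising the threshold never adds a top-correlated SNP", {
  cohort <- small_cohort(seed = 63, n_families = 40L, n_snps = 150L,
                         n_causal = 3L)
  g <- impute_genotypes(cohort$genotypes, 1)
  top <- g$snps$name[cohort$true_model$causal_index]
  sweep <- saturation_sweep(g, top, thresholds = c(0.6, 0.7, 0.8, 0.9))
  sets <- lapply(sweep$results, function(r) paste(r$top_snp, r$snp))
  for (i in 1:3) expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  # saturation only ever adds markers to the panel
  for (r in sweep$results)
    expect_true(all(top %in% union(top, r$snp)))
})

test_that("LD-block members are recovered as top-correlated", {
  cohort <- simulate_cohort(cohort_spec(
    n_families = 150L, samples_per_family = 6L, n_snps = 300L,
    ld_block_size = 10L, within_block_flip_prob = 0.05,
    maf_range = c(0.25, 0.5), n_causal = 3L,
    heritability = 0.5, missing_rate = 0, seed = 64))
  g <- cohort$genotypes
  tm <- cohort$true_model
  top <- g$snps$name[tm$causal_index]
  sat <- find_top_correlated(g, top, threshold = 0.8)
  recovered <- vapply(seq_along(top), function(i) {
    members <- g$snps$name[tm$block_of == tm$causal_blocks[i]]
    members <- setdiff(members, top[i])
    mean(members %in% sat$snp[sat$top_snp == top[i]])
  }, numeric(1))
  expect_gte(mean(recovered), 0.8)
})

test_that("distance summaries reproduce the per-SNP statistics", {
  r <- structure(data.frame(
    top_snp = c("t1", "t1", "t1", "t2"),
    snp = c("a", "b", "c", "d"),
    correlation = c(0.9, -0.85, 0.95, 0.9),
    same_chromosome = c(TRUE, TRUE, FALSE, TRUE),
    distance_bp = c(1000, 3000, NA, 1000),
    weight = c(0.1, 0, 0.2, 0.3)),
    class = c("saturation_result", "data.frame"))
  s <- distance_summary(r)
  t1 <- s[s$top_snp == "t1", ]
  expect_equal(t1$n, 3)
  expect_equal(t1$mean_distance_bp, 2000)
  expect_equal(t1$min_distance_bp, 1000)
  expect_equal(t1$max_distance_bp, 3000)
  # single correlated SNP at distance 1000
  t2 <- s[s$top_snp == "t2", ]
  expect_equal(c(t2$n, t2$mean_distance_bp, t2$min_distance_bp,
                 t2$max_distance_bp), c(1, 1000, 1000, 1000))
  # reporting rule: at least k top-correlated SNPs
  expect_equal(distance_summary(r, min_correlated = 2)$top_snp, "t1")
  # empty result: empty summary, no error
  empty <- distance_summary(find_top_correlated(
    impute_genotypes(small_cohort(seed = 65, n_families = 5L,
                                  n_snps = 10L,
                                  n_causal = 1L)$genotypes, 1),
    character(0), 0.9))
  expect_equal(nrow(empty), 0)
})

test_that("pooled median distance shrinks as the threshold rises", {
  cohort <- simulate_cohort(cohort_spec(
    n_families = 150L, samples_per_family = 6L, n_snps = 400L,
    ld_block_size = 20L, within_block_flip_prob = 0.05,
    ld_decay = "markov", n_causal = 4L,
    heritability = 0.5, missing_rate = 0, seed = 66))
  g <- cohort$genotypes
  top <- g$snps$name[cohort$true_model$causal_index]
  sweep <- saturation_sweep(g, top, thresholds = c(0.6, 0.7, 0.8, 0.9))
  med <- sweep$pooled$median_distance_bp
  med <- med[!is.na(med)]
  expect_true(all(diff(med) <= 0))
})
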