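#' Family-respecting development/validation resamplings
#'
#' Builds the resampling plan of the Data Analysis Protocol: in each of
#' `n_resamplings` rounds, whole families are shuffled (seeded) and
#' assigned to the development set until it holds at least `dev_fraction`
#' of the samples; the remaining families form the validation set.  Close
#' relatives share most of their genome, so letting a family straddle the
#' split leaks information and inflates validation accuracy — no family
#' ever does.  Internal cross-validation folds are likewise assigned at
#' the family level within each development set.
#'
#' @param family_ids character vector, one family label per sample.
#' @param n_resamplings number of development/validation rounds.
#' @param dev_fraction target fraction of samples in development,
#'   in (0, 1).
#' @param k_folds number of internal CV folds per development set.
#' @param seed integer seed; the plan is a pure function of its arguments.
#' @return An object of class `split_plan`: per resampling, integer sample
#'   indices `dev` and `val` and an integer `folds` vector (one fold id
#'   per development sample).
#' @export
interfamily_splits <- function(family_ids, n_resamplings = 15L,
                               dev_fraction = 0.7, k_folds = 10L,
                               seed = 1L) {
  family_ids <- as.character(family_ids)
  fams <- unique(family_ids)
  if (length(fams) < 2L)
    l1l2_stop("need at least two families to split", "l1l2dap_precondition_error")
  stopifnot(dev_fraction > 0, dev_fraction < 1, n_resamplings >= 1,
            k_folds >= 2)
  n <- length(family_ids)
  fam_size <- table(family_ids)
  if (max(fam_size) > dev_fraction * n)
    l1l2_stop("a single family exceeds dev_fraction of all samples; interfamily splits impossible",
              "l1l2dap_precondition_error")
  resamplings <- with_preserved_rng({
    set.seed(seed)
    lapply(seq_len(n_resamplings), function(r) {
      ord <- sample(fams)
      csize <- cumsum(as.numeric(fam_size[ord]))
      n_dev_fam <- which(csize >= dev_fraction * n)[1]
      dev_fams <- ord[seq_len(n_dev_fam)]
      dev <- which(family_ids %in% dev_fams)
      val <- setdiff(seq_len(n), dev)
      if (length(val) == 0L)
        l1l2_stop("dev_fraction leaves no validation families",
                  "l1l2dap_precondition_error")
      # family-level fold assignment: greedy balance on sample counts
      dev_shuffled <- sample(dev_fams)
      fold_of_fam <- integer(length(dev_shuffled))
      load <- numeric(k_folds)
      for (i in order(-as.numeric(fam_size[dev_shuffled]))) {
        f <- which.min(load)
        fold_of_fam[i] <- f
        load[f] <- load[f] + fam_size[dev_shuffled[i]]
      }
      folds <- fold_of_fam[match(family_ids[dev], dev_shuffled)]
      list(dev = dev, val = val, folds = folds)
    })
  })
  structure(list(resamplings = resamplings, n_resamplings = n_resamplings,
                 dev_fraction = dev_fraction, k_folds = k_folds,
                 seed = seed, family_ids = family_ids),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d interfamily resamplings, dev fraction %.2f, %d internal folds (seed %d)\n",
              x$n_resamplings, x$dev_fraction, x$k_folds, x$seed))
  invisible(x)
}

#' Squared Pearson correlation between truth and prediction
#'
#' The validation accuracy measure of the protocol.  A constant prediction
#' (zero variance, e.g. a degenerate empty-support model) scores 0 by
#' convention rather than being undefined, so wide penalty grids can be
#' swept without crashes.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return Scalar in \[0, 1\].
#' @export
squared_correlation <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    l1l2_stop("need two equal-length vectors of length >= 2",
              "l1l2dap_precondition_error")
  if (sd(y_pred) == 0 || sd(y_true) == 0) return(0)
  min(1, cor(y_true, y_pred)^2)
}

#' Regressor plugins for the protocols
#'
#' A plugin bundles `fit(X, y, params)`, `predict(model, X)` and
#' `ranked_list(model, universe)` so the protocol engines can drive either
#' the package's L1L2 estimator or an external regressor.
#'
#' `l1l2_plugin()` drives [l1l2()]; its ranked lists are the support
#' features by decreasing |debiased weight| (partial lists).
#'
#' `svr_plugin()` wraps epsilon support vector regression from \pkg{e1071}.
#' `params` may hold `gamma`, `cost` and `epsilon`.  With the Gaussian
#' (radial) kernel there is no meaningful weight vector, so ranked lists
#' are only available from the linear kernel, where the primal weights
#' `t(coefs) %*% SV` rank all features (full lists).
#'
#' @param tolerance,max_iterations,accelerate solver settings passed to
#'   [l1l2()].
#' @return A list with elements `name`, `fit`, `predict`, `ranked_list`
#'   (possibly `NULL`) and `weights`.
#' @export
l1l2_plugin <- function(tolerance = 1e-5, max_iterations = 5000L,
                        accelerate = TRUE) {
  list(name = "l1l2",
       fit = function(X, y, params)
         l1l2(X, y, mu = params$mu, tau = params$tau,
              lambda = if (is.null(params$lambda)) 0 else params$lambda,
              tolerance = tolerance, max_iterations = max_iterations,
              accelerate = accelerate),
       predict = function(model, X) predict(model, X),
       weights = function(model) model$weights,
       ranked_list = function(model, universe) ranked_features(model))
}

#' @rdname l1l2_plugin
#' @param kernel `"radial"` (Gaussian, for prediction) or `"linear"` (for
#'   feature ranking).
#' @export
svr_plugin <- function(kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  get_weights <- function(model) {
    w <- as.numeric(crossprod(model$coefs, model$SV))
    names(w) <- colnames(model$SV)
    w
  }
  list(name = paste0("svr_", kernel),
       fit = function(X, y, params) {
         args <- list(x = X, y = y, type = "eps-regression",
                      kernel = kernel, scale = FALSE)
         for (nm in intersect(names(params), c("gamma", "cost", "epsilon")))
           args[[nm]] <- params[[nm]]
         do.call(e1071::svm, args)
       },
       predict = function(model, X) as.numeric(predict(model, X)),
       weights = if (kernel == "linear") get_weights else NULL,
       ranked_list = if (kernel == "linear") {
         function(model, universe) {
           w <- get_weights(model)
           ord <- order(-abs(w), names(w))
           rl <- ranked_list(names(w)[ord], universe)
           attr(rl, "weights") <- unname(w[ord])
           rl
         }
       } else NULL)
}

#' Internal cross-validation over a hyperparameter grid
#'
#' For each grid point, fits on `k - 1` folds and scores mean squared
#' error on the held-out fold; the `k` fold-wise ranked marker lists are
#' summarized by the Canberra [stability_indicator()].  The output backs
#' the accuracy-stability plane in which the model is selected.
#'
#' @param X numeric matrix of the development samples.
#' @param y trait values for the development samples.
#' @param folds integer fold id per development sample (from a
#'   [interfamily_splits()] plan).
#' @param grid `data.frame` of hyperparameter columns, one row per grid
#'   point (e.g. from [l1l2_grid()]).
#' @param plugin a regressor plugin; default [l1l2_plugin()].
#' @return `grid` augmented with columns `cv_mse` and `cv_stability`.
#' @export
run_internal_cv <- function(X, y, folds, grid, plugin = l1l2_plugin()) {
  if (nrow(grid) == 0L)
    l1l2_stop("empty hyperparameter grid", "l1l2dap_precondition_error")
  fold_ids <- sort(unique(folds))
  if (length(fold_ids) < 2L)
    l1l2_stop("internal CV needs at least two folds", "l1l2dap_precondition_error")
  if (min(table(folds)) < 2L)
    l1l2_stop("an internal fold has fewer than 2 samples",
              "l1l2dap_precondition_error")
  universe <- colnames(X)
  if (is.null(universe)) universe <- paste0("x", seq_len(ncol(X)))
  cv_mse <- cv_stab <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    mses <- numeric(length(fold_ids))
    lists <- vector("list", length(fold_ids))
    for (fi in seq_along(fold_ids)) {
      hold <- folds == fold_ids[fi]
      model <- plugin$fit(X[!hold, , drop = FALSE], y[!hold], params)
      pred <- plugin$predict(model, X[hold, , drop = FALSE])
      mses[fi] <- mean((y[hold] - pred)^2)
      if (!is.null(plugin$ranked_list))
        lists[[fi]] <- plugin$ranked_list(model, universe)
    }
    cv_mse[gi] <- mean(mses)
    cv_stab[gi] <- if (is.null(plugin$ranked_list)) NA_real_ else
      stability_indicator(lists)$mean_distance
  }
  out <- grid
  out$cv_mse <- cv_mse
  out$cv_stability <- cv_stab
  out
}

#' Select a model in the accuracy-stability plane
#'
#' Among grid points whose CV mean squared error is within
#' `mse_tolerance` (a fraction) of the best, returns the one with the most
#' stable marker lists (minimal Canberra stability indicator).  Ties are
#' broken towards sparser models (larger `tau`), then lexicographically by
#' the remaining hyperparameters, so the choice is deterministic and
#' invariant to the order of the grid rows.
#'
#' @param grid_points output of [run_internal_cv()].
#' @param mse_tolerance fractional MSE slack around the minimum; 0 reduces
#'   to the pure MSE argmin with a stability tie-break.
#' @return The selected row of `grid_points` (a one-row `data.frame`).
#' @export
select_model <- function(grid_points, mse_tolerance = 0.05) {
  if (nrow(grid_points) == 0L)
    l1l2_stop("no grid points to select from", "l1l2dap_precondition_error")
  stopifnot(mse_tolerance >= 0)
  ok <- grid_points$cv_mse <= (1 + mse_tolerance) * min(grid_points$cv_mse)
  cand <- grid_points[ok, , drop = FALSE]
  stab <- if (all(is.na(cand$cv_stability))) rep(0, nrow(cand)) else
    cand$cv_stability
  keys <- list(stab)
  if (!is.null(cand$tau)) keys <- c(keys, list(-cand$tau))
  for (nm in intersect(c("mu", "tau", "lambda"), names(cand)))
    keys <- c(keys, list(cand[[nm]]))
  ord <- do.call(order, keys)
  cand[ord[1], , drop = FALSE]
}

# guard asserted on every resampling of every protocol run
.assert_no_leakage <- function(dev, val) {
  if (length(intersect(dev, val)))
    l1l2_stop("development and validation sets overlap", "l1l2dap_leakage_error")
}

#' Run the L1L2 Data Analysis Protocol
#'
#' The full stability-aware protocol: for each family-respecting
#' development/validation resampling, an internal k-fold cross-validation
#' over the hyperparameter grid measures accuracy (MSE) and marker-list
#' stability (Canberra indicator); [select_model()] picks the operating
#' point; the model is refit on the whole development set and scored by
#' [squared_correlation()] on the untouched validation families.  The
#' protocol never lets validation samples influence model selection, so
#' the aggregate accuracy is an unbiased estimate.
#'
#' @param g a fully imputed [genotype_matrix()] or plain numeric matrix.
#' @param y numeric trait vector aligned with the rows of `g`.
#' @param plan a [interfamily_splits()] plan; required for a
#'   `genotype_matrix` unless supplied, in which case it is built from the
#'   family ids with defaults and `seed`.
#' @param grid hyperparameter grid (default [l1l2_grid()] on the full
#'   data).
#' @param mse_tolerance accuracy slack of [select_model()].
#' @param plugin regressor plugin; default [l1l2_plugin()].
#' @param seed seed used only when `plan` must be built here.
#' @return An object of class `dap_result`: per-resampling selected
#'   hyperparameters, validation r-squared, validation ranked list and
#'   weight vector; `r2` (vector over resamplings), `mean_r2`, `range_r2`;
#'   and `accuracy_stability`, the per-resampling grid table backing the
#'   accuracy-stability diagnostic plot.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_families = 30, n_snps = 150,
#'                                       n_causal = 4, seed = 7))
#' plan <- interfamily_splits(cohort$genotypes$family_ids,
#'                            n_resamplings = 3, k_folds = 3, seed = 7)
#' res <- l1l2_dap(cohort$genotypes, cohort$phenotype, plan)
#' res
#' }
#' @export
l1l2_dap <- function(g, y, plan = NULL, grid = NULL, mse_tolerance = 0.05,
                     plugin = l1l2_plugin(), seed = 1L) {
  if (inherits(g, "genotype_matrix")) {
    if (any(g$missing_mask))
      l1l2_stop("genotype matrix has missing calls; run impute_genotypes()",
                "l1l2dap_data_error")
    fam <- g$family_ids
    X <- g$values
  } else {
    X <- as.matrix(g)
    fam <- as.character(seq_len(nrow(X)))  # no family structure supplied
  }
  if (is.null(plan)) plan <- interfamily_splits(fam, seed = seed)
  if (length(plan$family_ids) != nrow(X))
    l1l2_stop("split plan does not match the data", "l1l2dap_structural_error")
  if (is.null(grid)) grid <- l1l2_grid(X, y)
  universe <- colnames(X)
  if (is.null(universe)) universe <- paste0("x", seq_len(ncol(X)))

  per <- vector("list", plan$n_resamplings)
  acc_stab <- vector("list", plan$n_resamplings)
  for (r in seq_len(plan$n_resamplings)) {
    sp <- plan$resamplings[[r]]
    .assert_no_leakage(sp$dev, sp$val)
    Xd <- X[sp$dev, , drop = FALSE]; yd <- y[sp$dev]
    gp <- run_internal_cv(Xd, yd, sp$folds, grid, plugin)
    sel <- select_model(gp, mse_tolerance)
    model <- plugin$fit(Xd, yd, as.list(sel))
    pred <- plugin$predict(model, X[sp$val, , drop = FALSE])
    r2 <- squared_correlation(y[sp$val], pred)
    rl <- if (is.null(plugin$ranked_list)) NULL else
      plugin$ranked_list(model, universe)
    w <- if (is.null(plugin$weights)) NULL else plugin$weights(model)
    per[[r]] <- list(selected = sel[intersect(c("mu", "tau", "lambda",
                                                "gamma", "cost", "epsilon"),
                                              names(sel))],
                     r2 = r2, ranked = rl, weights = w)
    gp$resampling <- r
    acc_stab[[r]] <- gp
  }
  r2 <- vapply(per, `[[`, numeric(1), "r2")
  structure(list(per_resampling = per, r2 = r2,
                 mean_r2 = mean(r2), range_r2 = range(r2),
                 accuracy_stability = do.call(rbind, acc_stab),
                 plan = plan, grid = grid, plugin = plugin$name,
                 mse_tolerance = mse_tolerance),
            class = "dap_result")
}

#' @export
print.dap_result <- function(x, ...) {
  cat(sprintf("DAP result (%s): %d resamplings\n", x$plugin,
              length(x$r2)))
  cat(sprintf("  validation r^2: mean %.3f (range %.3f-%.3f)\n",
              x$mean_r2, x$range_r2[1], x$range_r2[2]))
  if (isTRUE(attr(x, "selection_bias_prone")))
    cat("  NOTE: bootstrap protocol reuses selection samples in validation;\n",
        "        results are potentially over-optimistic\n")
  invisible(x)
}

#' @export
summary.dap_result <- function(object, ...) {
  sel <- do.call(rbind, lapply(object$per_resampling, function(p)
    as.data.frame(p$selected)))
  sel$r2 <- object$r2
  sel$support_size <- vapply(object$per_resampling, function(p)
    if (is.null(p$weights)) NA_integer_ else sum(p$weights != 0), integer(1))
  rownames(sel) <- NULL
  cat(sprintf("DAP (%s), %d resamplings: mean r^2 = %.3f (%.3f-%.3f)\n\n",
              object$plugin, length(object$r2), object$mean_r2,
              object$range_r2[1], object$range_r2[2]))
  print(sel, digits = 4)
  invisible(sel)
}

#' Per-resampling weight vectors of a DAP result
#'
#' @param x a `dap_result` from an [l1l2_dap()] run (or any plugin that
#'   exposes weights).
#' @return A `p x n_resamplings` numeric matrix of regression weights, the
#'   input to [find_top_ranked()].
#' @export
dap_weights <- function(x) {
  stopifnot(inherits(x, "dap_result"))
  ws <- lapply(x$per_resampling, `[[`, "weights")
  if (any(vapply(ws, is.null, logical(1))))
    l1l2_stop("this DAP run's plugin does not expose weight vectors",
              "l1l2dap_structural_error")
  do.call(cbind, ws)
}

#' Run the bootstrap baseline protocol
#'
#' The simpler protocol used for the SVR baseline: hyperparameters are
#' chosen by grid search maximizing the mean squared correlation over
#' `n_grid_bootstraps` family-respecting 50% train/test resamplings; the
#' selected parameters are then evaluated on `n_eval_bootstraps` further
#' family-respecting resamplings.  Because the evaluation resamples the
#' same pool of samples already used for selection, the resulting accuracy
#' is potentially over-optimistic; the result carries attribute
#' `selection_bias_prone = TRUE` and its print method says so.
#'
#' @param g genotype matrix (fully imputed) or numeric matrix.
#' @param y trait vector.
#' @param plugin regressor plugin, e.g. `svr_plugin("radial")`.
#' @param param_grid `data.frame` of plugin parameter columns (e.g.
#'   `gamma`, `cost`), one row per candidate.
#' @param n_grid_bootstraps resamplings used for the grid search.
#' @param n_eval_bootstraps resamplings used for evaluation.
#' @param train_fraction fraction of samples (by whole families) in each
#'   training side.
#' @param seed integer seed.
#' @return A `dap_result` (without stability columns) with attribute
#'   `selection_bias_prone`.
#' @export
bootstrap_dap <- function(g, y, plugin, param_grid,
                          n_grid_bootstraps = 10L, n_eval_bootstraps = 15L,
                          train_fraction = 0.5, seed = 1L) {
  if (inherits(g, "genotype_matrix")) {
    fam <- g$family_ids; X <- g$values
  } else {
    X <- as.matrix(g); fam <- as.character(seq_len(nrow(X)))
  }
  if (nrow(param_grid) == 0L)
    l1l2_stop("empty parameter grid", "l1l2dap_precondition_error")
  sel_plan <- interfamily_splits(fam, n_grid_bootstraps, train_fraction,
                                 k_folds = 2L, seed = seed)
  mean_r2 <- numeric(nrow(param_grid))
  for (gi in seq_len(nrow(param_grid))) {
    params <- as.list(param_grid[gi, , drop = FALSE])
    r2s <- vapply(sel_plan$resamplings, function(sp) {
      .assert_no_leakage(sp$dev, sp$val)
      model <- plugin$fit(X[sp$dev, , drop = FALSE], y[sp$dev], params)
      squared_correlation(y[sp$val],
                          plugin$predict(model, X[sp$val, , drop = FALSE]))
    }, numeric(1))
    mean_r2[gi] <- mean(r2s)
  }
  best <- param_grid[order(-mean_r2,
                           seq_len(nrow(param_grid)))[1], , drop = FALSE]

  eval_plan <- interfamily_splits(fam, n_eval_bootstraps, train_fraction,
                                  k_folds = 2L, seed = seed + 1L)
  universe <- colnames(X)
  if (is.null(universe)) universe <- paste0("x", seq_len(ncol(X)))
  per <- lapply(eval_plan$resamplings, function(sp) {
    .assert_no_leakage(sp$dev, sp$val)
    model <- plugin$fit(X[sp$dev, , drop = FALSE], y[sp$dev], as.list(best))
    pred <- plugin$predict(model, X[sp$val, , drop = FALSE])
    list(selected = as.list(best),
         r2 = squared_correlation(y[sp$val], pred),
         ranked = if (is.null(plugin$ranked_list)) NULL else
           plugin$ranked_list(model, universe),
         weights = if (is.null(plugin$weights)) NULL else
           plugin$weights(model))
  })
  r2 <- vapply(per, `[[`, numeric(1), "r2")
  out <- structure(list(per_resampling = per, r2 = r2,
                        mean_r2 = mean(r2), range_r2 = range(r2),
                        accuracy_stability = NULL,
                        plan = eval_plan, grid = param_grid,
                        plugin = plugin$name, selected = best),
                   class = "dap_result")
  attr(out, "selection_bias_prone") <- TRUE
  out
}
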