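#' Top-ranked SNPs across resamplings
#'
#' A SNP is *top-ranked* when its |weight| falls in the top
#' `percentile`-percentile of a resampling's weight distribution in at
#' least `min_runs` of the resamplings (the reference setting: top
#' 10-percentile in at least 14 of 15).  For sparse L1L2 weight vectors
#' the percentile is taken over the nonzero weights of each resampling —
#' over all `p` weights the cut would be 0 and everything would qualify;
#' for dense weight vectors (e.g. a linear SVR baseline) set
#' `over_nonzero = FALSE` to use the full distribution.
#'
#' @param weights `p x n_resamplings` numeric matrix of regression weights
#'   with SNP names as row names (see [dap_weights()]).
#' @param percentile top percentile defining qualification, in (0, 100).
#' @param min_runs minimum number of qualifying resamplings.
#' @param over_nonzero take the percentile over nonzero |weights| only.
#' @return A `data.frame` of class `top_ranked_set`: `name`, `n_runs`
#'   (qualifying resamplings) and `mean_abs_weight`, ordered by decreasing
#'   `n_runs` then mean weight.
#' @export
find_top_ranked <- function(weights, percentile = 10, min_runs = 14L,
                            over_nonzero = TRUE) {
  weights <- as.matrix(weights)
  stopifnot(percentile > 0, percentile < 100)
  R <- ncol(weights)
  if (min_runs > R)
    l1l2_stop("min_runs exceeds the number of resamplings",
              "l1l2dap_precondition_error")
  if (is.null(rownames(weights)))
    rownames(weights) <- paste0("x", seq_len(nrow(weights)))
  aw <- abs(weights)
  qualifies <- matrix(FALSE, nrow(aw), R)
  for (r in seq_len(R)) {
    pool <- if (over_nonzero) aw[aw[, r] > 0, r] else aw[, r]
    if (length(pool) == 0L) next
    cut <- quantile(pool, 1 - percentile / 100, names = FALSE)
    qualifies[, r] <- aw[, r] >= cut & (if (over_nonzero) aw[, r] > 0 else TRUE)
  }
  n_runs <- rowSums(qualifies)
  keep <- which(n_runs >= min_runs)
  out <- data.frame(name = rownames(aw)[keep],
                    n_runs = n_runs[keep],
                    mean_abs_weight = rowMeans(aw)[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_runs, -out$mean_abs_weight, out$name), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("top_ranked_set", "data.frame")
  out
}

#' Top-correlated SNPs of each top-ranked SNP
#'
#' The saturation step: for every top-ranked SNP, find all other SNPs
#' whose genotype profile across the population has |Pearson correlation|
#' at or above `threshold` — markers in linkage disequilibrium that sparse
#' selection may have discarded.  Each hit records its correlation, the
#' base-pair distance to the top-ranked SNP when they share a chromosome
#' (`NA` otherwise) and, when `weights` is supplied, its own regression
#' weight (0 meaning it was eliminated by the sparse model).
#'
#' @param g a fully imputed [genotype_matrix()].
#' @param top a [find_top_ranked()] set (or character vector of SNP names).
#' @param threshold correlation threshold in (0, 1].
#' @param weights optional named weight vector (e.g. row means of
#'   [dap_weights()]) used to annotate the hits.
#' @return An object of class `saturation_result`: a `data.frame` with
#'   columns `top_snp`, `snp`, `correlation`, `same_chromosome`,
#'   `distance_bp`, `weight`, plus attribute `threshold`.
#' @export
find_top_correlated <- function(g, top, threshold = 0.8, weights = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  stopifnot(threshold > 0, threshold <= 1)
  if (any(g$missing_mask))
    l1l2_stop("genotype matrix has missing calls; run impute_genotypes()",
              "l1l2dap_data_error")
  top_names <- if (is.data.frame(top)) top$name else as.character(top)
  snps <- g$snps
  vars <- apply(g$values, 2, var)
  usable <- vars > 0
  if (any(!usable))
    warning(sprintf("%d zero-variance SNP column(s) skipped (correlation undefined)",
                    sum(!usable)), call. = FALSE)
  rows <- list()
  for (t in top_names) {
    ti <- match(t, snps$name)
    if (is.na(ti) || !usable[ti]) next
    cc <- suppressWarnings(
      as.numeric(cor(g$values[, ti], g$values[, usable, drop = FALSE])))
    names(cc) <- snps$name[usable]
    cc <- cc[names(cc) != t]
    hits <- names(cc)[abs(cc) >= threshold]
    if (!length(hits)) next
    hi <- match(hits, snps$name)
    same <- snps$chromosome[hi] == snps$chromosome[ti]
    dist <- ifelse(same, abs(snps$position_bp[hi] - snps$position_bp[ti]),
                   NA_real_)
    rows[[t]] <- data.frame(top_snp = t, snp = hits,
                            correlation = unname(cc[hits]),
                            same_chromosome = same,
                            distance_bp = dist,
                            weight = if (is.null(weights)) NA_real_ else
                              ifelse(is.na(weights[hits]), 0,
                                     weights[hits]),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(top_snp = character(), snp = character(),
               correlation = numeric(), same_chromosome = logical(),
               distance_bp = numeric(), weight = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("saturation_result", "data.frame")
  out
}

#' Summaries of a saturation result
#'
#' Per top-ranked SNP: the count of top-correlated SNPs and the mean, min
#' and max base-pair distance over the same-chromosome hits
#' (cross-chromosome hits count towards `n` but have no distance).
#' `min_correlated` reproduces the reporting rule of keeping only
#' top-ranked SNPs with at least that many top-correlated SNPs.
#'
#' @param r a [find_top_correlated()] result.
#' @param min_correlated minimum `n` for a top-ranked SNP to be reported.
#' @return `data.frame` with columns `top_snp`, `n`, `mean_distance_bp`,
#'   `min_distance_bp`, `max_distance_bp`, ordered by decreasing `n`.
#' @export
distance_summary <- function(r, min_correlated = 0L) {
  if (nrow(r) == 0L)
    return(data.frame(top_snp = character(), n = integer(),
                      mean_distance_bp = numeric(),
                      min_distance_bp = numeric(),
                      max_distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  parts <- split(r, r$top_snp)
  out <- do.call(rbind, lapply(parts, function(d) {
    dd <- d$distance_bp[d$same_chromosome]
    data.frame(top_snp = d$top_snp[1], n = nrow(d),
               mean_distance_bp = if (length(dd)) mean(dd) else NA_real_,
               min_distance_bp = if (length(dd)) min(dd) else NA_real_,
               max_distance_bp = if (length(dd)) max(dd) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n >= min_correlated, , drop = FALSE]
  out <- out[order(-out$n, out$top_snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled saturation sweep over correlation thresholds
#'
#' Runs [find_top_correlated()] at each threshold and pools the
#' same-chromosome distances and the weights of the hits across all
#' top-ranked SNPs — the data behind distance/weight distribution plots.
#' As the threshold rises, hits are lost but never gained, and the pooled
#' median distance typically shrinks: strongly correlated SNPs sit closer
#' on the chromosome.
#'
#' @inheritParams find_top_correlated
#' @param thresholds vector of correlation thresholds to sweep.
#' @return A list with `results` (one `saturation_result` per threshold)
#'   and `pooled`, a `data.frame` of `threshold`, `n`,
#'   `median_distance_bp` and `median_abs_weight`.
#' @export
saturation_sweep <- function(g, top, thresholds = c(0.6, 0.7, 0.8, 0.9),
                             weights = NULL) {
  results <- lapply(thresholds, function(th)
    find_top_correlated(g, top, th, weights))
  names(results) <- as.character(thresholds)
  pooled <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    r <- results[[i]]
    dd <- r$distance_bp[r$same_chromosome]
    data.frame(threshold = thresholds[i], n = nrow(r),
               median_distance_bp = if (length(dd)) median(dd) else NA_real_,
               median_abs_weight = if (all(is.na(r$weight))) NA_real_ else
                 median(abs(r$weight), na.rm = TRUE))
  }))
  list(results = results, pooled = pooled)
}

#' Write top-ranked and top-correlated SNP positions as BED
#'
#' Genome-track export of the saturated marker panel (top-ranked SNPs plus
#' their top-correlated SNPs), one zero-length feature per SNP with the
#' set membership in the name column.
#'
#' @param g the [genotype_matrix()] providing the SNP map.
#' @param top a [find_top_ranked()] set.
#' @param r a [find_top_correlated()] result.
#' @param path output BED path.
#' @return Invisibly, `path`.
#' @export
write_saturation_bed <- function(g, top, r, path) {
  top_names <- if (is.data.frame(top)) top$name else as.character(top)
  nm <- unique(c(top_names, r$snp))
  idx <- match(nm, g$snps$name)
  kind <- ifelse(nm %in% top_names, "top_ranked", "top_correlated")
  bed <- data.frame(chrom = g$snps$chromosome[idx],
                    start = g$snps$position_bp[idx] - 1L,
                    end = g$snps$position_bp[idx],
                    name = paste(nm, kind, sep = "|"))
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  write.table(bed, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
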