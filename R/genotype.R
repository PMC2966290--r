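#' SNP map records
#'
#' Constructs the per-SNP metadata table carried by a [genotype_matrix()]:
#' SNP name, chromosome label and base-pair position.  Chromosome labels are
#' treated as opaque strings (no numeric ordering is assumed) and positions
#' are 1-based base pairs, as in PLINK `.map` files.
#'
#' @param name character vector of unique SNP identifiers.
#' @param chromosome character vector of chromosome labels, recycled if scalar.
#' @param position_bp non-negative integer base-pair positions.
#' @return A `data.frame` with columns `name`, `chromosome`, `position_bp`.
#' @export
snp_records <- function(name, chromosome, position_bp) {
  name <- as.character(name)
  if (anyDuplicated(name))
    l1l2_stop("SNP names must be unique", "l1l2dap_data_error")
  position_bp <- as.numeric(position_bp)
  if (any(!is.finite(position_bp)) || any(position_bp < 0))
    l1l2_stop("SNP positions must be non-negative base pairs", "l1l2dap_data_error")
  data.frame(name = name,
             chromosome = rep_len(as.character(chromosome), length(name)),
             position_bp = position_bp,
             stringsAsFactors = FALSE)
}

#' Genotype matrix container
#'
#' A samples-by-SNPs numeric genotype matrix with per-SNP map metadata, a
#' missing-call mask, per-sample family labels and an encoding tag.  Under
#' the additive encoding every non-missing value is the count (0, 1 or 2) of
#' non-reference alleles, the reference allele being the major allele.
#'
#' @param values numeric matrix, `n_samples x n_snps`; entries at masked
#'   positions may be `NA`.
#' @param snps SNP metadata as returned by [snp_records()]; one row per
#'   column of `values`.
#' @param sample_ids character vector of sample identifiers (row names).
#' @param family_ids character vector of family labels, one per sample.
#' @param missing_mask logical matrix the same shape as `values`; defaults
#'   to `is.na(values)`.
#' @param encoding one of `"additive_012"`, `"centered_101"`,
#'   `"onehot_3col"`, `"class_frequency"`.
#' @return An object of class `genotype_matrix`.
#' @seealso [encode_genotypes()], [impute_genotypes()], [missingness()]
#' @export
genotype_matrix <- function(values, snps, sample_ids, family_ids,
                            missing_mask = is.na(values),
                            encoding = "additive_012") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  encoding <- match.arg(encoding,
                        c("additive_012", "centered_101", "onehot_3col",
                          "class_frequency"))
  if (nrow(snps) != ncol(values))
    l1l2_stop("SNP metadata rows must match genotype columns",
              "l1l2dap_structural_error")
  if (length(sample_ids) != nrow(values))
    l1l2_stop("sample_ids length must match genotype rows",
              "l1l2dap_structural_error")
  if (length(family_ids) != nrow(values))
    l1l2_stop("every sample needs a family_id", "l1l2dap_structural_error")
  if (!identical(dim(missing_mask), dim(values)))
    l1l2_stop("missing_mask shape must match values", "l1l2dap_structural_error")
  if (encoding == "additive_012") {
    obs <- values[!missing_mask]
    if (length(obs) && !all(obs %in% c(0, 1, 2)))
      l1l2_stop("additive encoding requires non-missing values in {0,1,2}",
                "l1l2dap_data_error")
  }
  dimnames(values) <- list(as.character(sample_ids), snps$name)
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values,
                 missing_mask = missing_mask,
                 snps = snps,
                 sample_ids = as.character(sample_ids),
                 family_ids = as.character(family_ids),
                 encoding = encoding),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%s encoding)\n",
              nrow(x$values), ncol(x$values), x$encoding))
  cat(sprintf("  families: %d, missing calls: %.3f%%\n",
              length(unique(x$family_ids)),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (integer, logical or sample-id character).
#' @param j SNP index (integer, logical or SNP-name character).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$snps$name)
  genotype_matrix(x$values[i, j, drop = FALSE],
                  x$snps[j, , drop = FALSE],
                  x$sample_ids[i], x$family_ids[i],
                  x$missing_mask[i, j, drop = FALSE],
                  x$encoding)
}

# split "A/G"-style calls into a 2-column allele matrix; NA stays NA
.split_calls <- function(calls) {
  a1 <- sub("/.*$", "", calls)
  a2 <- sub("^.*/", "", calls)
  a1[is.na(calls)] <- NA_character_
  a2[is.na(calls)] <- NA_character_
  list(a1 = a1, a2 = a2)
}

#' Encode raw genotype calls numerically
#'
#' Converts a matrix of raw genotype calls (strings like `"A/G"`, `NA` for
#' uncalled) into one of four numeric encodings.  The additive code counts
#' copies of the non-reference allele — the number of allelic deviations
#' from the major homozygote — so the homozygote for the major allele maps
#' to 0, the heterozygote to 1 and the minor homozygote to 2.
#'
#' * `additive_012`: count of non-reference alleles in \{0, 1, 2\}.
#' * `centered_101`: additive code shifted to \{-1, 0, 1\}.
#' * `onehot_3col`: one indicator column per genotype class
#'   (major homozygote, heterozygote, minor homozygote), tripling the
#'   column count.
#' * `class_frequency`: each call is replaced by the observed relative
#'   frequency of its genotype class at that locus.
#'
#' @param calls character matrix (`n_samples x n_snps`) of `"X/Y"` calls with
#'   `NA` for missing; column names are taken as SNP names when `snps` is
#'   not supplied.
#' @param scheme encoding name (see above).
#' @param snps optional [snp_records()] table; a placeholder map is built
#'   when absent.
#' @param sample_ids,family_ids optional identifiers; defaults are generated.
#' @return A [genotype_matrix()] in the requested encoding.
#' @examples
#' calls <- matrix(c("A/A", "A/G", "G/G"), ncol = 1,
#'                 dimnames = list(NULL, "snp1"))
#' encode_genotypes(calls, "additive_012")$values
#' @export
encode_genotypes <- function(calls, scheme = "additive_012", snps = NULL,
                             sample_ids = NULL, family_ids = NULL) {
  scheme <- match.arg(scheme, c("additive_012", "centered_101",
                                "onehot_3col", "class_frequency"))
  calls <- as.matrix(calls)
  n <- nrow(calls); p <- ncol(calls)
  if (is.null(snps)) {
    nm <- colnames(calls)
    if (is.null(nm)) nm <- paste0("snp", seq_len(p))
    snps <- snp_records(nm, "0", rep(0, p))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(family_ids)) family_ids <- sample_ids

  al <- .split_calls(calls)
  additive <- matrix(NA_real_, n, p)
  class_of <- matrix(NA_integer_, n, p)  # 0 = hom-ref, 1 = het, 2 = hom-alt
  for (j in seq_len(p)) {
    a1 <- al$a1[, j]; a2 <- al$a2[, j]
    ok <- !is.na(a1) & !is.na(a2)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) > 2)
      l1l2_stop(sprintf("SNP %s has more than 2 alleles (>3 genotype classes)",
                        snps$name[j]), "l1l2dap_data_error")
    if (length(alleles) == 0) next
    counts <- table(factor(c(a1[ok], a2[ok]), levels = alleles))
    # reference = major allele; lexicographic tie-break for determinism
    ref <- alleles[which.max(counts)]
    cls <- (a1 != ref) + (a2 != ref)
    additive[ok, j] <- cls[ok]
    class_of[ok, j] <- cls[ok]
  }
  mask <- is.na(additive)

  if (scheme %in% c("additive_012", "centered_101")) {
    vals <- if (scheme == "centered_101") additive - 1 else additive
    g <- genotype_matrix(vals, snps, sample_ids, family_ids, mask, scheme)
    return(g)
  }
  if (scheme == "class_frequency") {
    vals <- matrix(NA_real_, n, p)
    for (j in seq_len(p)) {
      cl <- class_of[, j]
      ok <- !is.na(cl)
      if (!any(ok)) next
      freq <- tabulate(cl[ok] + 1L, nbins = 3L) / sum(ok)
      vals[ok, j] <- freq[cl[ok] + 1L]
    }
    return(genotype_matrix(vals, snps, sample_ids, family_ids, mask,
                           "class_frequency"))
  }
  # onehot_3col: indicator triple per SNP
  vals <- matrix(NA_real_, n, 3L * p)
  suffix <- c("homref", "het", "homalt")
  snps3 <- snps[rep(seq_len(p), each = 3L), , drop = FALSE]
  snps3$name <- paste(snps3$name, rep(suffix, p), sep = "_")
  rownames(snps3) <- NULL
  for (j in seq_len(p)) {
    cl <- class_of[, j]
    for (k in 0:2) vals[, 3L * (j - 1L) + k + 1L] <- as.numeric(cl == k)
  }
  genotype_matrix(vals, snps3, sample_ids, family_ids, is.na(vals),
                  "onehot_3col")
}

#' Impute missing genotype calls by genotype-class frequency
#'
#' Every masked entry is replaced by a draw from \{0, 1, 2\} with
#' probabilities equal to the observed relative frequencies of the genotype
#' classes at that locus, so imputation preserves each locus's marginal
#' genotype distribution (and hence its allele frequency).  A single stream
#' seeded by `seed` is consumed in column-major SNP order; the result is
#' fully reproducible and non-missing entries are never altered.
#'
#' @param g a [genotype_matrix()] in additive encoding.
#' @param seed integer seed for the imputation stream.
#' @return The genotype matrix with all missing calls filled and the mask
#'   cleared.
#' @export
impute_genotypes <- function(g, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$encoding != "additive_012")
    l1l2_stop("imputation requires the additive {0,1,2} encoding",
              "l1l2dap_data_error")
  vals <- g$values
  mask <- g$missing_mask
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing))
    l1l2_stop(sprintf("SNP(s) with 100%% missing calls: %s",
                      paste(g$snps$name[all_missing], collapse = ", ")),
              "l1l2dap_data_error")
  with_preserved_rng({
    set.seed(seed)
    for (j in which(colSums(mask) > 0L)) {
      obs <- vals[!mask[, j], j]
      freq <- tabulate(obs + 1L, nbins = 3L) / length(obs)
      vals[mask[, j], j] <- sample(0:2, sum(mask[, j]), replace = TRUE,
                                   prob = freq)
    }
  })
  genotype_matrix(vals, g$snps, g$sample_ids, g$family_ids,
                  matrix(FALSE, nrow(vals), ncol(vals)), g$encoding)
}

# run expr under a locally-set RNG without disturbing the caller's stream
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Missing-call diagnostics
#'
#' @param g a [genotype_matrix()].
#' @param thresholds per-SNP missing-fraction thresholds at which to count
#'   SNPs exceeding each value.
#' @return A list with `overall` (fraction of masked entries), `per_snp`
#'   (named fraction vector) and `n_exceeding` (named counts of SNPs whose
#'   missing fraction strictly exceeds each threshold).
#' @export
missingness <- function(g, thresholds = c(0.01, 0.02, 0.05)) {
  stopifnot(inherits(g, "genotype_matrix"))
  per_snp <- colMeans(g$missing_mask)
  names(per_snp) <- g$snps$name
  n_exceeding <- vapply(thresholds, function(t) sum(per_snp > t), integer(1))
  names(n_exceeding) <- paste0(">", thresholds)
  list(overall = mean(g$missing_mask), per_snp = per_snp,
       n_exceeding = n_exceeding)
}
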