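#' Read a PLINK-style text genotype file pair
#'
#' Parses a whitespace-delimited `.ped` file (family, individual, father,
#' mother, sex, phenotype, then two allele tokens per SNP) together with its
#' `.map` file (chromosome, SNP name, genetic distance, base-pair position)
#' and returns the genotypes in additive encoding.  The allele code `"0"`
#' marks a missing call: a genotype with either allele missing is masked.
#' The reference allele at each locus is the major allele observed in the
#' file.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return A [genotype_matrix()] in additive encoding.  The `.ped`
#'   phenotype column is attached as attribute `"ped_phenotype"`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path) || !file.exists(map_path))
    l1l2_stop("ped/map file not found", "l1l2dap_structural_error")
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chromosome", "name", "cm", "position_bp"))
  snps <- snp_records(map$name, map$chromosome, map$position_bp)
  p <- nrow(snps)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  calls <- matrix(NA_character_, n, p)
  fam <- ind <- character(n)
  phen <- numeric(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * p)
      l1l2_stop(sprintf(
        "ped line %d: expected %d fields for %d SNPs, found %d",
        i, 6L + 2L * p, p, length(tok)), "l1l2dap_parse_error")
    fam[i] <- tok[1]; ind[i] <- tok[2]
    phen[i] <- suppressWarnings(as.numeric(tok[6]))
    a1 <- tok[seq(7L, by = 2L, length.out = p)]
    a2 <- tok[seq(8L, by = 2L, length.out = p)]
    g <- paste(a1, a2, sep = "/")
    g[a1 == "0" | a2 == "0"] <- NA_character_
    calls[i, ] <- g
  }
  if (anyDuplicated(ind)) ind <- paste(fam, ind, sep = ":")
  g <- encode_genotypes(calls, "additive_012", snps = snps,
                        sample_ids = ind, family_ids = fam)
  attr(g, "ped_phenotype") <- phen
  g
}

#' Write a genotype matrix as a PLINK-style text file pair
#'
#' Inverse of [read_plink_text()] for additively encoded data: code 0 is
#' written as `A/A`, 1 as `A/B`, 2 as `B/B`, and masked calls as `0 0`.
#'
#' @param g a [genotype_matrix()] in additive encoding.
#' @param ped_path,map_path output paths.
#' @param phenotype optional numeric vector for the `.ped` phenotype column
#'   (defaults to -9, the PLINK missing code).
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(g, ped_path, map_path, phenotype = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$encoding != "additive_012")
    l1l2_stop("ped output requires additive encoding", "l1l2dap_data_error")
  write.table(data.frame(g$snps$chromosome, g$snps$name, 0,
                         g$snps$position_bp),
              map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n <- nrow(g$values); p <- ncol(g$values)
  if (is.null(phenotype)) phenotype <- rep(-9, n)
  code_a1 <- c("A", "A", "B"); code_a2 <- c("A", "B", "B")
  rows <- character(n)
  for (i in seq_len(n)) {
    v <- g$values[i, ]
    a1 <- code_a1[v + 1L]; a2 <- code_a2[v + 1L]
    a1[g$missing_mask[i, ]] <- "0"; a2[g$missing_mask[i, ]] <- "0"
    geno <- as.vector(rbind(a1, a2))
    rows[i] <- paste(c(g$family_ids[i], g$sample_ids[i], "0", "0", "0",
                       format(phenotype[i], trim = TRUE), geno),
                     collapse = " ")
  }
  writeLines(rows, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read pre-encoded genotypes from TSV
#'
#' Reads the tab-separated dialect: a header row of SNP names, then one row
#' per sample with `sample_id`, `family_id` and additive codes in
#' \{0, 1, 2, NA\}.
#'
#' @param path TSV path.
#' @param snps optional [snp_records()] map; a placeholder is built when
#'   absent.
#' @return A [genotype_matrix()] in additive encoding.
#' @export
read_genotype_tsv <- function(path, snps = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (ncol(d) < 3L)
    l1l2_stop("genotype TSV needs sample_id, family_id and >=1 SNP column",
              "l1l2dap_parse_error")
  vals <- as.matrix(d[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  if (is.null(snps))
    snps <- snp_records(colnames(d)[-(1:2)], "0",
                        rep(0, ncol(d) - 2L))
  genotype_matrix(vals, snps, d[[1]], d[[2]])
}

#' Write pre-encoded genotypes to TSV
#' @param g a [genotype_matrix()]; masked entries are written as `NA`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_tsv <- function(g, path) {
  vals <- g$values
  vals[g$missing_mask] <- NA
  d <- data.frame(sample_id = g$sample_ids, family_id = g$family_ids,
                  vals, check.names = FALSE)
  write.table(d, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with header: `sample_id`, `family_id`, then one column per
#' real-valued trait.
#'
#' @param path TSV path.
#' @return A `data.frame` with character ids and numeric trait columns.
#' @export
read_phenotype_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 3L)
    l1l2_stop("phenotype TSV needs sample_id, family_id and >=1 trait",
              "l1l2dap_parse_error")
  for (j in 3:ncol(d)) d[[j]] <- as.numeric(d[[j]])
  d
}

#' Align a phenotype column to a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param pheno a phenotype `data.frame` from [read_phenotype_tsv()].
#' @param trait trait column name.
#' @return Numeric vector ordered like `g$sample_ids`.
#' @export
align_phenotype <- function(g, pheno, trait) {
  idx <- match(g$sample_ids, pheno$sample_id)
  if (anyNA(idx))
    l1l2_stop("phenotype table is missing some genotyped samples",
              "l1l2dap_structural_error")
  y <- pheno[[trait]][idx]
  if (any(!is.finite(y)))
    l1l2_stop("phenotype values must be finite", "l1l2dap_data_error")
  y
}

#' Write / read a ranked marker list as TSV (rank, feature, weight)
#' @param rl a [ranked_list()].
#' @param path output path.
#' @param weights optional numeric weights aligned with `rl$items`.
#' @return Invisibly, `path`.
#' @export
write_ranked_list <- function(rl, path, weights = NULL) {
  k <- length(rl$items)
  d <- data.frame(rank = seq_len(k), feature = rl$items,
                  weight = if (is.null(weights)) rep(NA_real_, k) else weights)
  write.table(d, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @param universe feature universe for the list read back.
#' @export
read_ranked_list <- function(path, universe) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ranked_list(d$feature[order(d$rank)], universe)
}

#' Serialize / deserialize a fitted L1L2 model as versioned JSON
#'
#' Stores the hyperparameters, the selected support (as SNP names), the
#' debiased weights, the intercept and the training standardization
#' statistics, so a model can be re-applied to new encoded genotypes.
#'
#' @param m an object of class `l1l2`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_l1l2_json <- function(m, path) {
  stopifnot(inherits(m, "l1l2"))
  obj <- list(format = "l1l2dap-model", version = 1L,
              hyperparams = list(mu = m$mu, tau = m$tau, lambda = m$lambda),
              feature_names = m$feature_names,
              support = m$feature_names[m$support],
              weights = unname(m$weights[m$support]),
              intercept = m$intercept,
              center = unname(m$center), scale = unname(m$scale),
              y_mean = m$y_mean)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_l1l2_json
#' @export
read_l1l2_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "l1l2dap-model"))
    l1l2_stop("not an l1l2dap model file", "l1l2dap_parse_error")
  p <- length(obj$feature_names)
  w <- numeric(p)
  support <- match(obj$support, obj$feature_names)
  w[support] <- obj$weights
  structure(list(mu = obj$hyperparams$mu, tau = obj$hyperparams$tau,
                 lambda = obj$hyperparams$lambda,
                 weights = stats::setNames(w, obj$feature_names),
                 naive_weights = NULL,
                 support = support,
                 intercept = obj$intercept,
                 center = stats::setNames(obj$center, obj$feature_names),
                 scale = stats::setNames(obj$scale, obj$feature_names),
                 y_mean = obj$y_mean,
                 feature_names = obj$feature_names,
                 iterations = NA_integer_, converged = NA),
            class = "l1l2")
}
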