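#' Specification of a synthetic family cohort
#'
#' Parameters of the cohort simulator, which emulates the statistical
#' structure of a heterogeneous-stock style mapping population: samples
#' grouped in multi-member families (so family-respecting splits matter),
#' SNPs clustered in linkage-disequilibrium blocks along chromosomes, a
#' sparse additive genetic architecture with controlled heritability, and
#' a small uniform missing-call rate.
#'
#' @param n_families number of families.
#' @param samples_per_family integer, or length-2 range to draw each
#'   family's size from uniformly.
#' @param n_snps total number of SNPs, spread evenly over chromosomes.
#' @param n_chromosomes number of chromosomes (opaque labels `"1"`, ...).
#' @param snp_spacing_bp base-pair spacing between adjacent SNPs.
#' @param ld_block_size SNPs per LD block (blocks never span chromosomes).
#' @param within_block_flip_prob per-SNP probability that a block member
#'   disagrees with its block's seed variant on a haplotype; 0 gives
#'   perfect within-block correlation, 0.5 destroys it.
#' @param ld_decay `"constant"`: every member is an independent noisy copy
#'   of the block seed, so within-block correlation is flat; `"markov"`:
#'   flips accumulate member to member, so correlation with the seed
#'   decays geometrically with within-block distance (as physical LD decays
#'   along a chromosome).
#' @param maf_range range of minor-allele frequencies for block seed
#'   variants, within (0, 0.5].
#' @param n_causal number of causal SNPs, one per distinct block.
#' @param effect_sizes causal effect magnitudes: `"geometric"` (default)
#'   for a heavy-tailed QTL-like profile with magnitudes
#'   `effect_decay^(0:(n_causal-1))` — a few major loci plus a polygenic
#'   tail, as seen in mapping populations — or a numeric vector of
#'   magnitudes (recycled to `n_causal`).  Signs are random either way.
#' @param effect_decay geometric decay ratio in (0, 1\] used when
#'   `effect_sizes = "geometric"`.
#' @param heritability h-squared, the fraction of phenotypic variance
#'   explained by the additive genetic component, strictly in (0, 1).
#' @param missing_rate probability that any single call is masked.
#' @param seed integer seed; the cohort is a pure function of the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_families = 100L, samples_per_family = 6L,
                        n_snps = 2000L, n_chromosomes = 20L,
                        snp_spacing_bp = 50000L, ld_block_size = 10L,
                        within_block_flip_prob = 0.05,
                        ld_decay = c("constant", "markov"),
                        maf_range = c(0.1, 0.5), n_causal = 20L,
                        effect_sizes = "geometric", effect_decay = 0.8,
                        heritability = 0.3, missing_rate = 0.0014,
                        seed = 1L) {
  spec <- list(n_families = as.integer(n_families),
               samples_per_family = as.integer(samples_per_family),
               n_snps = as.integer(n_snps),
               n_chromosomes = as.integer(n_chromosomes),
               snp_spacing_bp = as.integer(snp_spacing_bp),
               ld_block_size = as.integer(ld_block_size),
               within_block_flip_prob = within_block_flip_prob,
               ld_decay = match.arg(ld_decay, c("constant", "markov")),
               maf_range = maf_range, n_causal = as.integer(n_causal),
               effect_sizes = effect_sizes, effect_decay = effect_decay,
               heritability = heritability, missing_rate = missing_rate,
               seed = as.integer(seed))
  if (spec$n_causal > spec$n_snps)
    l1l2_stop("n_causal exceeds n_snps", "l1l2dap_spec_error")
  if (spec$heritability <= 0 || spec$heritability >= 1)
    l1l2_stop("heritability must be strictly inside (0, 1)",
              "l1l2dap_spec_error")
  if (spec$within_block_flip_prob < 0 || spec$within_block_flip_prob > 0.5)
    l1l2_stop("within_block_flip_prob must be in [0, 0.5]",
              "l1l2dap_spec_error")
  if (min(spec$maf_range) <= 0 || max(spec$maf_range) > 0.5)
    l1l2_stop("maf_range must lie within (0, 0.5]", "l1l2dap_spec_error")
  if (is.character(spec$effect_sizes)) {
    if (!identical(spec$effect_sizes, "geometric"))
      l1l2_stop("effect_sizes must be \"geometric\" or a numeric vector",
                "l1l2dap_spec_error")
    if (spec$effect_decay <= 0 || spec$effect_decay > 1)
      l1l2_stop("effect_decay must be in (0, 1]", "l1l2dap_spec_error")
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a family-structured SNP cohort with LD blocks
#'
#' Generates genotypes by a two-founder family model: each family draws
#' four founder haplotypes; every haplotype realizes each LD block by
#' drawing one seed variant at the block's minor-allele frequency and
#' copying it across the block with a per-SNP flip probability; offspring
#' receive one unrecombined haplotype from each founder (Mendelian
#' transmission), so relatives share long genotype stretches.  The trait
#' is `y = X beta + eps` with `beta` nonzero on the seed SNP of one block
#' per causal locus (random sign, magnitudes from the spec's effect-size
#' profile) and the noise
#' variance set so the genetic variance fraction matches the requested
#' heritability.  Calls are masked uniformly at `missing_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `genotypes` (a [genotype_matrix()] with missing
#'   calls masked), `phenotype` (numeric vector) and `true_model`, a list
#'   of class `true_model` with `causal_index`, `beta` (length-p, zero off
#'   the causal SNPs), `realized_heritability`, `block_of` (block id per
#'   SNP) and `causal_blocks`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_families = 20, n_snps = 100,
#'                                       n_causal = 3, seed = 42))
#' cohort$genotypes
#' cohort$true_model$realized_heritability
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    p <- spec$n_snps
    # chromosome layout and block structure
    chrom <- rep(seq_len(spec$n_chromosomes), length.out = p)
    chrom <- sort(chrom)
    pos <- integer(p)
    block_of <- integer(p)
    nb <- 0L
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- seq_along(idx) * spec$snp_spacing_bp
      bl <- (seq_along(idx) - 1L) %/% spec$ld_block_size
      block_of[idx] <- nb + bl + 1L
      nb <- nb + max(bl) + 1L
    }
    snps <- snp_records(sprintf("snp%04d", seq_len(p)),
                        as.character(chrom), pos)
    maf_block <- runif(nb, spec$maf_range[1], spec$maf_range[2])

    # family sizes and sample bookkeeping
    fam_sizes <- if (length(spec$samples_per_family) == 2L)
      sample(spec$samples_per_family[1]:spec$samples_per_family[2],
             spec$n_families, replace = TRUE)
    else rep(spec$samples_per_family, spec$n_families)
    n <- sum(fam_sizes)
    family_ids <- rep(sprintf("fam%03d", seq_len(spec$n_families)),
                      fam_sizes)
    sample_ids <- sprintf("%s_i%d", family_ids,
                          unlist(lapply(fam_sizes, seq_len)))

    # the first SNP of each block carries the seed variant itself; the
    # remaining members are noisy copies (per-SNP flips)
    is_seed <- !duplicated(block_of)
    draw_haplotype <- function() {
      seed_bits <- rbinom(nb, 1L, maf_block)
      h <- seed_bits[block_of]
      flips <- rbinom(p, 1L, spec$within_block_flip_prob)
      flips[is_seed] <- 0L
      if (spec$ld_decay == "markov") {
        # accumulate flips along the block: correlation with the seed
        # decays geometrically with member distance
        flips <- as.integer(unlist(lapply(
          split(flips, block_of), function(f) cumsum(f) %% 2L),
          use.names = FALSE))
      }
      as.integer(xor(h, flips))
    }
    X <- matrix(0, n, p)
    row <- 0L
    for (f in seq_len(spec$n_families)) {
      founders <- list(A = list(draw_haplotype(), draw_haplotype()),
                       B = list(draw_haplotype(), draw_haplotype()))
      for (k in seq_len(fam_sizes[f])) {
        row <- row + 1L
        hp <- founders$A[[sample.int(2L, 1L)]]
        hm <- founders$B[[sample.int(2L, 1L)]]
        X[row, ] <- hp + hm
      }
    }

    # sparse additive trait: one causal SNP per chosen block
    causal_blocks <- sort(sample.int(nb, spec$n_causal))
    # the causal SNP of a block is its seed member, so every other member
    # is a direct noisy copy of the causal variant
    causal_index <- vapply(causal_blocks, function(b)
      which(block_of == b & is_seed), integer(1))
    mags <- if (is.character(spec$effect_sizes))
      spec$effect_decay^(seq_len(spec$n_causal) - 1L)
    else rep_len(abs(spec$effect_sizes), spec$n_causal)
    beta <- numeric(p)
    beta[causal_index] <- sample(c(-1, 1), spec$n_causal, replace = TRUE) *
      mags
    genetic <- as.numeric(X %*% beta)
    vg <- var(genetic)
    eps <- rnorm(n, sd = sqrt(vg * (1 - spec$heritability) /
                                spec$heritability))
    y <- genetic + eps
    realized_h2 <- vg / var(y)

    mask <- matrix(rbinom(n * p, 1L, spec$missing_rate) == 1L, n, p)
    vals <- X
    vals[mask] <- NA_real_
    g <- genotype_matrix(vals, snps, sample_ids, family_ids, mask)
    true_model <- structure(list(causal_index = causal_index,
                                 beta = stats::setNames(beta, snps$name),
                                 realized_heritability = realized_h2,
                                 block_of = block_of,
                                 causal_blocks = causal_blocks,
                                 spec = spec),
                            class = "true_model")
    list(genotypes = g, phenotype = y, true_model = true_model)
  })
}

#' Realized linkage disequilibrium of a simulated cohort
#'
#' Diagnostic for the simulator's LD structure: the mean absolute pairwise
#' genotype correlation within each LD block, its decay with within-block
#' index distance, and a cross-block baseline from random SNP pairs on
#' different blocks.
#'
#' @param g the cohort's [genotype_matrix()].
#' @param true_model the cohort's `true_model` (provides block ids).
#' @param n_cross number of random cross-block pairs for the baseline.
#' @return A list with `within_block` (per-block mean |cor|),
#'   `mean_within`, `mean_cross` and `decay` (`data.frame` of mean |cor|
#'   by within-block index offset).
#' @export
realized_ld <- function(g, true_model, n_cross = 500L) {
  stopifnot(inherits(g, "genotype_matrix"))
  block_of <- true_model$block_of
  V <- g$values
  V[g$missing_mask] <- NA
  abs_cor <- function(i, j) {
    r <- suppressWarnings(cor(V[, i], V[, j],
                              use = "pairwise.complete.obs"))
    abs(r)
  }
  offsets <- list()
  within <- vapply(unique(block_of), function(b) {
    idx <- which(block_of == b)
    if (length(idx) < 2L) return(NA_real_)
    pr <- combn(idx, 2L)
    cc <- vapply(seq_len(ncol(pr)), function(k)
      abs_cor(pr[1, k], pr[2, k]), numeric(1))
    off <- pr[2, ] - pr[1, ]
    for (o in unique(off))
      offsets[[as.character(o)]] <<- c(offsets[[as.character(o)]],
                                       cc[off == o])
    mean(cc, na.rm = TRUE)
  }, numeric(1))
  cross <- with_preserved_rng({
    set.seed(true_model$spec$seed + 1L)
    mean(vapply(seq_len(n_cross), function(k) {
      repeat {
        ij <- sample.int(ncol(V), 2L)
        if (block_of[ij[1]] != block_of[ij[2]]) break
      }
      abs_cor(ij[1], ij[2])
    }, numeric(1)), na.rm = TRUE)
  })
  off_lv <- sort(as.integer(names(offsets)))
  decay <- data.frame(offset = off_lv,
                      mean_abs_cor = vapply(as.character(off_lv), function(o)
                        mean(offsets[[o]], na.rm = TRUE), numeric(1)))
  list(within_block = within, mean_within = mean(within, na.rm = TRUE),
       mean_cross = cross, decay = decay)
}

#' Shuffle a phenotype vector (permutation control)
#'
#' Randomly permutes trait values over samples while keeping the genotype
#' rows fixed, destroying any genotype-phenotype association.  Running the
#' full protocol on a shuffled trait is the negative control: validation
#' accuracy should drop to chance.
#'
#' @param y numeric phenotype vector.
#' @param seed integer seed.
#' @return Permuted copy of `y` (same multiset of values).
#' @export
shuffle_phenotype <- function(y, seed) {
  if (length(y) < 2L) return(y)
  with_preserved_rng({
    set.seed(seed)
    y[sample.int(length(y))]
  })
}
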