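#' Ranked partial feature list
#'
#' An ordered list of the top `k` feature identifiers out of a universe of
#' `p` features, as produced by sparse feature selection.  Two such lists
#' over a common universe can be compared with the Canberra distance after
#' completing each to a full rank vector.
#'
#' @param items ordered character vector of selected feature identifiers
#'   (best first), without duplicates.
#' @param universe character vector of all `p` feature identifiers, or a
#'   single integer `p` (features are then `1..p` as character).
#' @return An object of class `ranked_list` with elements `items` and
#'   `universe`.
#' @export
ranked_list <- function(items, universe) {
  items <- as.character(items)
  if (length(universe) == 1L && is.numeric(universe))
    universe <- as.character(seq_len(universe))
  universe <- as.character(universe)
  if (anyDuplicated(items))
    l1l2_stop("ranked list contains duplicate items", "l1l2dap_data_error")
  if (anyDuplicated(universe))
    l1l2_stop("feature universe contains duplicates", "l1l2dap_data_error")
  if (!all(items %in% universe))
    l1l2_stop("ranked list contains items outside the universe",
              "l1l2dap_structural_error")
  structure(list(items = items, universe = universe), class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list: %d of %d features\n",
              length(x$items), length(x$universe)))
  if (length(x$items))
    cat("  top:", paste(head(x$items, 5), collapse = ", "),
        if (length(x$items) > 5) "..." else "", "\n")
  invisible(x)
}

#' Canberra distance between two rank vectors
#'
#' \eqn{\sum_i |a_i - b_i| / (a_i + b_i)} for elementwise-positive rank
#' vectors.  Because the denominator grows with rank, a disagreement at the
#' top of the lists costs more than an equal-sized disagreement at the
#' bottom, which is why this distance is used to measure stability of
#' marker rankings.
#'
#' @param a,b positive rank vectors of equal length.
#' @return Non-negative scalar; 0 iff `a == b`.
#' @export
canberra_ranks <- function(a, b) {
  if (length(a) != length(b))
    l1l2_stop("rank vectors must have equal length", "l1l2dap_structural_error")
  stopifnot(all(a > 0), all(b > 0))
  sum(abs(a - b) / (a + b))
}

#' Complete a partial ranked list to a full rank vector
#'
#' Listed items receive ranks `1..k` in list order; every unlisted feature
#' receives the constant rank `(k + 1 + p) / 2`, the mean of the unoccupied
#' positions `k+1, ..., p` — the per-element expectation of its rank over
#' uniform extensions of the partial list.
#'
#' @param L a [ranked_list()].
#' @return Named numeric rank vector of length `p`, ordered like the
#'   universe.
#' @export
complete_ranks <- function(L) {
  stopifnot(inherits(L, "ranked_list"))
  p <- length(L$universe)
  k <- length(L$items)
  r <- rep((k + 1 + p) / 2, p)
  names(r) <- L$universe
  r[L$items] <- seq_len(k)
  r
}

#' Canberra distance between two partial ranked lists
#'
#' Each list is completed with [complete_ranks()] (lists may have different
#' lengths) and the classical Canberra distance of the completed rank
#' vectors is returned.
#'
#' @param L1,L2 [ranked_list()] objects over the same universe.
#' @return Non-negative scalar distance.
#' @export
canberra_partial <- function(L1, L2) {
  if (!identical(L1$universe, L2$universe))
    l1l2_stop("ranked lists live on different feature universes",
              "l1l2dap_structural_error")
  canberra_ranks(complete_ranks(L1), complete_ranks(L2))
}

#' Canberra stability indicator of a set of ranked lists
#'
#' The mean of all pairwise Canberra distances among the lists; lower
#' values indicate a more reproducible feature selection across folds or
#' resamplings.  The optional normalization divides by the expected
#' distance between two uniformly random full permutations of the universe
#' (Monte-Carlo estimate under a fixed internal seed), giving a scale-free
#' score for plotting; the raw value is the one used for model selection.
#'
#' @param lists a list of two or more [ranked_list()] objects over a common
#'   universe.
#' @param normalization `"raw"` or `"max_normalized"`.
#' @return A list of class `stability_value` with `mean_distance`,
#'   `n_lists` and `normalization`.
#' @export
stability_indicator <- function(lists, normalization = c("raw",
                                                         "max_normalized")) {
  normalization <- match.arg(normalization)
  m <- length(lists)
  if (m < 2L)
    l1l2_stop("stability requires at least two ranked lists",
              "l1l2dap_precondition_error")
  ranks <- vapply(lists, function(L) {
    if (!identical(L$universe, lists[[1]]$universe))
      l1l2_stop("ranked lists live on different feature universes",
                "l1l2dap_structural_error")
    complete_ranks(L)
  }, numeric(length(lists[[1]]$universe)))
  d <- 0
  for (i in seq_len(m - 1L))
    for (j in seq.int(i + 1L, m))
      d <- d + canberra_ranks(ranks[, i], ranks[, j])
  mean_d <- d / choose(m, 2)
  if (normalization == "max_normalized")
    mean_d <- mean_d / random_permutation_distance(length(lists[[1]]$universe))
  structure(list(mean_distance = mean_d, n_lists = m,
                 normalization = normalization),
            class = "stability_value")
}

#' @export
print.stability_value <- function(x, ...) {
  cat(sprintf("Canberra stability: %.4f (%s, %d lists)\n",
              x$mean_distance, x$normalization, x$n_lists))
  invisible(x)
}

# Expected Canberra distance between two uniform random permutations of
# 1..p, estimated once per p by Monte Carlo with a fixed internal seed and
# cached for the session.
random_permutation_distance <- local({
  cache <- new.env(parent = emptyenv())
  function(p, n_draws = 200L) {
    key <- as.character(p)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- with_preserved_rng({
      set.seed(20100L + p)
      mean(replicate(n_draws,
                     canberra_ranks(sample.int(p), sample.int(p))))
    })
    cache[[key]] <- val
    val
  }
})
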