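#' Euclidean distance to the ideal objective point
#'
#' The bi-objective formulation places its ideal (simultaneously optimal)
#' solution at the origin, so solution quality reduces to `sqrt(f1^2 + f2^2)`.
#'
#' @param objectives Numeric objective vector, or a matrix with one vector
#'   per row.
#' @return A non-negative number (or vector, for matrix input).
#' @export
distance_to_ideal <- function(objectives) {
  if (is.matrix(objectives)) sqrt(rowSums(objectives^2))
  else sqrt(sum(objectives^2))
}

#' Size-matched random gene subset
#'
#' Draws a uniformly random subset of exactly `size` genes out of `n`; the
#' null counterpart of an observed Pareto solution. Uses the current RNG
#' stream.
#'
#' @param size Number of member genes, `0 < size < n`.
#' @param n Total number of genes.
#' @return Logical membership vector of length `n`.
#' @export
null_matched_set <- function(size, n) {
  stopifnot(size > 0, size < n)
  bits <- logical(n)
  bits[sample.int(n, size)] <- TRUE
  bits
}

#' Anderson-Darling test for normality
#'
#' Composite-normality Anderson-Darling test (mean and variance estimated
#' from the sample, with the usual small-sample correction of the statistic).
#' Used diagnostically before the nonparametric two-sample comparison.
#'
#' @param x Numeric vector, length >= 8, non-constant.
#' @return A list with the corrected statistic `A2` and `p`.
#' @export
anderson_darling_normality <- function(x) {
  if (length(x) < 8) stop("need at least 8 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant vector: normality test undefined",
                              call. = FALSE)
  fit <- nortest::ad.test(x)
  list(A2 = unname(fit$statistic), p = fit$p.value)
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Rank-sum comparison of two samples. The exact null distribution is used
#' when both samples have at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' `alternative = "less"` tests whether `x` is stochastically smaller than
#' `y`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative `"less"` or `"two_sided"`.
#' @return A list with the Mann-Whitney `U` (for `x`) and `p`.
#' @export
wilcoxon_mann_whitney <- function(x, y, alternative = c("less", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 8 && !has_ties
  fit <- suppressWarnings(stats::wilcox.test(
    x, y,
    alternative = if (alternative == "less") "less" else "two.sided",
    exact = exact, correct = TRUE
  ))
  list(U = unname(fit$statistic), p = fit$p.value, exact = exact)
}

#' Significance of a Pareto set against size-matched random subsets
#'
#' For each solution of a Pareto set, a random gene set with the same number
#' of members is drawn and pushed through the same objective evaluator. The
#' two resulting distance-to-ideal samples (observed vs null) are compared
#' with a one-sided Wilcoxon-Mann-Whitney test (observed stochastically
#' smaller = the front sits closer to the ideal than chance size-matched
#' sets). Anderson-Darling normality checks of both samples are attached as
#' diagnostics — the procedure never branches on them, since distance
#' distributions are generally non-normal.
#'
#' @param pareto A `dnb_pareto` tibble from [run_nsga2()] (needs the `bits`
#'   list-column), or a list of logical membership vectors.
#' @param evaluate The objective evaluator used for the observed solutions.
#' @param n Number of genes.
#' @param seed Integer seed for the null draws.
#' @param null_replicates Null sets drawn per observed solution (default 1,
#'   one-to-one matching; more gives smoother null tails).
#' @param alternative Passed to [wilcoxon_mann_whitney()].
#' @return A list of class `dnb_significance`: `observed_distances`,
#'   `null_distances`, `ad_observed_p`, `ad_null_p` (NA when a sample is too
#'   small for the diagnostic), `wmw_u`, `wmw_p`, `n_pairs`.
#' @export
pareto_significance <- function(pareto, evaluate, n, seed = 1L,
                                null_replicates = 1L,
                                alternative = c("less", "two_sided")) {
  alternative <- match.arg(alternative)
  bits_list <- if (inherits(pareto, "data.frame")) pareto$bits else pareto
  stopifnot(length(bits_list) > 0)
  obs <- if (inherits(pareto, "data.frame") && "distance_to_ideal" %in% names(pareto)) {
    pareto$distance_to_ideal
  } else {
    vapply(bits_list, function(b) distance_to_ideal(as.numeric(evaluate(b))),
           numeric(1))
  }
  sizes <- vapply(bits_list, sum, numeric(1))
  nul <- withr::with_seed(seed, {
    unlist(lapply(seq_len(null_replicates), function(rep) {
      vapply(sizes, function(sz) {
        distance_to_ideal(as.numeric(evaluate(null_matched_set(sz, n))))
      }, numeric(1))
    }))
  })

  ad_safe <- function(v) {
    if (length(v) < 8 || stats::sd(v) == 0) return(NA_real_)
    anderson_darling_normality(v)$p
  }
  wmw <- wilcoxon_mann_whitney(obs, nul, alternative = alternative)
  structure(list(observed_distances = obs,
                 null_distances = nul,
                 ad_observed_p = ad_safe(obs),
                 ad_null_p = ad_safe(nul),
                 wmw_u = wmw$U,
                 wmw_p = wmw$p,
                 n_pairs = length(obs)),
            class = "dnb_significance")
}

#' @export
print.dnb_significance <- function(x, ...) {
  cat(sprintf("<dnb_significance> %d Pareto solution(s) vs %d null set(s)\n",
              x$n_pairs, length(x$null_distances)))
  cat(sprintf("  WMW (observed < null): U = %g, p = %.4g\n", x$wmw_u, x$wmw_p))
  cat(sprintf("  AD normality p: observed %s, null %s\n",
              format(x$ad_observed_p, digits = 3),
              format(x$ad_null_p, digits = 3)))
  invisible(x)
}

#' @method tidy dnb_significance
#' @export
tidy.dnb_significance <- function(x, ...) {
  tibble::tibble(
    sample = rep(c("observed", "null"),
                 c(length(x$observed_distances), length(x$null_distances))),
    distance = c(x$observed_distances, x$null_distances)
  )
}

#' @method glance dnb_significance
#' @export
glance.dnb_significance <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, wmw_u = x$wmw_u, wmw_p = x$wmw_p,
                 ad_observed_p = x$ad_observed_p, ad_null_p = x$ad_null_p)
}
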