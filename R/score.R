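#' Pearson correlation with a zero-variance guard
#'
#' Standard sample Pearson correlation. A vector with zero variance yields
#' `r = 0` with a warning rather than `NA`: during the evolutionary search a
#' mutation can momentarily include a flat gene, and a defined value keeps
#' the correlation averages total.
#'
#' @param u,v Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  stopifnot(length(u) >= 3)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("zero-variance vector in correlation; returning 0", call. = FALSE)
    return(0)
  }
  stats::cor(u, v)
}

# Absolute-correlation matrix of the rows of `mat`, with zero-variance rows
# contributing 0 (single warning). The diagonal is 1 and never enters any
# of the subset averages below.
abs_corr_matrix <- function(mat) {
  r <- suppressWarnings(stats::cor(t(mat)))
  if (anyNA(r)) {
    warning("zero-variance gene(s) in correlation matrix; treating r as 0",
            call. = FALSE)
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  abs(r)
}

subset_indices <- function(subset, n) {
  if (is.logical(subset)) {
    stopifnot(length(subset) == n)
    which(subset)
  } else {
    idx <- as.integer(subset)
    stopifnot(all(idx >= 1), all(idx <= n), !anyDuplicated(idx))
    idx
  }
}

#' Within-subset mean absolute correlation
#'
#' Mean of `|r|` over all distinct gene pairs inside the subset at one
#' time-point's matrix; the "intra-class" criterion that rises sharply as a
#' dynamical network biomarker approaches the tipping point.
#'
#' @param mat Gene x sample numeric matrix at one time-point.
#' @param subset Logical membership vector of length `nrow(mat)`, or integer
#'   gene indices; at least 2 members.
#' @return Mean absolute within-subset Pearson correlation in `[0, 1]`.
#' @export
intra_class_corr <- function(mat, subset) {
  idx <- subset_indices(subset, nrow(mat))
  if (length(idx) < 2) stop("subset must contain >= 2 genes", call. = FALSE)
  a <- abs_corr_matrix(mat[idx, , drop = FALSE])
  m <- length(idx)
  (sum(a) - m) / (m * (m - 1))
}

#' Subset-to-rest mean absolute correlation
#'
#' Mean of `|r|` over all (inside, outside) gene pairs; the "inter-class"
#' criterion that falls as the biomarker group decouples from the rest of
#' the network.
#'
#' @inheritParams intra_class_corr
#' @return Mean absolute inside-outside Pearson correlation in `[0, 1]`.
#' @export
inter_class_corr <- function(mat, subset) {
  idx <- subset_indices(subset, nrow(mat))
  n <- nrow(mat)
  if (length(idx) == 0 || length(idx) == n) {
    stop("subset must be non-empty and leave a non-empty complement",
         call. = FALSE)
  }
  a <- abs_corr_matrix(mat)
  mean(a[idx, -idx, drop = FALSE])
}

#' Mean per-gene standard deviation over a subset
#'
#' Mean, over subset genes, of the sample (n-1 denominator) standard
#' deviation across the samples of one time-point; the fluctuation
#' criterion.
#'
#' @inheritParams intra_class_corr
#' @return Non-negative mean standard deviation in expression units.
#' @export
mean_sd <- function(mat, subset) {
  idx <- subset_indices(subset, nrow(mat))
  if (length(idx) < 1) stop("subset must be non-empty", call. = FALSE)
  if (ncol(mat) < 2) stop("need >= 2 samples", call. = FALSE)
  mean(apply(mat[idx, , drop = FALSE], 1, stats::sd))
}

#' Composite early-warning index of a gene subset
#'
#' Combines the three dynamical-network-biomarker criteria into the scalar
#' \deqn{I = \mathrm{SD}_{in} \cdot \mathrm{PCC}_{in} / \max(\mathrm{PCC}_{out}, \epsilon)}
#' where SD_in is [mean_sd()], PCC_in is [intra_class_corr()], PCC_out is
#' [inter_class_corr()], and `eps` floors the denominator so a fully
#' decoupled subset does not blow up numerically.
#'
#' @param dataset A [dnb_dataset] (normalized; case samples are used).
#' @param subset Logical membership vector or integer gene indices.
#' @param t Time index (1-based position in `dataset$times`).
#' @param eps Denominator floor (default `1e-8`).
#' @return A one-row tibble with `sd_in`, `pcc_in`, `pcc_out`, `index`.
#' @export
composite_index <- function(dataset, subset, t, eps = 1e-8) {
  stopifnot(inherits(dataset, "dnb_dataset"),
            t >= 1, t <= length(dataset$times))
  mat <- dataset$case[[t]]
  composite_from_matrix(mat, subset, eps = eps)
}

#' @rdname composite_index
#' @param mat Gene x sample matrix at one time-point (alternative entry point
#'   when no dataset object is at hand).
#' @export
composite_from_matrix <- function(mat, subset, eps = 1e-8) {
  idx <- subset_indices(subset, nrow(mat))
  sd_in <- mean_sd(mat, idx)
  pcc_in <- intra_class_corr(mat, idx)
  pcc_out <- inter_class_corr(mat, idx)
  tibble::tibble(sd_in = sd_in, pcc_in = pcc_in, pcc_out = pcc_out,
                 index = sd_in * pcc_in / max(pcc_out, eps))
}

# Precomputed per-time statistics (|r| matrix + per-gene SD) for the fast
# evaluator used inside the search; algebraically identical to
# composite_from_matrix.
time_stats <- function(mat) {
  list(absR = abs_corr_matrix(mat), sd = apply(mat, 1, stats::sd))
}

index_from_stats <- function(stats, idx, eps = 1e-8) {
  m <- length(idx)
  a <- stats$absR
  pcc_in <- (sum(a[idx, idx]) - m) / (m * (m - 1))
  pcc_out <- (sum(a[idx, ]) - sum(a[idx, idx])) / (m * (nrow(a) - m))
  sd_in <- mean(stats$sd[idx])
  sd_in * pcc_in / max(pcc_out, eps)
}

#' Bi-objective value of a candidate subset
#'
#' The search asks a biomarker group to (1) show a strong composite-index
#' signal at the scanned time-point and (2) be quiet one sampling time
#' earlier, so that the signal marks the *onset* of the transition rather
#' than an established disease module. Both are cast as minimization with
#' ideal point `(0, 0)`:
#' \deqn{f_1 = 1 / (1 + I_t), \qquad f_2 = I_{t-1}.}
#' The look-back covers only the immediately preceding sampling time: on an
#' unintervened disease course the pre-disease stage is not revisited, so
#' earlier time-points carry no additional signal.
#'
#' @inheritParams composite_index
#' @param t Time index with a predecessor (`t >= 2`).
#' @return Named numeric vector `c(f1, f2)`.
#' @export
dnb_objectives <- function(dataset, subset, t, eps = 1e-8) {
  if (t < 2) stop("t must have a preceding time-point", call. = FALSE)
  i_now <- composite_index(dataset, subset, t, eps = eps)$index
  i_prev <- composite_index(dataset, subset, t - 1, eps = eps)$index
  c(f1 = 1 / (1 + i_now), f2 = i_prev)
}
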