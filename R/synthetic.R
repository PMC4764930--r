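#' Specification of a synthetic planted-DNB experiment
#'
#' Describes a seeded time-course case/control dataset with a planted
#' dynamical-network-biomarker block: a background of weakly correlated gene
#' blocks at every time-point, and one designated gene block whose
#' within-block correlation and per-gene variance escalate at the planted
#' pre-disease time while its correlation to the background drops to ~0.
#'
#' Defaults describe the package's reference study condition: 200 genes, a
#' 12-gene planted block, 6 time-points with 20 case and 20 control
#' replicates each, planted time-point 4, within-block correlation 0.8 at
#' the planted time vs 0.2 background, and a 3-fold SD boost. Case samples
#' of `de_fraction` of the genes (always including the planted block) are
#' mean-shifted by `shift` SD units above the control baseline at *all*
#' time-points, so the differential-expression filter retains them without
#' leaking the planted time.
#'
#' @param n_genes Total genes (default 200).
#' @param dnb_size Planted block size (default 12).
#' @param n_times Number of time-points (default 6; hours 1..T).
#' @param k_case,k_ctrl Replicates per group per time-point (default 20).
#' @param t_star Planted pre-disease time index (default 4).
#' @param rho_in Within-block correlation at `t_star` (default 0.8).
#' @param rho_bg Background within-block correlation (default 0.2).
#' @param sd_boost Planted-block SD multiplier at `t_star` (default 3).
#' @param de_fraction Fraction of genes with a case mean shift (default 1).
#' @param shift Case mean shift in control-SD units (default 1.5; with unit
#'   baseline mean this puts the linear fold change at 2.5, past the 2-fold
#'   filter).
#' @param base_mean Control baseline mean (default 1).
#' @param block_size Background block size (default 10).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, dnb_size = 12, n_times = 6,
                           k_case = 20, k_ctrl = 20, t_star = 4,
                           rho_in = 0.8, rho_bg = 0.2, sd_boost = 3,
                           de_fraction = 1, shift = 1.5, base_mean = 1,
                           block_size = 10, seed = 1L) {
  stopifnot(dnb_size < n_genes, dnb_size >= 2,
            t_star > 1, t_star <= n_times,
            rho_bg >= 0, rho_in >= rho_bg, rho_in < 1,
            sd_boost >= 1,
            de_fraction >= 0, de_fraction <= 1,
            k_case >= 3, k_ctrl >= 2)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Equicorrelated block draw: k samples for `m` genes sharing a latent factor.
# Gives exact population correlation `rho` within the block and 0 across
# blocks; valid for any rho in [0, 1).
equicorr_block <- function(m, k, rho) {
  z <- stats::rnorm(k)
  eps <- matrix(stats::rnorm(m * k), m, k)
  sqrt(rho) * matrix(z, m, k, byrow = TRUE) + sqrt(1 - rho) * eps
}

#' Generate a synthetic planted-DNB dataset
#'
#' Draws the dataset described by a [synthetic_spec()]. Sampling is via a
#' latent-factor factorization of the block covariance, fully driven by
#' `spec$seed`; the global RNG state is untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (an unnormalized [dnb_dataset] with both
#'   groups) and `truth` (list: `genes` — the planted block's identifiers,
#'   `t_star` — its time index, `t_star_hours`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_impl(spec))
}

generate_impl <- function(spec) {
  n <- spec$n_genes
  genes <- sprintf("g%03d", seq_len(n))
  dnb_idx <- sort(sample.int(n, spec$dnb_size))
  bg_idx <- setdiff(seq_len(n), dnb_idx)

  # background genes in random blocks of ~block_size
  bg_perm <- sample(bg_idx)
  bg_blocks <- split(bg_perm, ceiling(seq_along(bg_perm) / spec$block_size))

  # mean-shifted (differentially expressed) genes: planted block always in
  n_shift <- min(n, max(spec$dnb_size, round(spec$de_fraction * n)))
  shifted <- union(dnb_idx, sample(bg_idx, max(0, n_shift - spec$dnb_size)))

  draw_matrix <- function(k, group, ti) {
    m <- matrix(0, n, k)
    for (blk in bg_blocks) {
      m[blk, ] <- equicorr_block(length(blk), k, spec$rho_bg)
    }
    boosted <- group == "case" && ti == spec$t_star
    rho <- if (boosted) spec$rho_in else spec$rho_bg
    scale <- if (boosted) spec$sd_boost else 1
    m[dnb_idx, ] <- scale * equicorr_block(length(dnb_idx), k, rho)
    m <- m + spec$base_mean
    if (group == "case") {
      m[shifted, ] <- m[shifted, ] + spec$shift
    }
    colnames(m) <- sprintf("t%d_%s_%d", ti, group, seq_len(k))
    rownames(m) <- genes
    m
  }

  case <- lapply(seq_len(spec$n_times), function(ti)
    draw_matrix(spec$k_case, "case", ti))
  control <- lapply(seq_len(spec$n_times), function(ti)
    draw_matrix(spec$k_ctrl, "control", ti))

  dataset <- structure(
    list(genes = genes,
         times = as.numeric(seq_len(spec$n_times)),
         case = case,
         control = control,
         normalized = FALSE),
    class = "dnb_dataset"
  )
  list(dataset = dataset,
       truth = list(genes = genes[dnb_idx],
                    t_star = spec$t_star,
                    t_star_hours = as.numeric(spec$t_star)))
}

#' Write a synthetic dataset and its ground truth to disk
#'
#' Emits `expression.tsv`, `metadata.tsv` (the canonical two-table form read
#' by [read_expression_table()]) and `truth.json` with the planted gene
#' identifiers and time-point.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the generated object from [generate_dataset()].
#' @export
write_fixture <- function(spec, out_dir) {
  gen <- generate_dataset(spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_dataset(gen$dataset, out_dir)
  truth_json <- jsonlite::toJSON(gen$truth, auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
  writeLines(truth_json, file.path(out_dir, "truth.json"))
  invisible(gen)
}
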