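#' Aggregate probe-level values to gene level
#'
#' Multiple probes mapping to the same gene are averaged per sample; probes
#' without a mapping entry (absent, `NA`, or blank gene symbol) are dropped.
#' Output genes are in lexicographic order.
#'
#' @param probe_table A data frame whose first column is the probe identifier
#'   and whose remaining columns are numeric sample values.
#' @param mapping A data frame with columns `probe_id` and `gene_symbol`.
#' @return A tibble with a `gene` column followed by the sample columns.
#' @export
#' @examples
#' probes <- data.frame(probe_id = c("p1", "p2", "p3"),
#'                      s1 = c(2, 4, 7), s2 = c(1, 3, 9))
#' map <- data.frame(probe_id = c("p1", "p2"), gene_symbol = c("G", "G"))
#' aggregate_probes(probes, map)  # G: mean of p1, p2; p3 dropped
aggregate_probes <- function(probe_table, mapping) {
  probe_table <- tibble::as_tibble(probe_table)
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(mapping)))
  names(probe_table)[1] <- "probe_id"
  probe_table$probe_id <- as.character(probe_table$probe_id)
  mapping$probe_id <- as.character(mapping$probe_id)
  mapping$gene_symbol <- as.character(mapping$gene_symbol)
  mapping <- mapping[!is.na(mapping$gene_symbol) & mapping$gene_symbol != "", ]

  joined <- dplyr::inner_join(mapping[, c("probe_id", "gene_symbol")],
                              probe_table, by = "probe_id")
  if (nrow(joined) == 0) {
    stop("no probe maps to a gene symbol; nothing to aggregate", call. = FALSE)
  }
  out <- joined |>
    dplyr::select(-"probe_id") |>
    dplyr::rename(gene = "gene_symbol") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop") |>
    dplyr::arrange(.data$gene)
  out
}

#' Moderated two-sample t-test
#'
#' Welch's unequal-variance t-statistic with an additive offset `s0` on the
#' standard-error denominator: `t = (mean(case) - mean(control)) / (s + s0)`,
#' where `s` is the Welch standard error. `s0 = 0` recovers the standard
#' Welch test; a positive `s0` damps statistics driven by tiny variances, the
#' usual moderation for expression data. The p-value uses the two-sided t
#' distribution with Welch-Satterthwaite degrees of freedom.
#'
#' @param case,control Numeric vectors, each of length >= 2.
#' @param s0 Non-negative variance-stabilizing offset (default 0).
#' @return A named list with `t`, `p` and `df`.
#' @export
modified_t_test <- function(case, control, s0 = 0) {
  stopifnot(length(case) >= 2, length(control) >= 2, s0 >= 0)
  n1 <- length(case); n2 <- length(control)
  v1 <- stats::var(case); v2 <- stats::var(control)
  se2 <- v1 / n1 + v2 / n2
  s <- sqrt(se2)
  if (s == 0 && s0 == 0) {
    stop("zero variance in both groups with s0 = 0: statistic undefined",
         call. = FALSE)
  }
  tval <- (mean(case) - mean(control)) / (s + s0)
  df <- if (s > 0) {
    se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(tval), df = df)
  list(t = tval, p = p, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, returned in input order; `q >= p` always and
#' `q <= 1`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-expression filter for informative genes
#'
#' At each time-point, runs the moderated t-test case vs control per gene,
#' adjusts p-values across genes with [fdr_adjust()] (per time-point), and
#' computes the linear-scale fold change of group means. A gene is kept iff
#' at at least one time-point `q <= q_max` AND the fold change is at least
#' `fc_min` or at most `1/fc_min`.
#'
#' @param dataset An unnormalized [dnb_dataset] with both groups at every
#'   time-point.
#' @param q_max Maximal FDR level (default 0.01).
#' @param fc_min Minimal fold change (default 2: doubled or halved).
#' @param s0 Offset passed to [modified_t_test()].
#' @param input_scale `"linear"` (fold change = ratio of group means) or
#'   `"log2"` (fold change = `2^(mean difference)`).
#' @return A list of class `dnb_de`: `genes` (the survivors, in dataset
#'   order) and `stats`, a tibble with one row per gene x time
#'   (`gene`, `time_hours`, `t_statistic`, `p_value`, `q_value`,
#'   `fold_change`, `keep`).
#' @export
informative_gene_filter <- function(dataset, q_max = 0.01, fc_min = 2,
                                    s0 = 0, input_scale = c("linear", "log2")) {
  stopifnot(inherits(dataset, "dnb_dataset"))
  if (isTRUE(dataset$normalized)) {
    stop("informative_gene_filter expects an unnormalized dataset", call. = FALSE)
  }
  input_scale <- match.arg(input_scale)
  res <- list()
  for (ti in seq_along(dataset$times)) {
    cs <- dataset$case[[ti]]
    ct <- dataset$control[[ti]]
    if (ncol(cs) < 2 || ncol(ct) < 2) {
      stop(sprintf("need >= 2 case and control samples at t = %g h",
                   dataset$times[ti]), call. = FALSE)
    }
    tp <- vapply(seq_along(dataset$genes), function(i) {
      r <- modified_t_test(cs[i, ], ct[i, ], s0 = s0)
      c(r$t, r$p)
    }, numeric(2))
    fc <- if (input_scale == "linear") {
      rowMeans(cs) / rowMeans(ct)
    } else {
      2^(rowMeans(cs) - rowMeans(ct))
    }
    res[[ti]] <- tibble::tibble(
      gene = dataset$genes,
      time_hours = dataset$times[ti],
      t_statistic = tp[1, ],
      p_value = tp[2, ],
      q_value = fdr_adjust(tp[2, ]),
      fold_change = fc
    )
  }
  stats <- dplyr::bind_rows(res)
  stats$keep <- stats$q_value <= q_max &
    (stats$fold_change >= fc_min | stats$fold_change <= 1 / fc_min)
  kept <- unique(stats$gene[stats$keep])
  genes <- dataset$genes[dataset$genes %in% kept]
  if (length(genes) == 0) {
    warning("no gene passes the q-value and fold-change rules", call. = FALSE)
  }
  structure(list(genes = genes, stats = stats,
                 q_max = q_max, fc_min = fc_min),
            class = "dnb_de")
}

#' @export
print.dnb_de <- function(x, ...) {
  cat(sprintf("<dnb_de> %d informative gene(s) (q <= %g, fold change >= %g or <= %g)\n",
              length(x$genes), x$q_max, x$fc_min, 1 / x$fc_min))
  invisible(x)
}

#' @method tidy dnb_de
#' @export
tidy.dnb_de <- function(x, ...) x$stats

#' Control-referenced normalization
#'
#' Per gene and time-point, case expressions are centered by the control-group
#' mean and scaled by the control-group standard deviation, making
#' composite-index values comparable across time-points. Downstream analysis
#' then uses case samples only.
#'
#' @param dataset An unnormalized [dnb_dataset] with >= 2 control samples at
#'   every time-point.
#' @return The dataset with transformed case matrices and `normalized = TRUE`.
#'   A gene with zero control variance at some time-point is an error naming
#'   the (gene, time) pair; filter such genes out first.
#' @export
normalize_to_controls <- function(dataset) {
  stopifnot(inherits(dataset, "dnb_dataset"))
  if (isTRUE(dataset$normalized)) return(dataset)
  for (ti in seq_along(dataset$times)) {
    ct <- dataset$control[[ti]]
    if (ncol(ct) < 2) {
      stop(sprintf("need >= 2 control samples at t = %g h", dataset$times[ti]),
           call. = FALSE)
    }
    mu <- rowMeans(ct)
    sdv <- apply(ct, 1, stats::sd)
    if (any(sdv == 0)) {
      g <- dataset$genes[which(sdv == 0)[1]]
      stop(sprintf("zero control standard deviation for gene '%s' at t = %g h",
                   g, dataset$times[ti]), call. = FALSE)
    }
    dataset$case[[ti]] <- (dataset$case[[ti]] - mu) / sdv
  }
  dataset$normalized <- TRUE
  dataset
}
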