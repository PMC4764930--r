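derive_seed <- function(root, k) {
  as.integer((as.numeric(root) %% 2147483629) * 653 + 97 * k) %% 2147483629L + 1L
}

#' Scan candidate time-points with the evolutionary search
#'
#' Runs the NSGA-II subset search at every sampling time that has a
#' predecessor, up to and including `t_last`, assesses each resulting Pareto
#' set against size-matched random gene sets, and records every solution's
#' composite-index trajectory across all time-points. Each time-point's run
#' (and its null draws) uses a seed derived deterministically from
#' `config$seed` and the time index, so a root seed reproduces the whole
#' scan.
#'
#' @param dataset A normalized [dnb_dataset] with >= 3 case replicates per
#'   time-point.
#' @param config A [moo_config()].
#' @param t_last Last candidate time in hours (default: the latest sampling
#'   time, the fallback when no disease-onset knowledge is available).
#' @param eps Composite-index denominator floor.
#' @param null_replicates Null sets per Pareto solution for the significance
#'   test.
#' @return An object of class `dnb_scan_set`: a list of per-time scans, each
#'   of class `dnb_scan` with elements `time_hours`, `time_index`, `pareto`
#'   (tibble with a `genes` list-column), `significance`
#'   ([pareto_significance()] result) and `trajectories` (tibble
#'   `solution_id` x `time_hours` x `index`).
#' @export
scan_timepoints <- function(dataset, config = moo_config(), t_last = NULL,
                            eps = 1e-8, null_replicates = 1L) {
  stopifnot(inherits(dataset, "dnb_dataset"))
  if (!isTRUE(dataset$normalized)) {
    stop("scan_timepoints expects a control-normalized dataset", call. = FALSE)
  }
  times <- dataset$times
  if (length(times) < 2) stop("need at least 2 time-points", call. = FALSE)
  k_case <- vapply(dataset$case, ncol, integer(1))
  if (any(k_case < 3)) {
    stop("need >= 3 case replicates at every time-point for correlations",
         call. = FALSE)
  }
  if (is.null(t_last)) t_last <- max(times)
  candidates <- which(seq_along(times) >= 2 & times <= t_last)
  if (length(candidates) == 0) {
    stop("no candidate time-point at or before t_last", call. = FALSE)
  }
  n <- length(dataset$genes)
  stats <- lapply(dataset$case, time_stats)

  scans <- lapply(candidates, function(ti) {
    evaluate <- function(bits) {
      idx <- which(bits)
      c(1 / (1 + index_from_stats(stats[[ti]], idx, eps)),
        index_from_stats(stats[[ti - 1]], idx, eps))
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 2L * ti)
    pareto <- run_nsga2(evaluate, n, cfg)
    pareto$genes <- lapply(pareto$bits, function(b) dataset$genes[b])
    sig <- pareto_significance(pareto, evaluate, n,
                               seed = derive_seed(config$seed, 2L * ti + 1L),
                               null_replicates = null_replicates)
    traj <- tidyr::expand_grid(solution_id = pareto$solution_id,
                               time_index = seq_along(times))
    traj$time_hours <- times[traj$time_index]
    traj$index <- vapply(seq_len(nrow(traj)), function(r) {
      idx <- which(pareto$bits[[traj$solution_id[r]]])
      index_from_stats(stats[[traj$time_index[r]]], idx, eps)
    }, numeric(1))
    structure(list(time_hours = times[ti], time_index = ti,
                   pareto = pareto, significance = sig,
                   trajectories = traj[, c("solution_id", "time_hours", "index")]),
              class = "dnb_scan")
  })
  structure(scans, class = "dnb_scan_set", times = times)
}

#' @export
print.dnb_scan_set <- function(x, ...) {
  cat(sprintf("<dnb_scan_set> %d scanned time-point(s)\n", length(x)))
  print(tidy(x))
  invisible(x)
}

#' Per-time summary of a scan set
#'
#' @param x A `dnb_scan_set`.
#' @param ... Unused.
#' @return A tibble with one row per scanned time: `time_hours`,
#'   `n_solutions`, `min_distance`, `wmw_p`, AD diagnostics.
#' @method tidy dnb_scan_set
#' @export
tidy.dnb_scan_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, function(s) {
    tibble::tibble(time_hours = s$time_hours,
                   n_solutions = nrow(s$pareto),
                   min_distance = min(s$pareto$distance_to_ideal),
                   wmw_p = s$significance$wmw_p,
                   ad_observed_p = s$significance$ad_observed_p,
                   ad_null_p = s$significance$ad_null_p)
  }))
}

#' Select the pre-disease time-point
#'
#' The pre-disease stage is the scanned time whose Pareto set is most
#' significantly closer to the ideal point than chance: the smallest
#' Wilcoxon-Mann-Whitney p-value, ties broken toward the earliest time.
#'
#' @param scans A `dnb_scan_set`.
#' @return The selected time in hours.
#' @export
select_predisease <- function(scans) {
  stopifnot(inherits(scans, "dnb_scan_set"))
  p <- vapply(scans, function(s) s$significance$wmw_p, numeric(1))
  t <- vapply(scans, function(s) s$time_hours, numeric(1))
  t[order(p, t)[1]]
}

#' Select the biomarker from one time-point's Pareto set
#'
#' Stands in for the decision maker's default rule: the solution whose
#' objective vector is closest (Euclidean) to the ideal point. Ties go to
#' the smaller gene set, then the lexicographically smallest bit-string.
#'
#' @param scan A `dnb_scan` (one element of a `dnb_scan_set`).
#' @return A one-row tibble: the chosen Pareto solution with its `genes`.
#' @export
select_dnb <- function(scan) {
  stopifnot(inherits(scan, "dnb_scan"))
  p <- scan$pareto
  keys <- vapply(p$bits, bits_key, character(1))
  ord <- order(p$distance_to_ideal, p$size, keys)
  p[ord[1], , drop = FALSE]
}

#' Run the full biomarker-discovery workflow
#'
#' End-to-end chain: (optional) probe aggregation, differential-expression
#' filtering, control-referenced normalization, per-time evolutionary scan,
#' pre-disease time selection, and biomarker selection. Any stage error is
#' re-signalled with the stage name.
#'
#' @param expr Expression table: a file path (`.tsv`/`.csv`), or a data
#'   frame (first column gene — or probe — identifiers).
#' @param meta Sample metadata: a file path or data frame with `sample_id`,
#'   `time_hours`, `group`.
#' @param config A [moo_config()].
#' @param probe_mapping Optional probe-to-gene table (`probe_id`,
#'   `gene_symbol`) applied before anything else.
#' @param q_max,fc_min,s0,input_scale Passed to [informative_gene_filter()].
#' @param t_last,null_replicates Passed to [scan_timepoints()].
#' @param out_dir If non-NULL, [write_report()] is called on the result.
#' @param verbose Log gene counts and stage progress to stderr.
#' @return An object of class `dnb_report`; see [write_report()] for the
#'   serialized fields. The full `dnb_scan_set` is attached as `$scans`.
#' @export
run_full <- function(expr, meta, config = moo_config(), probe_mapping = NULL,
                     q_max = 0.01, fc_min = 2, s0 = 0,
                     input_scale = "linear", t_last = NULL,
                     null_replicates = 1L, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  dataset <- stage("load", {
    if (is.character(expr)) expr <- read_delim_by_ext(expr)
    if (is.character(meta)) meta <- read_delim_by_ext(meta)
    if (!is.null(probe_mapping)) expr <- aggregate_probes(expr, probe_mapping)
    dnb_dataset(expr, meta)
  })
  say("loaded %d genes x %d time-points", n_genes(dataset), n_times(dataset))

  de <- stage("filter", informative_gene_filter(
    dataset, q_max = q_max, fc_min = fc_min, s0 = s0,
    input_scale = input_scale))
  say("%d informative gene(s) after DE + fold-change filtering",
      length(de$genes))
  if (length(de$genes) <= config$min_size) {
    stop("[filter] too few informative genes for a subset search",
         call. = FALSE)
  }
  filtered <- subset_genes(dataset, de$genes)

  normalized <- stage("normalize", normalize_to_controls(filtered))
  scans <- stage("scan", scan_timepoints(
    normalized, config = config, t_last = t_last,
    null_replicates = null_replicates))

  t_sel <- select_predisease(scans)
  scan <- scans[[which(vapply(scans, `[[`, numeric(1), "time_hours") == t_sel)]]
  best <- select_dnb(scan)
  ti <- scan$time_index
  bits <- best$bits[[1]]
  i_now <- composite_index(normalized, bits, ti)$index
  i_prev <- composite_index(normalized, bits, ti - 1)$index

  dnb_genes <- best$genes[[1]]
  edges <- dnb_edges(normalized, dnb_genes, ti)

  report <- structure(list(
    predisease_time_hours = t_sel,
    dnb_genes = dnb_genes,
    dnb_size = length(dnb_genes),
    escalation = i_now - i_prev,
    selection_distance = best$distance_to_ideal,
    objectives = c(f1 = best$f1, f2 = best$f2),
    per_time = tidy(scans)[, c("time_hours", "n_solutions", "wmw_p")],
    trajectories = scan$trajectories,
    selected_solution_id = best$solution_id,
    n_genes_input = n_genes(dataset),
    n_genes_informative = length(de$genes),
    edges = edges,
    scans = scans,
    de = de
  ), class = "dnb_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Pearson correlations among the biomarker genes at the selected time:
# one row per unordered pair, suitable for network viewers.
dnb_edges <- function(dataset, genes, ti) {
  idx <- match(genes, dataset$genes)
  m <- dataset$case[[ti]][idx, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(m)))
  r[is.na(r)] <- 0
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  tibble::tibble(gene_a = genes[pairs[, 1]],
                 gene_b = genes[pairs[, 2]],
                 r = r[pairs])
}

#' @export
print.dnb_report <- function(x, ...) {
  cat("<dnb_report>\n")
  cat(sprintf("  pre-disease time: %g h (WMW p = %.4g)\n",
              x$predisease_time_hours,
              x$per_time$wmw_p[x$per_time$time_hours == x$predisease_time_hours]))
  cat(sprintf("  biomarker: %d gene(s), escalation %.3f, distance to ideal %.4f\n",
              x$dnb_size, x$escalation, x$selection_distance))
  cat(sprintf("  genes: %s\n", paste(x$dnb_genes, collapse = ", ")))
  invisible(x)
}

#' One-row summary of a discovery run
#'
#' @param x A `dnb_report`.
#' @param ... Unused.
#' @return A tibble with the headline quantities of the run.
#' @method glance dnb_report
#' @export
glance.dnb_report <- function(x, ...) {
  tibble::tibble(
    predisease_time_hours = x$predisease_time_hours,
    dnb_size = x$dnb_size,
    escalation = x$escalation,
    selection_distance = x$selection_distance,
    wmw_p = x$per_time$wmw_p[x$per_time$time_hours == x$predisease_time_hours],
    n_genes_input = x$n_genes_input,
    n_genes_informative = x$n_genes_informative
  )
}

#' @method tidy dnb_report
#' @export
tidy.dnb_report <- function(x, ...) x$per_time

#' Write a discovery report to disk
#'
#' Emits three artifacts in `out_dir`: `report.json` (chosen time, per-time
#' p-values, biomarker gene list, escalation, and the composite-index
#' trajectories of the selected scan's solutions), `pareto.tsv` (one row per
#' Pareto solution at the chosen time) and `edges.tsv` (pairwise Pearson
#' correlations among biomarker genes at the chosen time). The JSON is
#' written with a fixed key order and fixed float formatting, so re-writing
#' the same report is byte-identical.
#'
#' @param report A `dnb_report` from [run_full()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "dnb_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir,
                                 call. = FALSE)
  payload <- list(
    predisease_time_hours = report$predisease_time_hours,
    dnb_genes = report$dnb_genes,
    dnb_size = report$dnb_size,
    escalation = report$escalation,
    selection_distance = unname(report$selection_distance),
    objectives = as.list(report$objectives),
    per_time = as.list(report$per_time),
    trajectories = as.list(report$trajectories),
    selected_solution_id = report$selected_solution_id,
    n_genes_input = report$n_genes_input,
    n_genes_informative = report$n_genes_informative
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(12),
                           pretty = TRUE)
  json_path <- file.path(out_dir, "report.json")
  writeLines(json, json_path)

  scan <- report$scans[[which(vapply(report$scans, `[[`, numeric(1),
                                     "time_hours") == report$predisease_time_hours)]]
  ptab <- scan$pareto
  ptab$genes <- vapply(ptab$genes, paste, character(1), collapse = ",")
  ptab$bits <- NULL
  pareto_path <- file.path(out_dir, "pareto.tsv")
  readr::write_tsv(ptab, pareto_path, progress = FALSE)

  edges_path <- file.path(out_dir, "edges.tsv")
  readr::write_tsv(report$edges, edges_path, progress = FALSE)
  invisible(c(report = json_path, pareto = pareto_path, edges = edges_path))
}

#' Read back the machine-readable part of a report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A list with the serialized report fields (tibbles restored for
#'   `per_time` and `trajectories`).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_time <- tibble::as_tibble(x$per_time)
  x$trajectories <- tibble::as_tibble(x$trajectories)
  x$dnb_genes <- as.character(x$dnb_genes)
  x
}
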