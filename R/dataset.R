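#' Time-course case/control expression dataset
#'
#' `dnb_dataset()` bundles a gene-by-sample expression table and its sample
#' metadata into the container used throughout the package: one expression
#' matrix per (time-point, group) cell, rows aligned to a single gene order.
#'
#' @param expr A data frame whose first column holds gene identifiers and
#'   whose remaining columns are numeric sample columns named by `sample_id`.
#' @param meta A data frame with columns `sample_id`, `time_hours` (numeric)
#'   and `group` (`"case"` or `"control"`) mapping every expression column.
#'
#' @details
#' Gene identifiers are opaque, case-sensitive strings. Time-points are
#' numeric hours so that "the previous time-point" is well defined by sort
#' order even on irregular sampling grids. Within a (time, group) cell,
#' sample columns keep their file order. Missing or non-numeric cells are
#' load-time errors naming the offending cell. Replicate-count requirements
#' (at least 3 case samples for correlation, at least 2 controls for
#' normalization) are enforced by the operations that need them, so that
#' small hand-built tables remain loadable for inspection.
#'
#' @return An object of class `dnb_dataset`: a list with elements
#'   `genes` (character), `times` (sorted numeric hours), `case` and
#'   `control` (lists of gene x sample matrices, one per time-point) and
#'   `normalized` (logical flag).
#' @seealso [read_expression_table()], [normalize_to_controls()],
#'   [generate_dataset()]
#' @export
#' @examples
#' expr <- data.frame(gene = c("g1", "g2"),
#'                    s1 = c(1, 2), s2 = c(2, 3), s3 = c(3, 4),
#'                    s4 = c(1.5, 2.5), s5 = c(2.5, 3.5), s6 = c(3.5, 4.5))
#' meta <- data.frame(sample_id = paste0("s", 1:6),
#'                    time_hours = 1,
#'                    group = rep(c("case", "control"), each = 3))
#' ds <- dnb_dataset(expr, meta)
#' ds
dnb_dataset <- function(expr, meta) {
  expr <- tibble::as_tibble(expr)
  meta <- tibble::as_tibble(meta)

  required <- c("sample_id", "time_hours", "group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    dups <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicate sample_id in metadata: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  if (!all(meta$group %in% c("case", "control"))) {
    bad <- unique(meta$group[!meta$group %in% c("case", "control")])
    stop("group must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(meta$time_hours) || anyNA(meta$time_hours)) {
    stop("time_hours must be numeric and complete", call. = FALSE)
  }

  genes <- as.character(expr[[1]])
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    stop("duplicate gene identifiers: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- names(expr)[-1]
  unmapped <- setdiff(sample_ids, meta$sample_id)
  if (length(unmapped) > 0) {
    stop("sample column(s) absent from metadata: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  vals <- expr[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col) || is.factor(col)) {
      conv <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(conv) & !is.na(as.character(col)))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in column '%s', gene '%s'",
                     sample_ids[j], genes[bad[1]]), call. = FALSE)
      }
      col <- conv
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1]
      stop(sprintf("missing value in column '%s', gene '%s'",
                   sample_ids[j], genes[bad]), call. = FALSE)
    }
    vals[[j]] <- as.numeric(col)
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes

  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  times <- sort(unique(meta$time_hours))

  split_group <- function(group) {
    lapply(times, function(t) {
      keep <- meta$time_hours == t & meta$group == group
      m <- mat[, keep, drop = FALSE]
      colnames(m) <- meta$sample_id[keep]
      m
    })
  }

  out <- structure(
    list(genes = genes,
         times = times,
         case = split_group("case"),
         control = split_group("control"),
         normalized = FALSE),
    class = "dnb_dataset"
  )
  out
}

#' Read a time-course expression dataset from delimited text files
#'
#' Reads the canonical two-table form: an expression table (first column gene
#' identifiers, one column per sample) and a sample-metadata table
#' (`sample_id`, `time_hours`, `group`). The delimiter is taken from the file
#' extension: `.tsv` reads tab-separated, `.csv` comma-separated; no content
#' sniffing is done so reads are bit-reproducible.
#'
#' @param expr_path Path to the expression table.
#' @param meta_path Path to the metadata table.
#' @return A [dnb_dataset].
#' @export
read_expression_table <- function(expr_path, meta_path) {
  expr <- read_delim_by_ext(expr_path)
  meta <- read_delim_by_ext(meta_path)
  dnb_dataset(expr, meta)
}

read_delim_by_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    stop("unrecognized extension '", ext, "' (use .tsv or .csv)", call. = FALSE)
  }
}

#' Write a dataset back to the two-table TSV form
#'
#' Inverse of [read_expression_table()]: emits `expression.tsv` and
#' `metadata.tsv` in `out_dir`, with case columns before control columns at
#' each time-point.
#'
#' @param dataset A [dnb_dataset].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "dnb_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mats <- list()
  meta <- list()
  for (ti in seq_along(dataset$times)) {
    for (grp in c("case", "control")) {
      m <- dataset[[grp]][[ti]]
      if (is.null(m) || ncol(m) == 0) next
      mats[[length(mats) + 1]] <- m
      meta[[length(meta) + 1]] <- tibble::tibble(
        sample_id = colnames(m),
        time_hours = dataset$times[ti],
        group = grp
      )
    }
  }
  expr <- tibble::as_tibble(as.data.frame(do.call(cbind, mats)))
  expr <- dplyr::bind_cols(tibble::tibble(gene = dataset$genes), expr)
  meta <- dplyr::bind_rows(meta)
  expr_path <- file.path(out_dir, "expression.tsv")
  meta_path <- file.path(out_dir, "metadata.tsv")
  readr::write_tsv(expr, expr_path, progress = FALSE)
  readr::write_tsv(meta, meta_path, progress = FALSE)
  invisible(c(expression = expr_path, metadata = meta_path))
}

#' @export
print.dnb_dataset <- function(x, ...) {
  k_case <- vapply(x$case, ncol, integer(1))
  k_ctrl <- vapply(x$control, ncol, integer(1))
  cat(sprintf("<dnb_dataset> %d genes, %d time-points (%s h)%s\n",
              length(x$genes), length(x$times),
              paste(x$times, collapse = ", "),
              if (x$normalized) ", control-normalized" else ""))
  cat(sprintf("  case replicates:    %s\n", paste(k_case, collapse = ", ")))
  cat(sprintf("  control replicates: %s\n", paste(k_ctrl, collapse = ", ")))
  invisible(x)
}

#' Number of genes, time-points, and replicates
#'
#' Small accessors used throughout; counts always reflect the source files.
#'
#' @param dataset A [dnb_dataset].
#' @return `n_genes()`/`n_times()` return single integers; `n_replicates()`
#'   a tibble with per-time case and control counts.
#' @export
n_genes <- function(dataset) length(dataset$genes)

#' @rdname n_genes
#' @export
n_times <- function(dataset) length(dataset$times)

#' @rdname n_genes
#' @export
n_replicates <- function(dataset) {
  tibble::tibble(
    time_hours = dataset$times,
    k_case = vapply(dataset$case, ncol, integer(1)),
    k_control = vapply(dataset$control, ncol, integer(1))
  )
}

#' Restrict a dataset to a gene subset
#'
#' @param dataset A [dnb_dataset].
#' @param genes Character vector of gene identifiers to keep (order taken
#'   from the dataset, not from `genes`).
#' @return A [dnb_dataset] over the requested genes.
#' @export
subset_genes <- function(dataset, genes) {
  stopifnot(inherits(dataset, "dnb_dataset"))
  missing <- setdiff(genes, dataset$genes)
  if (length(missing) > 0) {
    stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  keep <- dataset$genes %in% genes
  dataset$genes <- dataset$genes[keep]
  dataset$case <- lapply(dataset$case, function(m) m[keep, , drop = FALSE])
  dataset$control <- lapply(dataset$control, function(m) m[keep, , drop = FALSE])
  dataset
}

#' @method as_tibble dnb_dataset
#' @export
as_tibble.dnb_dataset <- function(x, ...) {
  rows <- list()
  for (ti in seq_along(x$times)) {
    for (grp in c("case", "control")) {
      m <- x[[grp]][[ti]]
      if (is.null(m) || ncol(m) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = rep(x$genes, times = ncol(m)),
        sample_id = rep(colnames(m), each = nrow(m)),
        time_hours = x$times[ti],
        group = grp,
        value = as.vector(m)
      )
    }
  }
  dplyr::bind_rows(rows)
}
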