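#' Validate a long-form accuracy table
#'
#' An accuracy grid is the package's central tabular currency: one row per
#' combination of training sample size and scan time per participant, holding
#' the (repetition-averaged) prediction accuracy of one phenotype in one
#' dataset. A single tibble may stack many grids, distinguished by the
#' `dataset`, `phenotype` and `metric` columns.
#'
#' @param data A data frame with columns `dataset`, `phenotype`, `metric`
#'   (`"pearson"` or `"cod"`), `n_train` (positive integer participants),
#'   `t_min` (positive minutes), `accuracy` and optionally `n_reps`
#'   (defaults to 1).
#'
#' @return A tibble with the validated columns in canonical order.
#' @export
#' @examples
#' as_accuracy_grid(data.frame(
#'   dataset = "demo", phenotype = "cognition", metric = "pearson",
#'   n_train = c(100, 100, 200, 200), t_min = c(10, 20, 10, 20),
#'   accuracy = c(0.21, 0.25, 0.27, 0.31)
#' ))
as_accuracy_grid <- function(data) {
  required <- c("dataset", "phenotype", "metric", "n_train", "t_min",
                "accuracy")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Accuracy table is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  data <- tibble::as_tibble(data)
  if (!"n_reps" %in% names(data)) {
    data$n_reps <- 1L
  }
  data <- data[, c(required, "n_reps")]

  for (col in c("n_train", "t_min", "accuracy", "n_reps")) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))))
      abort(sprintf("Column `%s` must be numeric (first offending row: %d).",
                    col, if (length(bad)) bad[1] else 1L))
    }
  }
  if (anyNA(data$accuracy) || any(!is.finite(data$accuracy))) {
    abort("Column `accuracy` contains missing or non-finite values.")
  }
  if (any(data$n_train <= 0) || any(data$t_min <= 0)) {
    abort("`n_train` and `t_min` must be strictly positive.")
  }
  bad_metric <- setdiff(unique(data$metric), c("pearson", "cod"))
  if (length(bad_metric) > 0) {
    abort(paste0("Unknown metric value(s): ",
                 paste(bad_metric, collapse = ", "),
                 ". Expected \"pearson\" or \"cod\"."))
  }
  pearson <- data$metric == "pearson"
  if (any(abs(data$accuracy[pearson]) > 1)) {
    abort("Pearson accuracies must lie in [-1, 1].")
  }
  dup <- duplicated(data[, c("dataset", "phenotype", "metric",
                             "n_train", "t_min")])
  if (any(dup)) {
    abort(sprintf(
      "Duplicate (n_train, t_min) cell(s) within a grid (first at row %d).",
      which(dup)[1]))
  }
  data
}

grid_groups <- function(data) {
  dplyr::group_by(data, .data$dataset, .data$phenotype, .data$metric)
}

#' Read or write accuracy tables as delimited text
#'
#' Long-form tables with header `dataset, phenotype, metric, n_train, t_min,
#' accuracy[, n_reps]`. The delimiter (comma or tab) is auto-detected on
#' reading; writing uses the delimiter implied by the file extension
#' (`.tsv` for tab, comma otherwise).
#'
#' @param path File path.
#' @param delim Optional delimiter override (`","` or `"\t"`).
#'
#' @return `read_accuracy_table()` returns a validated accuracy tibble;
#'   `write_accuracy_table()` returns `path` invisibly.
#' @export
read_accuracy_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed cell at line %d of %s: %s",
                  probs$row[1] + 1L, path, probs$expected[1]))
  }
  for (col in intersect(c("n_train", "t_min", "accuracy", "n_reps"),
                        names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value in column `%s` at line %d of %s.",
                    col, bad[1] + 1L, path))
    }
    raw[[col]] <- parsed
  }
  as_accuracy_grid(raw)
}

#' @rdname read_accuracy_table
#' @param data An accuracy table (validated on the way out).
#' @export
write_accuracy_table <- function(data, path, delim = NULL) {
  data <- as_accuracy_grid(data)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  }
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Filter phenotype grids by predictability
#'
#' Screens accuracy grids before scaling-law fitting. Two rules are
#' supported: `"max_gt"` keeps phenotypes whose best cell exceeds a
#' threshold accuracy (the primary screen for well-predicted phenotypes);
#' `"positive_pct"` keeps phenotypes whose accuracy is positive in at least
#' a given share of (N, T) cells (the looser screen).
#'
#' @param data An accuracy table (possibly many phenotypes).
#' @param rule `"max_gt"` or `"positive_pct"`.
#' @param threshold Accuracy threshold for `"max_gt"` (default 0.1).
#' @param min_positive Minimum fraction of positive cells for
#'   `"positive_pct"` (default 0.9).
#'
#' @return The rows of `data` belonging to phenotypes passing the rule.
#' @export
filter_phenotypes <- function(data, rule = c("max_gt", "positive_pct"),
                              threshold = 0.1, min_positive = 0.9) {
  rule <- rlang::arg_match(rule)
  data <- as_accuracy_grid(data)
  keep <- dplyr::summarise(
    grid_groups(data),
    .pass = if (rule == "max_gt") {
      max(.data$accuracy) > threshold
    } else {
      mean(.data$accuracy > 0) >= min_positive
    },
    .groups = "drop"
  )
  keep <- keep[keep$.pass, c("dataset", "phenotype", "metric")]
  dplyr::semi_join(data, keep, by = c("dataset", "phenotype", "metric"))
}
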