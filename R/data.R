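#' Assemble labeled and unlabeled data into a stacked IPD dataset
#'
#' All inference-on-predicted-data methods operate on a *stacked* dataset: a
#' block of labeled rows carrying the observed outcome, the prediction, and
#' the features, followed by a block of unlabeled rows carrying the
#' prediction and features only.  Data may be supplied in one of two modes:
#'
#' * **stacked**: a single table plus `label`, the name of a set-indicator
#'   column distinguishing labeled from unlabeled rows;
#' * **separate**: `data` holds the labeled rows and `unlabeled_data` the
#'   unlabeled rows.
#'
#' Exactly one of `label` / `unlabeled_data` must be given.  Only columns
#' referenced by the formula (or by `label`) are retained.
#'
#' The set-indicator column may be logical, numeric in \{0, 1\} (1 =
#' labeled), or character/factor with values such as `"labeled"` /
#' `"unlabeled"` (also accepted, case-insensitively: `"true"`/`"false"`,
#' `"yes"`/`"no"`, `"label"`, `"unlabelled"`).  Rows labeled `"training"`
#' (or `"train"`) are dropped with a message: such rows are used upstream to
#' fit the prediction algorithm and take no part in downstream inference.
#' Any other value is an error.
#'
#' Missing values in referenced feature or prediction columns are an error
#' (silent row-dropping would change the estimand), as is a missing outcome
#' on a labeled row.  An outcome column present on unlabeled rows is
#' retained but ignored by every method except the [benchmark_fit()] oracle.
#'
#' @param formula An [ipd_formula()] (or anything coercible to one).
#' @param data A data frame: the stacked table, or the labeled table in
#'   separate mode.
#' @param unlabeled_data Optional data frame of unlabeled rows.
#' @param label Optional name of the set-indicator column in `data`.
#'
#' @return An object of class `"ipd_data"`: a list with the outcome,
#'   prediction and feature columns stored labeled-block-first, the counts
#'   `n_labeled` / `n_unlabeled`, and the parsed formula.
#'
#' @examples
#' lab <- data.frame(Y = rnorm(5), f = rnorm(5), X1 = rnorm(5))
#' unl <- data.frame(f = rnorm(8), X1 = rnorm(8))
#' ds <- ipd_data(Y - f ~ X1, data = lab, unlabeled_data = unl)
#' ds$n_labeled
#' @export
ipd_data <- function(formula, data, unlabeled_data = NULL, label = NULL) {
  formula <- ipd_formula(formula)
  if (is.null(label) == is.null(unlabeled_data)) {
    stop("supply exactly one of `label` (stacked mode) or ",
         "`unlabeled_data` (separate mode).", call. = FALSE)
  }
  data <- as.data.frame(data)

  if (!is.null(label)) {
    if (!is.character(label) || length(label) != 1L) {
      stop("`label` must be a single column name.", call. = FALSE)
    }
    if (!label %in% names(data)) {
      stop("label column `", label, "` not found in `data`.", call. = FALSE)
    }
    set <- interpret_set_indicator(data[[label]], label)
    n_drop <- sum(is.na(set))
    if (n_drop > 0L) {
      message("dropping ", n_drop,
              " training row(s) not part of the labeled/unlabeled split")
      data <- data[!is.na(set), , drop = FALSE]
      set <- set[!is.na(set)]
    }
    labeled <- data[set, , drop = FALSE]
    unlabeled <- data[!set, , drop = FALSE]
  } else {
    labeled <- data
    unlabeled <- as.data.frame(unlabeled_data)
  }

  need_lab <- c(formula$outcome, formula$prediction, formula$features)
  need_unl <- c(formula$prediction, formula$features)
  check_columns(labeled, need_lab, "labeled data")
  check_columns(unlabeled, need_unl, "unlabeled data")

  n <- nrow(labeled)
  N <- nrow(unlabeled)
  if (n < 1L) {
    stop("at least one labeled row is required.", call. = FALSE)
  }

  outcome_l <- as_numeric_column(labeled[[formula$outcome]], formula$outcome)
  if (anyNA(outcome_l)) {
    stop("missing outcome value(s) on labeled row(s).", call. = FALSE)
  }
  # true outcomes on unlabeled rows (simulated data) are kept for the oracle
  if (formula$outcome %in% names(unlabeled)) {
    outcome_u <- as_numeric_column(unlabeled[[formula$outcome]],
                                   formula$outcome)
  } else {
    outcome_u <- rep(NA_real_, N)
  }

  prediction <- c(
    as_numeric_column(labeled[[formula$prediction]], formula$prediction),
    if (N > 0L) as_numeric_column(unlabeled[[formula$prediction]],
                                  formula$prediction)
  )
  if (anyNA(prediction)) {
    stop("missing value(s) in prediction column `", formula$prediction,
         "`; no imputation is performed.", call. = FALSE)
  }

  p <- length(formula$features)
  features <- matrix(numeric(0), nrow = n + N, ncol = p,
                     dimnames = list(NULL, formula$features))
  for (v in formula$features) {
    col <- c(as_numeric_column(labeled[[v]], v),
             if (N > 0L) as_numeric_column(unlabeled[[v]], v))
    if (anyNA(col)) {
      stop("missing value(s) in feature column `", v,
           "`; no imputation is performed.", call. = FALSE)
    }
    features[, v] <- col
  }

  structure(
    list(
      outcome = c(outcome_l, outcome_u),
      prediction = prediction,
      features = features,
      set_labeled = c(rep(TRUE, n), rep(FALSE, N)),
      n_labeled = n,
      n_unlabeled = N,
      formula = formula
    ),
    class = "ipd_data"
  )
}

#' @export
print.ipd_data <- function(x, ...) {
  cat("<ipd_data> ", format(x$formula), "\n", sep = "")
  cat("  labeled rows:   ", x$n_labeled, "\n", sep = "")
  cat("  unlabeled rows: ", x$n_unlabeled,
      if (x$n_unlabeled > 0L && !anyNA(x$outcome[!x$set_labeled]))
        "  (true outcomes present: oracle benchmark available)",
      "\n", sep = "")
  invisible(x)
}

interpret_set_indicator <- function(v, label) {
  if (is.logical(v)) {
    if (anyNA(v)) stop("missing values in label column `", label, "`.",
                       call. = FALSE)
    return(v)
  }
  if (is.numeric(v)) {
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      stop("numeric label column `", label, "` must contain only 0/1.",
           call. = FALSE)
    }
    return(v == 1)
  }
  v <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "labeled", "labelled", "label", "yes")] <- TRUE
  out[v %in% c("0", "false", "unlabeled", "unlabelled", "no")] <- FALSE
  is_train <- v %in% c("training", "train")
  bad <- !is_train & is.na(out)
  if (any(bad)) {
    stop("unrecognized value(s) in label column `", label, "`: ",
         paste0("\"", unique(v[bad]), "\"", collapse = ", "), ".",
         call. = FALSE)
  }
  out[is_train] <- NA # marked for exclusion by the caller
  out
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("column(s) ", paste0("`", missing, "`", collapse = ", "),
         " not found in ", what, ".", call. = FALSE)
  }
  invisible(TRUE)
}

as_numeric_column <- function(v, name) {
  if (!is.numeric(v) && !is.logical(v)) {
    stop("column `", name, "` must be numeric.", call. = FALSE)
  }
  as.numeric(v)
}

#' Build a design matrix from an IPD dataset
#'
#' Returns the model matrix for the requested block of rows: an intercept
#' column (when the formula carries one) followed by the feature columns in
#' formula order.
#'
#' @param ds An [ipd_data()] object.
#' @param subset Which rows: `"labeled"`, `"unlabeled"`, or `"all"`.
#'
#' @return A numeric matrix with named columns.
#' @export
build_design <- function(ds, subset = c("labeled", "unlabeled", "all")) {
  stopifnot(inherits(ds, "ipd_data"))
  subset <- match.arg(subset)
  keep <- switch(subset,
    labeled = ds$set_labeled,
    unlabeled = !ds$set_labeled,
    all = rep(TRUE, length(ds$set_labeled))
  )
  if (!any(keep)) {
    stop("no ", subset, " rows available to build a design matrix.",
         call. = FALSE)
  }
  X <- ds$features[keep, , drop = FALSE]
  if (ds$formula$intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (ncol(X) == 0L) {
    stop("empty design: the formula has no intercept and no features.",
         call. = FALSE)
  }
  X
}

#' Read a delimited data file for IPD analysis
#'
#' Thin reader for header-bearing CSV/TSV tables.  The delimiter is inferred
#' from the file extension (`.csv` is comma-separated, `.tsv`/`.tab`/`.txt`
#' tab-separated) and can be overridden.
#'
#' @param path Path to the file.
#' @param delim Optional single-character delimiter overriding the inference.
#'
#' @return A data frame.
#' @export
read_ipd_data <- function(path, delim = NULL) {
  if (is.null(delim)) {
    ext <- tolower(tools::file_ext(path))
    delim <- switch(ext,
      csv = ",",
      tsv = "\t",
      tab = "\t",
      txt = "\t",
      stop("cannot infer delimiter from extension `.", ext,
           "`; pass `delim` explicitly.", call. = FALSE)
    )
  }
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an IPD analysis configuration file
#'
#' Reads a YAML (or flat `key: value`) file describing a complete [ipd()]
#' call: recognized keys are `formula`, `data`, `unlabeled_data`, `label`,
#' `method`, `model`, `alpha`, `q`, `seed`, and `nboot`.  Paths given for
#' `data` / `unlabeled_data` are loaded with [read_ipd_data()] relative to
#' the configuration file's directory.
#'
#' @param path Path to the configuration file.
#' @return A named list of arguments suitable for `do.call(ipd, ...)`.
#' @seealso [ipd_from_config()]
#' @export
read_ipd_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read configuration files.",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  allowed <- c("formula", "data", "unlabeled_data", "label", "method",
               "model", "alpha", "q", "seed", "nboot")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0("`", unknown, "`", collapse = ", "), ".", call. = FALSE)
  }
  for (k in c("data", "unlabeled_data")) {
    if (!is.null(cfg[[k]])) {
      p <- cfg[[k]]
      if (!file.exists(p)) p <- file.path(dirname(path), cfg[[k]])
      cfg[[k]] <- read_ipd_data(p)
    }
  }
  cfg
}

#' Run an IPD analysis described by a configuration file
#'
#' @inheritParams read_ipd_config
#' @return An [ipd()] fit.
#' @export
ipd_from_config <- function(path) {
  do.call(ipd, read_ipd_config(path))
}
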