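#' Parse an inference-on-predicted-data model formula
#'
#' Models for inference on predicted data (IPD) are specified with a formula
#' of the form `Y - f ~ X1 + X2 + ...`, where `Y` names the observed outcome
#' column (available on labeled rows only), `f` names the predicted-outcome
#' column (available on all rows), and the right-hand side lists the feature
#' columns of interest.  The intercept-only form `Y - f ~ 1` is used for the
#' scalar estimands (mean, quantile).
#'
#' Two dialects are accepted and treated identically: the conventional R form
#' with `~`, and the rendered form `Y - f = X1 + X2` with `=` as separator
#' (a Unicode minus sign on the left-hand side is also normalized).
#'
#' Features must be plain numeric columns: interactions, transformations, and
#' factor expansion are not supported, and duplicate feature names are an
#' error.
#'
#' @param formula A formula or a single character string, e.g.
#'   `"Y - f ~ X1 + X2"`.
#'
#' @return An object of class `"ipd_formula"`: a list with elements
#'   `outcome`, `prediction` (column names), `features` (character vector,
#'   possibly empty), and `intercept` (logical).
#'
#' @examples
#' ipd_formula(Y - f ~ X1 + X2)
#' ipd_formula("Y - f ~ 1")
#' @export
ipd_formula <- function(formula) {
  if (inherits(formula, "ipd_formula")) {
    return(formula)
  }
  if (inherits(formula, "formula")) {
    spec <- paste(deparse(formula), collapse = " ")
  } else if (is.character(formula) && length(formula) == 1L) {
    spec <- formula
  } else {
    stop("`formula` must be a formula or a single character string.",
         call. = FALSE)
  }

  # normalize the rendered dialect: unicode minus and `=` as separator
  spec <- gsub("−", "-", spec)
  if (!grepl("~", spec, fixed = TRUE)) {
    spec <- sub("=", "~", spec, fixed = TRUE)
  }

  fml <- tryCatch(
    stats::as.formula(spec, env = baseenv()),
    error = function(e) {
      stop("could not parse formula `", spec, "`: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(fml) != 3L) {
    stop("formula must be two-sided, with left-hand side `<outcome> - ",
         "<prediction>`; got `", spec, "`.", call. = FALSE)
  }

  lhs <- fml[[2L]]
  lhs_ok <- is.call(lhs) && identical(lhs[[1L]], as.name("-")) &&
    length(lhs) == 3L && is.name(lhs[[2L]]) && is.name(lhs[[3L]])
  if (!lhs_ok) {
    stop("left-hand side must be of the form `<outcome> - <prediction>` ",
         "(exactly two names); got `", paste(deparse(lhs), collapse = ""),
         "`.", call. = FALSE)
  }
  outcome <- as.character(lhs[[2L]])
  prediction <- as.character(lhs[[3L]])
  if (identical(outcome, prediction)) {
    stop("outcome and prediction must name different columns (both are `",
         outcome, "`).", call. = FALSE)
  }

  rhs <- fml
  rhs[[2L]] <- NULL # one-sided formula for terms()
  tt <- stats::terms(rhs)
  intercept <- attr(tt, "intercept") == 1L
  # walk the raw `+` tree ourselves: terms() silently deduplicates, and a
  # repeated feature should be reported, not absorbed
  features <- flatten_sum(fml[[3L]])
  features <- features[!features %in% c("0", "1")]

  bad <- features[!grepl("^[.A-Za-z][._A-Za-z0-9]*$", features)]
  if (length(bad)) {
    stop("features must be plain column names (no interactions or ",
         "transformations): offending term(s) ",
         paste0("`", bad, "`", collapse = ", "), ".", call. = FALSE)
  }
  if (anyDuplicated(features)) {
    dup <- unique(features[duplicated(features)])
    stop("duplicate feature(s) in formula: ",
         paste0("`", dup, "`", collapse = ", "), ".", call. = FALSE)
  }
  if (any(c(outcome, prediction) %in% features)) {
    stop("outcome/prediction names must not reappear among the features.",
         call. = FALSE)
  }

  structure(
    list(outcome = outcome, prediction = prediction,
         features = as.character(features), intercept = intercept),
    class = "ipd_formula"
  )
}

flatten_sum <- function(expr) {
  if (is.call(expr) && identical(expr[[1L]], as.name("+")) &&
      length(expr) == 3L) {
    return(c(flatten_sum(expr[[2L]]), flatten_sum(expr[[3L]])))
  }
  if (is.call(expr) && identical(expr[[1L]], as.name("-")) &&
      length(expr) == 3L && identical(expr[[3L]], 1)) {
    return(flatten_sum(expr[[2L]])) # `- 1` only toggles the intercept
  }
  paste(deparse(expr), collapse = "")
}

#' @export
format.ipd_formula <- function(x, ...) {
  rhs <- if (length(x$features)) paste(x$features, collapse = " + ") else "1"
  if (!x$intercept) rhs <- paste(rhs, "- 1")
  paste0(x$outcome, " - ", x$prediction, " ~ ", rhs)
}

#' @export
print.ipd_formula <- function(x, ...) {
  cat("<ipd_formula> ", format(x), "\n", sep = "")
  invisible(x)
}
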