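#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @export
print.ipd_fit <- function(x, digits = 4, ...) {
  cat("IPD fit: method = ", x$method, ", estimand = ",
      format_estimand(x$estimand), "\n\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

format_estimand <- function(est) {
  if (est$model == "quantile") paste0("quantile(q = ", est$q, ")") else
    est$model
}

#' Summarize an IPD fit
#'
#' Detailed view of a fit: the coefficient table with sandwich standard
#' errors and confidence limits, plus the sample sizes and method metadata.
#' The [print()] method gives the abbreviated version (coefficients only).
#'
#' @param object An `ipd_fit`.
#' @param ... Unused.
#' @return An object of class `"summary.ipd_fit"`.
#' @export
summary.ipd_fit <- function(object, ...) {
  tab <- cbind(
    Estimate = object$coefficients,
    `Std. Error` = object$std_errors,
    `Lower` = object$ci_lower,
    `Upper` = object$ci_upper
  )
  structure(
    list(method = object$method,
         estimand = format_estimand(object$estimand),
         coefficients = tab, alpha = object$alpha,
         n_used = object$n_used, seed = object$seed,
         converged = object$converged,
         formula = object$formula),
    class = "summary.ipd_fit"
  )
}

#' @export
print.summary.ipd_fit <- function(x, digits = 4, ...) {
  cat("Inference on predicted data\n\n")
  cat("Formula:  ", format(x$formula), "\n", sep = "")
  cat("Method:   ", x$method, "\n", sep = "")
  cat("Estimand: ", x$estimand, "\n", sep = "")
  cat("Rows:     ", x$n_used["labeled"], " labeled, ",
      x$n_used["unlabeled"], " unlabeled\n", sep = "")
  if (!is.null(x$seed)) cat("Seed:     ", x$seed, "\n", sep = "")
  cat("\nCoefficients (", format(100 * (1 - x$alpha)),
      "% confidence limits):\n", sep = "")
  print(round(x$coefficients, digits))
  if (!isTRUE(x$converged)) cat("\nWarning: fit did not fully converge.\n")
  invisible(x)
}

#' Tidy an IPD fit into a coefficient table
#'
#' @param x An `ipd_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `method`, `estimand`.
#' @method tidy ipd_fit
#' @export
tidy.ipd_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    conf.low = unname(x$ci_lower),
    conf.high = unname(x$ci_upper),
    method = x$method,
    estimand = format_estimand(x$estimand)
  )
}

#' One-row summary of an IPD fit
#'
#' @param x An `ipd_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the method, estimand, sample sizes, alpha,
#'   convergence flag, and a digest of the tuning intermediates (lambda /
#'   omega / bootstrap replicates, where applicable).
#' @method glance ipd_fit
#' @export
glance.ipd_fit <- function(x, ...) {
  im <- x$intermediates
  tibble::tibble(
    method = x$method,
    estimand = format_estimand(x$estimand),
    n_labeled = unname(x$n_used["labeled"]),
    n_unlabeled = unname(x$n_used["unlabeled"]),
    alpha = x$alpha,
    converged = x$converged,
    lambda = if (!is.null(im$lam)) im$lam else NA_real_,
    omega = if (!is.null(im$omega)) {
      paste(signif(im$omega, 3), collapse = ",")
    } else {
      NA_character_
    },
    nboot = if (!is.null(im$nboot)) im$nboot else NA_integer_
  )
}

#' Augment data with fitted values and residuals from an IPD fit
#'
#' For the regression estimands the fitted value is the linear predictor
#' (`ols`) or fitted probability (`logistic`) on every row; for the scalar
#' estimands it is the estimate itself.  Residuals `Y - fitted` are defined
#' on labeled rows only and are `NA` elsewhere (there is no truth to
#' subtract on unlabeled rows).
#'
#' @param x An `ipd_fit`.
#' @param data Optional table to augment; defaults to the data the fit was
#'   built from.  Must contain the formula's feature columns (and the
#'   outcome column for residuals on labeled rows).
#' @param ... Unused.
#' @return A tibble: the referenced columns plus `.fitted` and `.resid`.
#' @method augment ipd_fit
#' @export
augment.ipd_fit <- function(x, data = NULL, ...) {
  est <- x$estimand
  if (is.null(data)) {
    ds <- x$data
    out <- data.frame(ds$features)
    out[[x$formula$prediction]] <- ds$prediction
    out[[x$formula$outcome]] <- ds$outcome
    labeled <- ds$set_labeled
    feats <- ds$features
  } else {
    out <- as.data.frame(data)
    check_columns(out, x$formula$features, "data")
    labeled <- if (x$formula$outcome %in% names(out)) {
      !is.na(out[[x$formula$outcome]])
    } else {
      rep(FALSE, nrow(out))
    }
    feats <- as.matrix(out[, x$formula$features, drop = FALSE])
  }

  if (est$model %in% c("mean", "quantile")) {
    fitted <- rep(unname(x$coefficients[1]), nrow(out))
  } else {
    X <- if (x$formula$intercept) cbind(`(Intercept)` = 1, feats) else feats
    eta <- drop(X %*% x$coefficients)
    fitted <- if (est$model == "logistic") stats::plogis(eta) else eta
  }
  resid <- rep(NA_real_, nrow(out))
  if (x$formula$outcome %in% names(out)) {
    yy <- out[[x$formula$outcome]]
    resid[labeled] <- yy[labeled] - fitted[labeled]
  }
  out$.fitted <- fitted
  out$.resid <- resid
  tibble::as_tibble(out)
}

#' Dump an IPD fit to JSON
#'
#' Machine-readable export of the fit: coefficient table, alpha, sample
#' sizes, method metadata, and tuning intermediates.
#'
#' @param fit An `ipd_fit`.
#' @param path Optional file to write; if `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
ipd_fit_json <- function(fit, path = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the `jsonlite` package is required for JSON export.",
         call. = FALSE)
  }
  im <- fit$intermediates
  payload <- list(
    method = fit$method,
    estimand = format_estimand(fit$estimand),
    formula = format(fit$formula),
    alpha = fit$alpha,
    n_labeled = unname(fit$n_used["labeled"]),
    n_unlabeled = unname(fit$n_used["unlabeled"]),
    coefficients = as.data.frame(tidy(fit))[, 1:5],
    lambda = im$lam,
    omega = unname(im$omega),
    nboot = im$nboot,
    seed = fit$seed,
    converged = fit$converged
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(json)
}
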