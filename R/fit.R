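# Internal constructor shared by every method and benchmark: packages the
# point estimate, sandwich pieces, and normal-approximation interval into
# the glm-style fit object the reporting layer consumes.
new_ipd_fit <- function(method, estimand, coefficients, vcov, alpha, n_used,
                        ds, intermediates = list(), seed = NULL,
                        converged = TRUE, call = sys.call(-1)) {
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- names(coefficients)
  z <- stats::qnorm(1 - alpha / 2)
  fit <- structure(
    list(
      method = method,
      estimand = estimand,
      coefficients = coefficients,
      std_errors = se,
      vcov = vcov,
      ci_lower = coefficients - z * se,
      ci_upper = coefficients + z * se,
      alpha = alpha,
      n_used = n_used,
      intermediates = intermediates,
      formula = ds$formula,
      data = ds,
      seed = seed,
      converged = converged,
      call = call
    ),
    class = "ipd_fit"
  )
  fit
}

#' @export
coef.ipd_fit <- function(object, ...) object$coefficients

#' @export
vcov.ipd_fit <- function(object, ...) object$vcov

#' Confidence intervals for an IPD fit
#'
#' Normal-approximation two-sided intervals, `estimate +/- z(1 - alpha/2) *
#' SE`.  The default level is the one the fit was constructed with.
#'
#' @param object An `ipd_fit`.
#' @param parm Coefficients to include (names or indices); all by default.
#' @param level Confidence level in (0, 1), i.e. `1 - alpha`.
#' @param ... Unused.
#'
#' @return A two-column matrix of lower and upper limits.
#' @export
confint.ipd_fit <- function(object, parm = NULL,
                            level = 1 - object$alpha, ...) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("`level` must be a single number strictly inside (0, 1).",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(
    object$coefficients - z * object$std_errors,
    object$coefficients + z * object$std_errors
  )
  pct <- format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                trim = TRUE, digits = 5)
  dimnames(ci) <- list(names(object$coefficients), paste(pct, "%"))
  if (is.null(parm)) ci else ci[parm, , drop = FALSE]
}
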