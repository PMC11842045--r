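#' Fit the outcome-prediction relationship model
#'
#' The PostPI corrections rest on a *relationship model*: a regression of
#' the true outcome on its prediction, fit on the labeled rows, from which
#' pseudo-outcomes resembling the unobserved truth can be simulated.
#'
#' * Continuous outcomes: ordinary least squares of `Y` on `f`, with the
#'   residual standard deviation as the pseudo-outcome noise scale.
#' * Binary outcomes: a logistic calibration of `Y` on `f`; when the
#'   predictions are themselves 0/1 classes this reproduces the
#'   class-conditional frequencies `P(Y = 1 | f)` exactly, and when they
#'   are probabilities it acts as a one-dimensional recalibration.
#'
#' @param ds An [ipd_data()] object (only the labeled block is used).
#' @param binary Fit the binary-outcome calibration instead of least
#'   squares?
#'
#' @return An object of class `"ipd_relationship"` with elements
#'   `intercept`, `slope`, `residual_scale` (continuous; `NA` for binary),
#'   `binary`, `vcov` (coefficient covariance), and `simulate(f, n)`, a
#'   function drawing pseudo-outcomes at new predictions.
#' @export
fit_relationship <- function(ds, binary = FALSE) {
  stopifnot(inherits(ds, "ipd_data"))
  y <- ds$outcome[ds$set_labeled]
  f <- ds$prediction[ds$set_labeled]
  fit_relationship_yf(y, f, binary)
}

fit_relationship_yf <- function(y, f, binary = FALSE) {
  if (length(y) < 3L) {
    stop("at least 3 labeled rows are needed to fit the relationship ",
         "model.", call. = FALSE)
  }
  if (stats::var(f) <= .Machine$double.eps) {
    stop("degenerate predictor: the predictions are constant on the ",
         "labeled rows, so no outcome-prediction relationship can be ",
         "estimated.", call. = FALSE)
  }

  if (binary) {
    if (!all(y %in% c(0, 1))) {
      stop("binary relationship model requires a 0/1-coded outcome.",
           call. = FALSE)
    }
    fit <- suppressWarnings(
      stats::glm(y ~ f, family = stats::binomial())
    )
    cf <- stats::coef(fit)
    sim <- function(fnew) {
      pr <- stats::plogis(cf[1] + cf[2] * fnew)
      stats::rbinom(length(fnew), 1L, pr)
    }
    rel <- list(intercept = unname(cf[1]), slope = unname(cf[2]),
                residual_scale = NA_real_, binary = TRUE,
                vcov = stats::vcov(fit), simulate = sim)
  } else {
    fit <- stats::lm(y ~ f)
    cf <- stats::coef(fit)
    # a perfect fit (zero residual) is legitimate here, not a warning
    sigma <- suppressWarnings(summary(fit)$sigma)
    if (!is.finite(sigma)) sigma <- 0
    sim <- function(fnew) {
      cf[1] + cf[2] * fnew + stats::rnorm(length(fnew), 0, sigma)
    }
    rel <- list(intercept = unname(cf[1]), slope = unname(cf[2]),
                residual_scale = sigma, binary = FALSE,
                vcov = suppressWarnings(stats::vcov(fit)), simulate = sim)
  }
  structure(rel, class = "ipd_relationship")
}

#' @export
print.ipd_relationship <- function(x, ...) {
  cat("<ipd_relationship> ",
      if (x$binary) "logistic calibration" else "least squares", "\n",
      "  intercept: ", signif(x$intercept, 5),
      "   slope: ", signif(x$slope, 5),
      if (!x$binary) paste0("   residual sd: ",
                            signif(x$residual_scale, 5)),
      "\n", sep = "")
  invisible(x)
}

# Deterministic per-iteration seed stream: a fixed-stride counter split so
# that changing the number of bootstrap replicates never reshuffles the
# draws of earlier iterations.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) + as.double(counter) * 104729) %% 2147483629)
}

#' PostPI bootstrap correction
#'
#' Corrects inference on the outcome scale by repeatedly simulating
#' pseudo-outcomes from the relationship model (see [fit_relationship()]).
#' Each bootstrap iteration resamples the unlabeled rows, draws
#' pseudo-outcomes at their predictions from the relationship model, and
#' fits the target model on the pseudo-outcome / feature pairs.  The point
#' estimate is the median of the bootstrap draws; the standard error is,
#' by default, the average within-iteration sandwich standard error
#' (`se_mode = "parametric"`) rescaled by `sqrt(N/n)` (`scale_se = TRUE`),
#' acknowledging that the labeled sample, through the relationship model,
#' is the information bottleneck: the raw within-iteration SEs reflect the
#' unlabeled sample size only.  Confidence intervals use the normal
#' approximation.
#'
#' The correction is centered at the relationship-rescaled naive fit, so
#' its validity rests on the predictions carrying the outcome's systematic
#' signal; with weak, noisy predictions the point estimate is attenuated
#' toward zero, a structural limitation of outcome-scale corrections that
#' the calibration-scale methods ([ppi()], [ppi_plusplus()], [pspa()])
#' were designed to remove.
#'
#' @inheritParams ppi
#' @param model Estimand: `"ols"` or `"logistic"` (the outcome-scale
#'   correction is defined for regression estimands).
#' @param nboot Number of bootstrap iterations (at least 2).
#' @param se_mode `"parametric"` (mean of within-iteration model SEs, the
#'   default) or `"nonparametric"` (spread of bootstrap estimates).
#' @param boot_relationship Additionally refit the relationship model on a
#'   resampled labeled set in each iteration (off by default)?
#' @param scale_se Multiply the standard errors by `sqrt(N/n)`?
#' @param seed Integer seed making the bootstrap reproducible.
#'
#' @return An object of class `"ipd_fit"`; the intermediates carry the
#'   full-sample relationship model and the matrix of bootstrap draws.
#' @references Wang et al. (2020) "Methods for correcting inference based
#'   on outcomes predicted by machine learning".
#' @export
postpi_boot <- function(ds, model = "ols", alpha = 0.05, nboot = 100,
                        se_mode = c("parametric", "nonparametric"),
                        boot_relationship = FALSE, scale_se = TRUE,
                        seed = NULL) {
  stopifnot(inherits(ds, "ipd_data"))
  se_mode <- match.arg(se_mode)
  if (!model %in% c("ols", "logistic")) {
    stop("postpi_boot supports the `ols` and `logistic` estimands; ",
         "the outcome-scale correction is not defined for `", model, "`.",
         call. = FALSE)
  }
  est <- estimand_spec(model)
  check_alpha(alpha)
  if (!is.numeric(nboot) || length(nboot) != 1L || is.na(nboot) ||
      nboot < 2) {
    stop("`nboot` must be at least 2.", call. = FALSE)
  }
  nboot <- as.integer(nboot)
  if (is.null(seed)) seed <- sample.int(2147483629L, 1L)
  seed <- as.integer(seed)

  b <- method_blocks(ds, est)
  binary <- est$model == "logistic"
  rel <- fit_relationship(ds, binary = binary)
  p <- ncol(b$XL)

  draws <- matrix(NA_real_, nboot, p)
  model_ses <- matrix(NA_real_, nboot, p)
  for (it in seq_len(nboot)) {
    set.seed(derive_seed(seed, it))
    rel_b <- rel
    if (boot_relationship) {
      # retry on degenerate resamples (all-constant predictions)
      for (attempt in 1:10) {
        idx_l <- sample.int(b$n, b$n, replace = TRUE)
        rel_try <- tryCatch(
          fit_relationship_yf(b$yL[idx_l], b$fL[idx_l], binary),
          error = function(e) NULL
        )
        if (!is.null(rel_try)) {
          rel_b <- rel_try
          break
        }
      }
    }
    idx_u <- sample.int(b$N, b$N, replace = TRUE)
    f_b <- b$fU[idx_u]
    X_b <- b$XU[idx_u, , drop = FALSE]
    y_tilde <- rel_b$simulate(f_b)
    theta_b <- tryCatch(solve_m_estimate(est, y_tilde, X_b),
                        error = function(e) NULL)
    if (is.null(theta_b)) next
    draws[it, ] <- theta_b
    model_ses[it, ] <- sqrt(diag(sandwich_vcov(est, y_tilde, X_b, theta_b)))
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 2L) {
    stop("fewer than 2 successful bootstrap iterations; the pseudo-",
         "outcome fits failed (check the relationship model).",
         call. = FALSE)
  }

  theta <- apply(draws[ok, , drop = FALSE], 2, stats::median)
  se <- switch(se_mode,
    nonparametric = apply(draws[ok, , drop = FALSE], 2, stats::sd),
    parametric = colMeans(model_ses[ok, , drop = FALSE])
  )
  if (scale_se) se <- se * sqrt(b$N / b$n)
  names(theta) <- names(se) <- colnames(b$XL)
  vcov <- diag(se^2, nrow = p)
  dimnames(vcov) <- list(colnames(b$XL), colnames(b$XL))

  new_ipd_fit(
    method = "postpi_boot", estimand = est, coefficients = theta,
    vcov = vcov, alpha = alpha,
    n_used = c(labeled = b$n, unlabeled = b$N), ds = ds, seed = seed,
    converged = all(ok),
    intermediates = list(relationship = rel, nboot = nboot,
                         n_failed = sum(!ok), se_mode = se_mode,
                         boot_relationship = boot_relationship,
                         scale_se = scale_se, draws = draws)
  )
}

#' PostPI analytic correction (linear regression)
#'
#' Closed-form counterpart of [postpi_boot()] for the linear-regression
#' estimand.  With relationship model `Y = gamma0 + gamma1 f + e` fit on
#' the labeled rows, and the naive regression of the predictions on the
#' features over the unlabeled rows giving `theta_naive`, the corrected
#' coefficients are
#'
#'   `theta = gamma1 * theta_naive + gamma0 * e1`
#'
#' (the intercept absorbs `gamma0`).  The covariance combines the two
#' independent sources of uncertainty by the delta method: the inference
#' model contributes `(gamma1^2 sigma_u^2 + sigma_e^2) (X'X)^{-1}` (the
#' naive design uncertainty rescaled by the slope, plus the relationship
#' residual noise an outcome-scale regression would see), and the
#' relationship model contributes `J Var(gamma) J'` with
#' `J = [e1, theta_naive]`.
#'
#' @inheritParams ppi
#' @param model Must be `"ols"`: the analytic correction is defined for
#'   linear regression only.
#'
#' @return An object of class `"ipd_fit"`; the intermediates carry the
#'   relationship model and the naive coefficients.
#' @references Wang et al. (2020).
#' @export
postpi_analytic <- function(ds, model = "ols", alpha = 0.05) {
  stopifnot(inherits(ds, "ipd_data"))
  if (!identical(model, "ols")) {
    stop("postpi_analytic is defined for the `ols` estimand only; use ",
         "postpi_boot for logistic regression.", call. = FALSE)
  }
  est <- estimand_spec("ols")
  check_alpha(alpha)
  b <- method_blocks(ds, est)
  if (!ds$formula$intercept) {
    stop("postpi_analytic requires an intercept in the inference model ",
         "(the relationship intercept must be absorbed somewhere).",
         call. = FALSE)
  }
  rel <- fit_relationship(ds, binary = FALSE)

  theta_naive <- solve_m_estimate(est, b$fU, b$XU)
  XtXinv <- solve_checked(crossprod(b$XU))
  resid_naive <- b$fU - drop(b$XU %*% theta_naive)
  p <- ncol(b$XU)
  sigma2_u <- sum(resid_naive^2) / (b$N - p)

  theta <- rel$slope * theta_naive
  theta[1] <- theta[1] + rel$intercept

  e1 <- c(1, rep(0, p - 1))
  J <- cbind(e1, theta_naive)
  V <- (rel$slope^2 * sigma2_u + rel$residual_scale^2) * XtXinv +
    J %*% rel$vcov %*% t(J)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(b$XU), colnames(b$XU))

  new_ipd_fit(
    method = "postpi_analytic", estimand = est, coefficients = theta,
    vcov = V, alpha = alpha,
    n_used = c(labeled = b$n, unlabeled = b$N), ds = ds,
    intermediates = list(relationship = rel, naive = theta_naive)
  )
}
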