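#' Specify the target estimand
#'
#' Every estimand supported by the package is cast as an M-estimation
#' problem: the population target \eqn{\theta_0} is the root of
#' \eqn{E[\psi(Y, X; \theta)] = 0} for an estimating function \eqn{\psi},
#' namely
#'
#' * `mean`: \eqn{\psi = y - \theta};
#' * `quantile` (level `q`): \eqn{\psi = 1\{y \le \theta\} - q};
#' * `ols`: \eqn{\psi = x (y - x^\top\theta)};
#' * `logistic`: \eqn{\psi = x (y - \mathrm{expit}(x^\top\theta))}.
#'
#' @param model One of `"mean"`, `"quantile"`, `"ols"`, `"logistic"`.
#' @param q Quantile level in (0, 1); required iff `model = "quantile"`.
#'
#' @return An object of class `"estimand_spec"`.
#' @export
estimand_spec <- function(model = c("mean", "quantile", "ols", "logistic"),
                          q = NULL) {
  model <- match.arg(model)
  if (model == "quantile") {
    if (is.null(q) || !is.numeric(q) || length(q) != 1L || is.na(q) ||
        q <= 0 || q >= 1) {
      stop("`q` must be a single probability strictly inside (0, 1) for ",
           "the quantile estimand.", call. = FALSE)
    }
  } else if (!is.null(q)) {
    stop("`q` is only meaningful for the quantile estimand.", call. = FALSE)
  }
  structure(list(model = model, q = q), class = "estimand_spec")
}

n_params <- function(est, X) {
  if (est$model %in% c("mean", "quantile")) 1L else ncol(X)
}

#' Estimating-function (score) values
#'
#' Evaluates the estimand's estimating function at each observation.  For
#' the scalar estimands (mean, quantile) the design matrix is ignored.
#'
#' @param est An [estimand_spec()].
#' @param y Numeric response vector (the observed outcome, or a prediction
#'   standing in for it).
#' @param X Design matrix with one row per element of `y`.
#' @param theta Parameter vector at which to evaluate the score.
#'
#' @return An `n x p` matrix of per-observation scores.
#' @export
est_score <- function(est, y, X, theta) {
  p <- n_params(est, X)
  if (length(theta) != p) {
    stop("`theta` has length ", length(theta), " but the ", est$model,
         " estimand expects ", p, ".", call. = FALSE)
  }
  switch(est$model,
    mean = cbind(mean = y - theta),
    quantile = cbind(quantile = as.numeric(y <= theta) - est$q),
    ols = X * drop(y - X %*% theta),
    logistic = X * drop(y - stats::plogis(X %*% theta))
  )
}

# Mean Jacobian of the score, d/d(theta) (1/n) sum psi_i.  For the quantile
# estimand the indicator score is non-differentiable and the population
# Jacobian is the outcome density at theta; we plug in a Gaussian-kernel
# estimate with Silverman's bandwidth.
est_jacobian <- function(est, y, X, theta) {
  switch(est$model,
    mean = matrix(-1, 1, 1),
    quantile = matrix(kernel_density_at(y, theta), 1, 1),
    ols = -crossprod(X) / nrow(X),
    logistic = {
      pr <- drop(stats::plogis(X %*% theta))
      -crossprod(X, X * (pr * (1 - pr))) / nrow(X)
    }
  )
}

kernel_density_at <- function(y, at) {
  bw <- stats::bw.nrd0(y)
  if (!is.finite(bw) || bw <= 0) {
    stop("cannot estimate the outcome density: degenerate sample.",
         call. = FALSE)
  }
  mean(stats::dnorm((at - y) / bw)) / bw
}

#' Solve an estimating equation for a single sample
#'
#' Computes the (optionally weighted) M-estimate for an estimand on one
#' block of data: the weighted mean, the weighted empirical quantile
#' (inverted-CDF convention, ties broken toward the smaller value), weighted
#' least squares, or a logistic fit via iteratively reweighted least
#' squares.  At the returned value the mean weighted score is zero to within
#' solver tolerance (exactly, for the closed-form estimands).
#'
#' @inheritParams est_score
#' @param weights Optional non-negative observation weights.
#'
#' @return The parameter vector, named after the design columns (or the
#'   estimand, for scalar targets).
#' @export
solve_m_estimate <- function(est, y, X, weights = NULL) {
  n <- length(y)
  if (n < 1L) stop("no rows to fit.", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || anyNA(weights)) {
    stop("`weights` must be non-negative and match the number of rows.",
         call. = FALSE)
  }

  switch(est$model,
    mean = c(mean = stats::weighted.mean(y, weights)),
    quantile = c(quantile = weighted_quantile_type1(y, weights, est$q)),
    ols = {
      check_rank(X, n)
      w <- sqrt(weights)
      fit <- stats::lm.fit(X * w, y * w)
      if (fit$rank < ncol(X)) {
        stop("singular design in least-squares fit.", call. = FALSE)
      }
      stats::setNames(fit$coefficients, colnames(X))
    },
    logistic = {
      if (!all(y %in% c(0, 1))) {
        stop("logistic estimand requires a 0/1-coded outcome; refusing to ",
             "recode.", call. = FALSE)
      }
      check_rank(X, n)
      fit <- suppressWarnings(stats::glm.fit(
        X, y, weights = weights, family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)
      ))
      if (!fit$converged || any(!is.finite(fit$coefficients))) {
        stop("logistic fit did not converge after ", fit$iter,
             " iterations (possible separation).", call. = FALSE)
      }
      stats::setNames(fit$coefficients, colnames(X))
    }
  )
}

check_rank <- function(X, n) {
  if (n < ncol(X) + 1L) {
    stop("too few rows (", n, ") to fit ", ncol(X),
         " parameters.", call. = FALSE)
  }
  invisible(TRUE)
}

# Left-continuous (inverted CDF) weighted quantile: the smallest y whose
# cumulative weight reaches q, matching the root set of the indicator score.
weighted_quantile_type1 <- function(y, w, q) {
  ord <- order(y)
  y <- y[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  y[which(cw >= q - 1e-12)[1L]]
}

#' Sandwich (robust) variance of an M-estimate
#'
#' Standard sandwich covariance \eqn{A^{-1} B A^{-\top} / n} with
#' \eqn{A} the mean score Jacobian and \eqn{B} the mean outer product of
#' per-observation scores (the HC0 flavor; no small-sample correction).
#' For the quantile estimand \eqn{A} uses a kernel density estimate at the
#' fitted quantile, giving the familiar \eqn{q(1-q)/(n \hat d^2)} plug-in.
#'
#' @inheritParams est_score
#' @param theta The solution of the estimating equation (see
#'   [solve_m_estimate()]).
#'
#' @return A symmetric positive semi-definite `p x p` matrix.
#' @export
sandwich_vcov <- function(est, y, X, theta) {
  n <- length(y)
  S <- est_score(est, y, X, theta)
  A <- est_jacobian(est, y, X, theta)
  B <- crossprod(S) / n
  Ainv <- solve_checked(A)
  V <- Ainv %*% B %*% t(Ainv) / n
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(S), colnames(S))
  V
}

solve_checked <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    stop("singular score Jacobian: the sandwich variance is not defined.",
         call. = FALSE)
  }
  out
}

#' Benchmark fits: oracle, naive, and classic
#'
#' The three reference estimators against which the IPD corrections are
#' judged:
#'
#' * **oracle** — fits the target model on the *true* outcomes of the
#'   unlabeled rows.  Only possible on simulated data where those outcomes
#'   are known; it is the best-case estimator.
#' * **naive** — fits on the unlabeled rows treating the *predictions* as if
#'   they were true outcomes; generally biased with anti-conservative
#'   intervals.
#' * **classic** — fits on the labeled rows only; valid but inefficient.
#'
#' All three report sandwich (HC0) standard errors and normal-approximation
#' confidence intervals.
#'
#' @param which One of `"oracle"`, `"naive"`, `"classic"`.
#' @param ds An [ipd_data()] object.
#' @param model,q Estimand, as in [ipd()].
#' @param alpha Significance level for the 100(1 - alpha)% intervals.
#'
#' @return An object of class `"ipd_fit"`.
#' @export
benchmark_fit <- function(which = c("oracle", "naive", "classic"), ds,
                          model = "ols", q = NULL, alpha = 0.05) {
  which <- match.arg(which)
  stopifnot(inherits(ds, "ipd_data"))
  est <- estimand_spec(model, q)
  check_alpha(alpha)

  scalar <- est$model %in% c("mean", "quantile")
  scalar_design <- function(n) {
    matrix(1, n, 1, dimnames = list(NULL, est$model))
  }
  if (which == "classic") {
    y <- ds$outcome[ds$set_labeled]
    X <- if (scalar) scalar_design(ds$n_labeled) else
      build_design(ds, "labeled")
    n_used <- c(labeled = ds$n_labeled, unlabeled = 0L)
  } else {
    if (ds$n_unlabeled < 1L) {
      stop("the ", which, " benchmark needs unlabeled rows.", call. = FALSE)
    }
    X <- if (scalar) scalar_design(ds$n_unlabeled) else
      build_design(ds, "unlabeled")
    n_used <- c(labeled = 0L, unlabeled = ds$n_unlabeled)
    if (which == "oracle") {
      y <- ds$outcome[!ds$set_labeled]
      if (anyNA(y)) {
        stop("oracle benchmark requires true outcomes on the unlabeled ",
             "rows; they are only available on simulated data.",
             call. = FALSE)
      }
    } else {
      y <- ds$prediction[!ds$set_labeled]
    }
  }

  theta <- solve_m_estimate(est, y, X)
  vcov <- sandwich_vcov(est, y, X, theta)
  new_ipd_fit(
    method = which, estimand = est, coefficients = theta, vcov = vcov,
    alpha = alpha, n_used = n_used, ds = ds,
    intermediates = list()
  )
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number strictly inside (0, 1).",
         call. = FALSE)
  }
  invisible(TRUE)
}
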