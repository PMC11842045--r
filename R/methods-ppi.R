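# Rectified estimating equations ----------------------------------------
#
# PPI, PPI++, and PSPA all solve a weighted, rectified estimating equation
#
#   g_w(theta) = (1/n) sum_L psi(Y_i, X_i; theta)
#              + diag(w) [ (1/N) sum_U psi(f_i, X_i; theta)
#                          - (1/n) sum_L psi(f_i, X_i; theta) ] = 0,
#
# where w is a per-coordinate weight vector in [0, 1]^p.  w = 0 recovers the
# classic labeled-only estimator, w = 1 the PPI rectifier; PPI++ uses a
# common scalar weight (power tuning) and PSPA a per-coordinate vector, each
# estimated to minimize asymptotic variance.

method_blocks <- function(ds, est) {
  scalar <- est$model %in% c("mean", "quantile")
  if (ds$n_unlabeled < 1L) {
    stop("this correction needs unlabeled rows: with no unlabeled ",
         "predictions there is nothing to correct.", call. = FALSE)
  }
  nm <- if (est$model == "mean") "mean" else if (est$model == "quantile")
    "quantile" else NULL
  XL <- if (scalar) {
    matrix(1, ds$n_labeled, 1, dimnames = list(NULL, nm))
  } else {
    build_design(ds, "labeled")
  }
  XU <- if (scalar) {
    matrix(1, ds$n_unlabeled, 1, dimnames = list(NULL, nm))
  } else {
    build_design(ds, "unlabeled")
  }
  list(
    yL = ds$outcome[ds$set_labeled],
    fL = ds$prediction[ds$set_labeled],
    fU = ds$prediction[!ds$set_labeled],
    XL = XL, XU = XU,
    n = ds$n_labeled, N = ds$n_unlabeled
  )
}

check_weights <- function(w, p) {
  if (!is.numeric(w) || anyNA(w)) {
    stop("weights must be numeric and non-missing.", call. = FALSE)
  }
  if (length(w) == 1L) w <- rep(w, p)
  if (length(w) != p) {
    stop("weight vector has length ", length(w), " but the estimand has ",
         p, " parameter(s).", call. = FALSE)
  }
  w
}

rectified_solve <- function(est, b, w) {
  p <- n_params(est, b$XL)
  w <- check_weights(w, p)
  theta <- switch(est$model,
    mean = c(mean = mean(b$yL) + w * (mean(b$fU) - mean(b$fL))),
    ols = {
      check_rank(b$XL, b$n)
      ML <- crossprod(b$XL) / b$n
      MU <- crossprod(b$XU) / b$N
      M <- ML + (MU - ML) * w # rows scaled by w
      rhs <- drop(crossprod(b$XL, b$yL)) / b$n +
        w * (drop(crossprod(b$XU, b$fU)) / b$N -
               drop(crossprod(b$XL, b$fL)) / b$n)
      drop(solve_checked(M) %*% rhs)
    },
    quantile = c(quantile = rectified_quantile(b, w, est$q)),
    logistic = rectified_logistic(b, w)
  )
  if (est$model %in% c("ols", "logistic")) {
    names(theta) <- colnames(b$XL)
  }
  theta
}

# The rectified quantile equation is a step function of theta; evaluate it
# on the pooled jump points and take the smallest point where it reaches
# zero, the direct generalization of the inverted-CDF sample quantile.
rectified_quantile <- function(b, w, q) {
  cand <- sort(unique(c(b$yL, b$fL, b$fU)))
  g <- vapply(cand, function(t) {
    mean(b$yL <= t) - q + w * (mean(b$fU <= t) - mean(b$fL <= t))
  }, numeric(1))
  hit <- which(g >= -1e-12)
  if (!length(hit)) cand[length(cand)] else cand[hit[1L]]
}

rectified_logistic <- function(b, w, max_iter = 100, tol = 1e-10) {
  if (!all(b$yL %in% c(0, 1))) {
    stop("logistic estimand requires a 0/1-coded outcome; refusing to ",
         "recode.", call. = FALSE)
  }
  check_rank(b$XL, b$n)
  p <- ncol(b$XL)
  gfun <- function(theta) {
    drop(crossprod(b$XL, b$yL - stats::plogis(b$XL %*% theta))) / b$n +
      w * (drop(crossprod(b$XU, b$fU - stats::plogis(b$XU %*% theta))) /
             b$N -
           drop(crossprod(b$XL, b$fL - stats::plogis(b$XL %*% theta))) /
             b$n)
  }
  jfun <- function(theta) {
    pl <- drop(stats::plogis(b$XL %*% theta))
    pu <- drop(stats::plogis(b$XU %*% theta))
    JL <- -crossprod(b$XL, b$XL * (pl * (1 - pl))) / b$n
    JU <- -crossprod(b$XU, b$XU * (pu * (1 - pu))) / b$N
    JL + (JU - JL) * w
  }
  theta <- tryCatch(
    unname(solve_m_estimate(estimand_spec("logistic"), b$yL, b$XL)),
    error = function(e) rep(0, p)
  )
  g <- gfun(theta)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(g^2)) < tol) break
    step <- drop(solve_checked(jfun(theta)) %*% g)
    # damped Newton: halve until the score norm decreases
    fac <- 1
    repeat {
      theta_new <- theta - fac * step
      g_new <- gfun(theta_new)
      if (sqrt(sum(g_new^2)) <= sqrt(sum(g^2)) || fac < 1e-4) break
      fac <- fac / 2
    }
    theta <- theta_new
    g <- g_new
  }
  if (sqrt(sum(g^2)) >= 1e-6) {
    stop("rectified logistic fit did not converge (", max_iter,
         " iterations; final score norm ", signif(sqrt(sum(g^2)), 3),
         ").", call. = FALSE)
  }
  theta
}

# Per-observation score blocks and Jacobians at theta, shared by the
# variance and the weight-estimation steps.
rectified_pieces <- function(est, b, theta) {
  list(
    psiY = est_score(est, b$yL, b$XL, theta),
    psiFL = est_score(est, b$fL, b$XL, theta),
    psiFU = est_score(est, b$fU, b$XU, theta),
    JY = est_jacobian(est, b$yL, b$XL, theta),
    JFL = est_jacobian(est, b$fL, b$XL, theta),
    JFU = est_jacobian(est, b$fU, b$XU, theta)
  )
}

cov_n <- function(S) {
  Sc <- sweep(S, 2, colMeans(S), "-")
  crossprod(Sc) / nrow(S)
}

cross_cov_n <- function(S1, S2) {
  S1c <- sweep(S1, 2, colMeans(S1), "-")
  S2c <- sweep(S2, 2, colMeans(S2), "-")
  crossprod(S1c, S2c) / nrow(S1)
}

# Sandwich covariance of the weighted rectified estimator:
#   A(w)^{-1} [ Cov_L(psi^Y - W psi^f)/n + W Cov_U(psi^f) W / N ] A(w)^{-T},
# with A(w) = J_L^Y + W (J_U^f - J_L^f) the Jacobian of g_w.
rectified_vcov <- function(est, b, theta, w) {
  p <- length(theta)
  w <- check_weights(w, p)
  pc <- rectified_pieces(est, b, theta)
  A <- pc$JY + (pc$JFU - pc$JFL) * w
  D <- pc$psiY - sweep(pc$psiFL, 2, w, "*")
  B <- cov_n(D) / b$n + (cov_n(pc$psiFU) * outer(w, w)) / b$N
  Ainv <- solve_checked(A)
  V <- Ainv %*% B %*% t(Ainv)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(theta), names(theta))
  V
}

# Scalar power-tuning weight: with A held at its w = 1 value, the trace of
# the asymptotic covariance is quadratic in lambda; its minimizer is
#   lambda* = tr(Ai (C + C')/2 Ai') / n
#           / [ tr(Ai V_f^L Ai') / n + tr(Ai V_f^U Ai') / N ],
# where C = Cov_L(psi^Y, psi^f) and Ai = A^{-1}.
estimate_lambda <- function(est, b, theta) {
  pc <- rectified_pieces(est, b, theta)
  A <- pc$JY + (pc$JFU - pc$JFL)
  Ai <- solve_checked(A)
  C <- cross_cov_n(pc$psiY, pc$psiFL)
  tr <- function(M) sum(diag(M))
  num <- tr(Ai %*% ((C + t(C)) / 2) %*% t(Ai)) / b$n
  den <- tr(Ai %*% cov_n(pc$psiFL) %*% t(Ai)) / b$n +
    tr(Ai %*% cov_n(pc$psiFU) %*% t(Ai)) / b$N
  if (!is.finite(den) || den <= .Machine$double.eps) {
    return(0) # flat criterion: default to the conservative, classic end
  }
  num / den
}

# Element-wise weights: coordinate j's asymptotic variance is quadratic in
# omega_j given the other coordinates, so the joint first-order conditions
# form a p x p linear system; we solve it for the raw weights and, when
# clipping, polish with a projected Gauss-Seidel sweep onto [0, 1]^p.
estimate_omega <- function(est, b, theta, clip = TRUE) {
  pc <- rectified_pieces(est, b, theta)
  p <- length(theta)
  A <- pc$JY + (pc$JFU - pc$JFL)
  Ai <- solve_checked(A)
  Yc <- sweep(pc$psiY, 2, colMeans(pc$psiY), "-")
  Fc <- sweep(pc$psiFL, 2, colMeans(pc$psiFL), "-")
  Uc <- sweep(pc$psiFU, 2, colMeans(pc$psiFU), "-")
  ratio <- b$n / b$N

  G <- vector("list", p)
  cvec <- numeric(p)
  R <- matrix(0, p, p)
  for (j in seq_len(p)) {
    a <- Ai[j, ]
    Zj <- sweep(Fc, 2, a, "*")
    Zuj <- sweep(Uc, 2, a, "*")
    G[[j]] <- crossprod(Zj) / b$n + ratio * crossprod(Zuj) / b$N
    u <- drop(Yc %*% a)
    cj <- drop(crossprod(Zj, u)) / b$n
    cvec[j] <- cj[j]
    R[j, ] <- G[[j]][j, ]
  }

  diag_ok <- vapply(G, function(g) diag(g), numeric(p))
  raw <- tryCatch(drop(solve(R, cvec)), error = function(e) NULL)
  if (is.null(raw) || any(!is.finite(raw))) {
    raw <- vapply(seq_len(p), function(j) {
      d <- G[[j]][j, j]
      if (d <= .Machine$double.eps) 0 else cvec[j] / d
    }, numeric(1))
  }
  if (!clip) {
    return(list(omega = raw, omega_raw = raw))
  }
  omega <- pmin(pmax(raw, 0), 1)
  for (sweep_i in seq_len(200)) {
    delta <- 0
    for (j in seq_len(p)) {
      d <- G[[j]][j, j]
      new_j <- if (d <= .Machine$double.eps) {
        0
      } else {
        (cvec[j] - sum(omega[-j] * G[[j]][j, -j])) / d
      }
      new_j <- min(max(new_j, 0), 1)
      delta <- max(delta, abs(new_j - omega[j]))
      omega[j] <- new_j
    }
    if (delta < 1e-10) break
  }
  list(omega = omega, omega_raw = raw)
}

# Exported methods -------------------------------------------------------

#' Prediction-powered inference (PPI)
#'
#' Debiases the prediction-based fit with a labeled-data *rectifier*: the
#' estimate solves the unlabeled estimating equation evaluated at the
#' predictions, minus the labeled-data average difference between
#' prediction-based and outcome-based scores.  For the mean this reduces to
#' the closed form `mean(f_U) - mean(f_L - Y_L)`.  The sandwich variance
#' combines the unlabeled score covariance (scaled by 1/N) with the
#' covariance of the labeled score difference (scaled by 1/n).
#'
#' @param ds An [ipd_data()] object.
#' @param model Estimand: `"mean"`, `"quantile"`, `"ols"`, or `"logistic"`.
#' @param q Quantile level, required iff `model = "quantile"`.
#' @param alpha Significance level for the 100(1 - alpha)% intervals.
#'
#' @return An object of class `"ipd_fit"`.
#' @references Angelopoulos et al. (2023) "Prediction-powered inference".
#' @export
ppi <- function(ds, model = "ols", q = NULL, alpha = 0.05) {
  stopifnot(inherits(ds, "ipd_data"))
  est <- estimand_spec(model, q)
  check_alpha(alpha)
  b <- method_blocks(ds, est)
  theta <- rectified_solve(est, b, 1)
  vcov <- rectified_vcov(est, b, theta, 1)
  rectifier <- colMeans(est_score(est, b$fL, b$XL, theta)) -
    colMeans(est_score(est, b$yL, b$XL, theta))
  new_ipd_fit(
    method = "ppi", estimand = est, coefficients = theta, vcov = vcov,
    alpha = alpha, n_used = c(labeled = b$n, unlabeled = b$N), ds = ds,
    intermediates = list(rectifier = rectifier)
  )
}

#' Power-tuned prediction-powered inference (PPI++)
#'
#' As [ppi()], but the rectifying correction is multiplied by a scalar
#' power-tuning weight `lambda`, estimated to minimize the trace of the
#' asymptotic covariance (and clipped to `[0, 1]` by default; the raw value
#' is kept in the fit's intermediates).  `lambda = 0` recovers the classic
#' labeled-only estimator and `lambda = 1` recovers PPI, so the tuned
#' estimator adapts to the quality of the predictions.
#'
#' @inheritParams ppi
#' @param lambda Optional fixed weight, bypassing estimation (used mainly
#'   for the reduction identities `lambda = 0` / `lambda = 1`).
#' @param clip Clip the estimated weight to `[0, 1]`?  Clipping guards
#'   against anti-shrinkage from noisy covariance estimates at small n.
#'
#' @return An object of class `"ipd_fit"` with `lam` (and `lam_raw`) among
#'   the intermediates.
#' @references Angelopoulos et al. (2023) "PPI++: efficient
#'   prediction-powered inference".
#' @export
ppi_plusplus <- function(ds, model = "ols", q = NULL, alpha = 0.05,
                         lambda = NULL, clip = TRUE) {
  stopifnot(inherits(ds, "ipd_data"))
  est <- estimand_spec(model, q)
  check_alpha(alpha)
  b <- method_blocks(ds, est)
  if (is.null(lambda)) {
    theta_init <- rectified_solve(est, b, 1)
    lam_raw <- estimate_lambda(est, b, theta_init)
    lam <- if (clip) min(max(lam_raw, 0), 1) else lam_raw
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda)) {
      stop("`lambda` must be a single numeric weight.", call. = FALSE)
    }
    lam_raw <- lam <- lambda
  }
  theta <- rectified_solve(est, b, lam)
  vcov <- rectified_vcov(est, b, theta, lam)
  new_ipd_fit(
    method = "ppi_plusplus", estimand = est, coefficients = theta,
    vcov = vcov, alpha = alpha,
    n_used = c(labeled = b$n, unlabeled = b$N), ds = ds,
    intermediates = list(lam = lam, lam_raw = lam_raw,
                         lam_fixed = !is.null(lambda))
  )
}

#' Post-prediction adaptive inference (PSPA)
#'
#' Generalizes the [ppi_plusplus()] power tuning to an element-wise weight
#' vector `omega`, one entry per parameter, chosen to minimize each
#' coordinate's asymptotic variance (the joint first-order conditions are
#' solved as a linear system; with clipping the solution is polished by a
#' projected Gauss-Seidel pass onto `[0, 1]^p`).  `omega = 0` recovers the
#' classic estimator and `omega = 1` recovers PPI, coordinate by
#' coordinate.
#'
#' @inheritParams ppi
#' @param omega Optional fixed weight vector (or scalar, recycled),
#'   bypassing estimation.
#' @param clip Clip the weights to `[0, 1]`?
#'
#' @return An object of class `"ipd_fit"` with `omega` (and `omega_raw`)
#'   among the intermediates.
#' @references Miao et al. (2023) "Assumption-lean and data-adaptive
#'   post-prediction inference".
#' @export
pspa <- function(ds, model = "ols", q = NULL, alpha = 0.05, omega = NULL,
                 clip = TRUE) {
  stopifnot(inherits(ds, "ipd_data"))
  est <- estimand_spec(model, q)
  check_alpha(alpha)
  b <- method_blocks(ds, est)
  p <- n_params(est, b$XL)
  if (is.null(omega)) {
    theta_init <- rectified_solve(est, b, 1)
    om <- estimate_omega(est, b, theta_init, clip = clip)
    omega_used <- om$omega
    omega_raw <- om$omega_raw
  } else {
    omega_used <- omega_raw <- check_weights(omega, p)
  }
  theta <- rectified_solve(est, b, omega_used)
  vcov <- rectified_vcov(est, b, theta, omega_used)
  names(omega_used) <- names(theta)
  new_ipd_fit(
    method = "pspa", estimand = est, coefficients = theta, vcov = vcov,
    alpha = alpha, n_used = c(labeled = b$n, unlabeled = b$N), ds = ds,
    intermediates = list(omega = omega_used, omega_raw = omega_raw,
                         omega_fixed = !is.null(omega))
  )
}
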