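ipd_methods <- c("postpi_analytic", "postpi_boot", "ppi", "ppi_plusplus",
                 "pspa")
ipd_models <- c("mean", "quantile", "ols", "logistic")

# which estimands each correction supports; unsupported cells fail fast
method_model_grid <- list(
  postpi_analytic = "ols",
  postpi_boot = c("ols", "logistic"),
  ppi = ipd_models,
  ppi_plusplus = ipd_models,
  pspa = ipd_models
)

#' Inference on predicted data
#'
#' One-stop interface to the correction methods for downstream inference
#' when outcome values are machine-generated predictions.  The model is
#' specified with a formula of the form `Y - f ~ X1 + X2 + ...` naming the
#' observed outcome, the predicted outcome, and the features (see
#' [ipd_formula()]); data may be supplied stacked (with `label` naming the
#' set-indicator column) or as separate labeled/unlabeled tables (see
#' [ipd_data()]).
#'
#' Available methods and the estimands each supports:
#'
#' | method            | mean | quantile | ols | logistic |
#' |-------------------|------|----------|-----|----------|
#' | `postpi_analytic` |      |          | yes |          |
#' | `postpi_boot`     |      |          | yes | yes      |
#' | `ppi`             | yes  | yes      | yes | yes      |
#' | `ppi_plusplus`    | yes  | yes      | yes | yes      |
#' | `pspa`            | yes  | yes      | yes | yes      |
#'
#' Each published correction is implemented over its published scope;
#' requesting an unsupported method/estimand cell is an error rather than a
#' silent approximation.
#'
#' @param formula `Y - f ~ X1 + ...`; use `Y - f ~ 1` for the scalar
#'   estimands.
#' @param method One of `"postpi_analytic"`, `"postpi_boot"`, `"ppi"`,
#'   `"ppi_plusplus"`, `"pspa"`.
#' @param model Estimand: `"mean"`, `"quantile"`, `"ols"`, `"logistic"`.
#' @param data Data frame: stacked table, or the labeled rows.
#' @param unlabeled_data Optional data frame of unlabeled rows (separate
#'   mode).
#' @param label Optional name of the set-indicator column (stacked mode).
#' @param alpha Significance level for the 100(1 - alpha)% confidence
#'   intervals.
#' @param q Quantile level, required iff `model = "quantile"`.
#' @param seed Integer seed for the stochastic methods (`postpi_boot`).
#' @param ... Further method-specific arguments (e.g. `nboot`, `se_mode`
#'   for `postpi_boot`; `lambda`, `clip` for `ppi_plusplus`; `omega` for
#'   `pspa`).
#'
#' @return An object of class `"ipd_fit"`: a glm-style list carrying the
#'   coefficient estimates, sandwich standard errors, confidence limits,
#'   call metadata, and method-specific intermediate quantities (the
#'   relationship model for PostPI, the tuning weights for PPI++/PSPA).
#'   Inspect with [print()], [summary()], [tidy()], [glance()],
#'   [augment()].
#'
#' @examples
#' dat <- simdat(n_train = 50, n_labeled = 50, n_unlabeled = 200, seed = 1)
#' pred <- train_predictor(dat)
#' dat <- add_predictions(dat, pred)
#' fit <- ipd(Y - f ~ X1 + X2 + X3 + X4, method = "pspa", model = "ols",
#'            data = dat, label = "set_label")
#' summary(fit)
#' @export
ipd <- function(formula, method, model, data, unlabeled_data = NULL,
                label = NULL, alpha = 0.05, q = NULL, seed = NULL, ...) {
  if (missing(method) || !is.character(method) || length(method) != 1L ||
      !method %in% ipd_methods) {
    stop("`method` must be one of: ",
         paste0("\"", ipd_methods, "\"", collapse = ", "), ".",
         call. = FALSE)
  }
  if (missing(model) || !is.character(model) || length(model) != 1L ||
      !model %in% ipd_models) {
    stop("`model` must be one of: ",
         paste0("\"", ipd_models, "\"", collapse = ", "), ".",
         call. = FALSE)
  }
  if (!model %in% method_model_grid[[method]]) {
    stop("method \"", method, "\" does not support the \"", model,
         "\" estimand (supported: ",
         paste0("\"", method_model_grid[[method]], "\"", collapse = ", "),
         ").", call. = FALSE)
  }
  if (model == "quantile" && is.null(q)) {
    stop("the quantile estimand requires `q`.", call. = FALSE)
  }

  ds <- ipd_data(formula, data, unlabeled_data = unlabeled_data,
                 label = label)
  fit <- switch(method,
    postpi_analytic = postpi_analytic(ds, model = model, alpha = alpha,
                                      ...),
    postpi_boot = postpi_boot(ds, model = model, alpha = alpha,
                              seed = seed, ...),
    ppi = ppi(ds, model = model, q = q, alpha = alpha, ...),
    ppi_plusplus = ppi_plusplus(ds, model = model, q = q, alpha = alpha,
                                ...),
    pspa = pspa(ds, model = model, q = q, alpha = alpha, ...)
  )
  fit$call <- match.call()
  fit
}
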