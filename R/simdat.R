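#' Simulate a stacked dataset for method evaluation
#'
#' Generates data from a nonlinear regression with one linear target
#' coefficient:
#'
#'   `Y = beta1 * X1 + (1/2) X2^2 + (1/3) X3^3 + (1/4) X4^2 + eps`,
#'
#' with `X1, ..., X4 ~ N(0, 1)` independent and `eps ~ N(0, sigma_y^2)`.
#' The target of inference is the linear-regression coefficient of `X1`,
#' whose population value is `beta1`; the remaining covariates enter
#' nonlinearly, so a flexible smoother (see [train_predictor()]) has signal
#' to learn while a linear model remains well-defined as a projection.
#'
#' Rows are split into `training` / `labeled` / `unlabeled` blocks,
#' recorded in a `set_label` column: the training block is reserved for
#' fitting the prediction algorithm upstream, the labeled block carries
#' observed outcomes for downstream correction, and the unlabeled block is
#' where inference on predictions happens.  The true outcome is generated
#' on every row (so the oracle benchmark is available); the methods only
#' ever see it on labeled rows.
#'
#' In binary mode the continuous outcome above is latent and the recorded
#' outcome is `Y = 1{latent > median(latent)}`, thresholded at the sample
#' median of the generated latent values.
#'
#' @param n_train,n_labeled,n_unlabeled Block sizes (defaults 100 / 100 /
#'   1000).
#' @param beta1 Linear coefficient of `X1` (default 1).
#' @param sigma_y Noise standard deviation (default 4).
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @param seed Optional integer seed; the same seed reproduces the table
#'   bitwise.
#'
#' @return A data frame with columns `X1`-`X4`, `Y`, `set_label`.
#'
#' @examples
#' dat <- simdat(seed = 1)
#' table(dat$set_label)
#' @export
simdat <- function(n_train = 100, n_labeled = 100, n_unlabeled = 1000,
                   beta1 = 1, sigma_y = 4,
                   outcome_kind = c("continuous", "binary"), seed = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  counts <- c(n_train = n_train, n_labeled = n_labeled,
              n_unlabeled = n_unlabeled)
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != round(counts))) {
    stop("`n_train`, `n_labeled`, and `n_unlabeled` must be positive ",
         "integers.", call. = FALSE)
  }
  if (!is.numeric(sigma_y) || length(sigma_y) != 1L || sigma_y <= 0) {
    stop("`sigma_y` must be a single positive number.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- sum(counts)
  X <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("X", 1:4)))
  eps <- stats::rnorm(n, 0, sigma_y)
  y <- beta1 * X[, 1] + X[, 2]^2 / 2 + X[, 3]^3 / 3 + X[, 4]^2 / 4 + eps
  if (outcome_kind == "binary") {
    y <- as.numeric(y > stats::median(y))
  }

  data.frame(
    X,
    Y = y,
    set_label = rep(c("training", "labeled", "unlabeled"), counts),
    stringsAsFactors = FALSE
  )
}

#' Train a flexible prediction model on the training block
#'
#' Fits a generalized additive model (penalized per-covariate thin-plate
#' splines with GCV smoothness selection, via [mgcv::gam()]) of the outcome
#' on every covariate column, using the `training` rows of a stacked table
#' produced by [simdat()] (or the whole table if no `set_label` column is
#' present).  For a binary outcome a binomial GAM is used and predictions
#' are probabilities.
#'
#' The trained object stands in for the pre-trained AI/ML system whose
#' predictions downstream analyses would consume: it is fit on rows
#' disjoint from both inference blocks.
#'
#' @param data A data frame with outcome column `Y`, covariate columns, and
#'   optionally `set_label`.
#' @param outcome Name of the outcome column (default `"Y"`).
#'
#' @return An object of class `"ipd_predictor"`; apply it to new data with
#'   [predict()] or [add_predictions()].
#' @export
train_predictor <- function(data, outcome = "Y") {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    stop("outcome column `", outcome, "` not found.", call. = FALSE)
  }
  if ("set_label" %in% names(data)) {
    train <- data[tolower(data$set_label) %in% c("training", "train"), ,
                  drop = FALSE]
  } else {
    train <- data
  }
  if (nrow(train) < 20L) {
    stop("at least 20 training rows are required to train the smoother ",
         "(got ", nrow(train), ").", call. = FALSE)
  }
  covars <- setdiff(names(train), c(outcome, "set_label", "f"))
  covars <- covars[vapply(train[covars], is.numeric, logical(1))]
  if (!length(covars)) {
    stop("no numeric covariate columns to train on.", call. = FALSE)
  }

  y <- train[[outcome]]
  binary <- all(y %in% c(0, 1)) && length(unique(y)) == 2L
  # smooth terms only where a spline basis is identifiable
  terms <- vapply(covars, function(v) {
    if (length(unique(train[[v]])) >= 10L) paste0("s(", v, ")") else v
  }, character(1))
  fml <- stats::reformulate(terms, response = outcome)
  fit <- mgcv::gam(fml, data = train,
                   family = if (binary) stats::binomial() else
                     stats::gaussian())
  structure(
    list(fit = fit, covariates = covars, outcome = outcome,
         binary = binary),
    class = "ipd_predictor"
  )
}

#' @export
predict.ipd_predictor <- function(object, newdata, ...) {
  as.numeric(mgcv::predict.gam(object$fit, newdata = as.data.frame(newdata),
                               type = "response"))
}

#' @export
print.ipd_predictor <- function(x, ...) {
  cat("<ipd_predictor> ", if (x$binary) "binomial" else "gaussian",
      " additive smoother on ", paste(x$covariates, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Add predicted outcomes to a stacked table
#'
#' Fills a prediction column for every row of the table (training rows
#' included, for completeness) from a trained predictor.
#'
#' @param data A data frame with the predictor's covariate columns.
#' @param predictor An [train_predictor()] object, or any function mapping
#'   a data frame of covariates to a numeric vector.
#' @param col Name of the prediction column to create (default `"f"`).
#' @param overwrite Allow replacing an existing column of that name?
#'
#' @return `data` with the prediction column appended.
#' @export
add_predictions <- function(data, predictor, col = "f",
                            overwrite = FALSE) {
  data <- as.data.frame(data)
  if (col %in% names(data) && !overwrite) {
    stop("column `", col, "` already exists; set `overwrite = TRUE` to ",
         "replace it.", call. = FALSE)
  }
  preds <- if (inherits(predictor, "ipd_predictor")) {
    predict(predictor, data)
  } else if (is.function(predictor)) {
    predictor(data)
  } else {
    stop("`predictor` must be an ipd_predictor or a function.",
         call. = FALSE)
  }
  if (length(preds) != nrow(data) || !is.numeric(preds)) {
    stop("predictor did not return one numeric prediction per row.",
         call. = FALSE)
  }
  data[[col]] <- as.numeric(preds)
  data
}
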