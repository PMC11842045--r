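#' Replicated simulation benchmark of the IPD methods
#'
#' Runs the full evaluation pipeline `reps` times: simulate a stacked
#' dataset ([simdat()]), train the smoother on the training block
#' ([train_predictor()]), predict on the labeled and unlabeled blocks
#' ([add_predictions()]), drop the training rows, and fit the three
#' benchmark regressions ([benchmark_fit()]) alongside each requested
#' correction method for the linear-regression estimand.  For every fit the
#' coefficient of `term` is recorded with its confidence interval, whether
#' the interval covers the generating value `beta1`, and its width.
#'
#' A master seed spawns independent per-replicate seeds, so the whole
#' experiment is reproducible and individual replicates can be re-run in
#' isolation.  A replicate in which some fit fails is recorded (with its
#' seed) and the run continues.
#'
#' @param reps Number of simulation replicates.
#' @param n_train,n_labeled,n_unlabeled,beta1,sigma_y Passed to [simdat()].
#' @param methods Correction methods to evaluate.
#' @param benchmarks Reference fits to evaluate (subset of `"oracle"`,
#'   `"naive"`, `"classic"`).
#' @param alpha Significance level.
#' @param nboot Bootstrap replicates for `postpi_boot`.
#' @param term Coefficient to track (default `"X1"`, the linear target).
#' @param seed Master seed.
#' @param progress Print a progress line every 100 replicates?
#'
#' @return An object of class `"ipd_benchmark"`: a list with `results`
#'   (one row per replicate x fit), `summary` (per-fit mean estimate,
#'   empirical coverage, mean interval width, replicate counts), `failures`,
#'   and the configuration.
#'
#' @examples
#' \donttest{
#' bm <- run_benchmark(reps = 5, n_train = 50, n_labeled = 50,
#'                     n_unlabeled = 200, nboot = 20, seed = 1)
#' bm$summary
#' }
#' @export
run_benchmark <- function(reps, n_train = 100, n_labeled = 100,
                          n_unlabeled = 1000, beta1 = 1, sigma_y = 4,
                          methods = c("postpi_boot", "ppi", "ppi_plusplus",
                                      "pspa"),
                          benchmarks = c("oracle", "naive", "classic"),
                          alpha = 0.05, nboot = 100, term = "X1",
                          seed = NULL, progress = FALSE) {
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) {
    stop("`reps` must be a positive integer.", call. = FALSE)
  }
  reps <- as.integer(reps)
  methods <- match.arg(methods, ipd_methods, several.ok = TRUE)
  benchmarks <- match.arg(benchmarks, c("oracle", "naive", "classic"),
                          several.ok = TRUE)
  if (is.null(seed)) seed <- sample.int(2147483629L, 1L)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483629L, reps)

  fits_wanted <- c(benchmarks, methods)
  rows <- vector("list", reps)
  failures <- list()

  for (r in seq_len(reps)) {
    seed_r <- rep_seeds[r]
    rec <- tryCatch(
      benchmark_replicate(seed_r, n_train, n_labeled, n_unlabeled, beta1,
                          sigma_y, methods, benchmarks, alpha, nboot, term),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1L]] <-
        list(replicate = r, seed = seed_r, error = conditionMessage(rec))
      next
    }
    if (length(rec$failed)) {
      for (nm in names(rec$failed)) {
        failures[[length(failures) + 1L]] <-
          list(replicate = r, seed = seed_r,
               error = paste0(nm, ": ", rec$failed[[nm]]))
      }
    }
    rec$table$replicate <- r
    rec$table$seed <- seed_r
    rows[[r]] <- rec$table
    if (progress && r %% 100L == 0L) {
      message("replicate ", r, "/", reps)
    }
  }

  results <- do.call(rbind, rows)
  results <- tibble::as_tibble(results)
  summary <- do.call(rbind, lapply(fits_wanted, function(nm) {
    sub <- results[results$fit == nm, , drop = FALSE]
    data.frame(
      fit = nm,
      mean_estimate = mean(sub$estimate),
      mean_se = mean(sub$std.error),
      coverage = mean(sub$covered),
      mean_width = mean(sub$width),
      n_reps = nrow(sub),
      stringsAsFactors = FALSE
    )
  }))
  summary <- tibble::as_tibble(summary)

  structure(
    list(results = results, summary = summary, failures = failures,
         config = list(reps = reps, n_train = n_train,
                       n_labeled = n_labeled, n_unlabeled = n_unlabeled,
                       beta1 = beta1, sigma_y = sigma_y, alpha = alpha,
                       nboot = nboot, term = term, seed = seed)),
    class = "ipd_benchmark"
  )
}

benchmark_replicate <- function(seed_r, n_train, n_labeled, n_unlabeled,
                                beta1, sigma_y, methods, benchmarks, alpha,
                                nboot, term) {
  dat <- simdat(n_train = n_train, n_labeled = n_labeled,
                n_unlabeled = n_unlabeled, beta1 = beta1,
                sigma_y = sigma_y, seed = seed_r)
  predictor <- train_predictor(dat)
  dat <- add_predictions(dat, predictor)
  ds <- suppressMessages(
    ipd_data(Y - f ~ X1 + X2 + X3 + X4, data = dat, label = "set_label")
  )

  fit_one <- function(nm) {
    switch(nm,
      oracle = ,
      naive = ,
      classic = benchmark_fit(nm, ds, model = "ols", alpha = alpha),
      postpi_analytic = postpi_analytic(ds, alpha = alpha),
      postpi_boot = postpi_boot(ds, alpha = alpha, nboot = nboot,
                                seed = derive_seed(seed_r, 5e8)),
      ppi = ppi(ds, model = "ols", alpha = alpha),
      ppi_plusplus = ppi_plusplus(ds, model = "ols", alpha = alpha),
      pspa = pspa(ds, model = "ols", alpha = alpha)
    )
  }

  out <- list()
  failed <- list()
  for (nm in c(benchmarks, methods)) {
    fit <- tryCatch(fit_one(nm), error = function(e) e)
    if (inherits(fit, "error")) {
      failed[[nm]] <- conditionMessage(fit)
      next
    }
    est <- unname(fit$coefficients[term])
    se <- unname(fit$std_errors[term])
    lo <- unname(fit$ci_lower[term])
    hi <- unname(fit$ci_upper[term])
    out[[nm]] <- data.frame(
      fit = nm, estimate = est, std.error = se, conf.low = lo,
      conf.high = hi, covered = (lo <= beta1 && beta1 <= hi),
      width = hi - lo, stringsAsFactors = FALSE
    )
  }
  list(table = do.call(rbind, out), failed = failed)
}

#' @export
print.ipd_benchmark <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat("IPD simulation benchmark: ", cfg$reps, " replicates, ",
      cfg$n_train, "/", cfg$n_labeled, "/", cfg$n_unlabeled,
      " training/labeled/unlabeled, beta1 = ", cfg$beta1,
      ", sigma_y = ", cfg$sigma_y, "\n", sep = "")
  if (length(x$failures)) {
    cat(length(x$failures), "recorded failure(s)\n")
  }
  cat("\n")
  print(as.data.frame(lapply(x$summary, function(col) {
    if (is.numeric(col)) round(col, digits) else col
  })), row.names = FALSE)
  invisible(x)
}
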