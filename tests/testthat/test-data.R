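make_tables <- function(n = 3, N = 2, seed = 5) {
  set.seed(seed)
  lab <- data.frame(Y = rnorm(n), f = rnorm(n), X1 = rnorm(n),
                    X2 = rnorm(n), junk = letters[seq_len(n)])
  unl <- data.frame(f = rnorm(N), X1 = rnorm(N), X2 = rnorm(N),
                    junk = letters[seq_len(N)])
  list(lab = lab, unl = unl)
}

test_that("separate mode counts labeled and unlabeled rows", {
  tb <- make_tables(3, 2)
  ds <- ipd_data(Y - f ~ X1 + X2, tb$lab, unlabeled_data = tb$unl)
  expect_s3_class(ds, "ipd_data")
  expect_identical(ds$n_labeled, 3L)
  expect_identical(ds$n_unlabeled, 2L)
  expect_identical(colnames(ds$features), c("X1", "X2"))
})

test_that("stacked and separate modes built from the same rows agree", {
  tb <- make_tables(6, 9)
  stacked <- rbind(
    cbind(tb$lab[setdiff(names(tb$lab), "junk")], set = "labeled"),
    cbind(Y = NA_real_, tb$unl[setdiff(names(tb$unl), "junk")],
          set = "unlabeled")
  )
  ds_sep <- ipd_data(Y - f ~ X1 + X2, tb$lab, unlabeled_data = tb$unl)
  ds_stk <- ipd_data(Y - f ~ X1 + X2, stacked, label = "set")
  for (field in c("prediction", "features", "set_labeled", "n_labeled",
                  "n_unlabeled")) {
    expect_equal(ds_sep[[field]], ds_stk[[field]])
  }
  # outcomes agree on labeled rows (unlabeled truths absent in both)
  expect_equal(ds_sep$outcome[ds_sep$set_labeled],
               ds_stk$outcome[ds_stk$set_labeled])
})

test_that("splitting a stacked dataset by its indicator recovers the blocks", {
  tb <- make_tables(4, 7)
  ds <- ipd_data(Y - f ~ X1 + X2, tb$lab, unlabeled_data = tb$unl)
  expect_equal(ds$outcome[ds$set_labeled], tb$lab$Y)
  expect_equal(ds$prediction[ds$set_labeled], tb$lab$f)
  expect_equal(ds$prediction[!ds$set_labeled], tb$unl$f)
  expect_equal(unname(ds$features[!ds$set_labeled, "X2"]), tb$unl$X2)
})

test_that("set-indicator conventions: 0/1, logical, strings, training rows", {
  base <- data.frame(Y = c(1, 2, 3, NA, NA), f = rnorm(5), X1 = rnorm(5))
  for (set in list(c(1, 1, 1, 0, 0),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   c("Labeled", "labeled", "TRUE", "unlabeled", "no"))) {
    d <- base
    d$Y[4:5] <- NA
    d$set <- set
    ds <- ipd_data(Y - f ~ X1, d, label = "set")
    expect_identical(ds$n_labeled, 3L)
    expect_identical(ds$n_unlabeled, 2L)
  }

  d <- base
  d$set <- c("training", "labeled", "labeled", "unlabeled", "unlabeled")
  d$Y[1] <- 99 # training outcome, must be discarded with the row
  expect_message(ds <- ipd_data(Y - f ~ X1, d, label = "set"),
                 "1 training row")
  expect_identical(ds$n_labeled, 2L)

  d$set[1] <- "mystery"
  expect_error(ipd_data(Y - f ~ X1, d, label = "set"), "unrecognized")
})

test_that("usage and validation errors fire", {
  tb <- make_tables()
  # both or neither of label / unlabeled_data
  expect_error(ipd_data(Y - f ~ X1, tb$lab), "exactly one")
  tb$lab$set <- "labeled"
  expect_error(ipd_data(Y - f ~ X1, tb$lab, unlabeled_data = tb$unl,
                        label = "set"), "exactly one")
  # missing outcome on a labeled row
  bad <- tb$lab
  bad$Y[2] <- NA
  expect_error(ipd_data(Y - f ~ X1, bad, unlabeled_data = tb$unl),
               "missing outcome")
  # NA in a referenced feature is a hard error, not a dropped row
  bad <- tb$unl
  bad$X1[1] <- NA
  expect_error(ipd_data(Y - f ~ X1, tb$lab, unlabeled_data = bad),
               "missing value")
  # zero labeled rows
  expect_error(ipd_data(Y - f ~ X1, tb$lab[0, ], unlabeled_data = tb$unl),
               "at least one labeled")
  # unresolved column
  expect_error(ipd_data(Y - f ~ X9, tb$lab, unlabeled_data = tb$unl),
               "X9")
})

test_that("unreferenced columns are dropped, unlabeled outcomes retained", {
  tb <- make_tables()
  tb$unl$Y <- c(10, 20)
  ds <- ipd_data(Y - f ~ X1 + X2, tb$lab, unlabeled_data = tb$unl)
  expect_false("junk" %in% c(colnames(ds$features), names(ds)))
  expect_equal(ds$outcome[!ds$set_labeled], c(10, 20))
})

test_that("design matrices have intercept first and formula-ordered columns", {
  tb <- make_tables(5, 4)
  ds <- ipd_data(Y - f ~ X2 + X1, tb$lab, unlabeled_data = tb$unl)
  X <- build_design(ds, "labeled")
  expect_identical(colnames(X), c("(Intercept)", "X2", "X1"))
  expect_identical(dim(X), c(5L, 3L))
  expect_true(all(X[, 1] == 1))
  expect_identical(nrow(build_design(ds, "all")), 9L)

  ds1 <- ipd_data(Y - f ~ 1, tb$lab, unlabeled_data = tb$unl)
  X1 <- build_design(ds1, "labeled")
  expect_identical(ncol(X1), 1L)
  expect_true(all(X1 == 1))

  ds0 <- ipd_data(Y - f ~ X1, tb$lab, unlabeled_data = tb$unl[0, ])
  expect_error(build_design(ds0, "unlabeled"), "no unlabeled rows")
})

test_that("delimited reading round-trips with write.csv", {
  tb <- make_tables()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tb$lab, path, row.names = FALSE)
  back <- read_ipd_data(path)
  expect_equal(back$Y, tb$lab$Y)
  expect_error(read_ipd_data("x.weird"), "delimiter")
})

test_that("a YAML config drives a complete fit", {
  skip_if_not_installed("yaml")
  dir <- withr::local_tempdir()
  tb <- make_tables(30, 80, seed = 3)
  utils::write.csv(tb$lab, file.path(dir, "lab.csv"), row.names = FALSE)
  utils::write.csv(tb$unl, file.path(dir, "unl.csv"), row.names = FALSE)
  writeLines(c(
    "formula: Y - f ~ X1 + X2",
    "data: lab.csv",
    "unlabeled_data: unl.csv",
    "method: ppi",
    "model: ols",
    "alpha: 0.1"
  ), file.path(dir, "cfg.yml"))
  fit <- ipd_from_config(file.path(dir, "cfg.yml"))
  expect_s3_class(fit, "ipd_fit")
  expect_identical(fit$method, "ppi")
  expect_identical(fit$alpha, 0.1)
})
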