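test_that("the mean rectifier matches the hand-computed closed form", {
  dat <- data.frame(
    Y = c(1, 2, 3, NA, NA), f = c(1, 1, 1, 2, 2),
    set = c(1, 1, 1, 0, 0)
  )
  ds <- suppressMessages(ipd_data(Y - f ~ 1, dat, label = "set"))
  fit <- ppi(ds, model = "mean")
  # mean(f_U) - mean(f_L - Y_L) = 2 - (0 - 1 - 2)/3 = 3
  expect_equal(unname(coef(fit)), 3, tolerance = 1e-12)
})

test_that("mean closed form agrees with a generic root-finding oracle", {
  for (seed in 1:6) {
    ds <- toy_ipd_data(n = 25, N = 90, seed = seed, formula = Y - f ~ 1)
    fit <- ppi(ds, model = "mean")
    yl <- ds$outcome[ds$set_labeled]
    fl <- ds$prediction[ds$set_labeled]
    fu <- ds$prediction[!ds$set_labeled]
    # oracle: solve the rectified estimating equation numerically
    g <- function(t) mean(fu - t) - (mean(fl - t) - mean(yl - t))
    root <- uniroot(g, interval = c(-100, 100), tol = 1e-14)$root
    expect_equal(unname(coef(fit)), root, tolerance = 1e-10)
  }
})

test_that("weight reductions recover classic and ppi exactly", {
  for (model in c("mean", "ols")) {
    fml <- if (model == "mean") Y - f ~ 1 else Y - f ~ X1 + X2
    ds <- toy_ipd_data(n = 40, N = 150, seed = 2, formula = fml)
    cl <- benchmark_fit("classic", ds, model = model)
    pp <- ppi(ds, model = model)

    l0 <- ppi_plusplus(ds, model = model, lambda = 0)
    expect_equal(coef(l0), coef(cl), tolerance = 1e-10)
    expect_equal(vcov(l0), vcov(cl), tolerance = 1e-10)
    l1 <- ppi_plusplus(ds, model = model, lambda = 1)
    expect_equal(coef(l1), coef(pp), tolerance = 1e-10)
    expect_equal(vcov(l1), vcov(pp), tolerance = 1e-10)

    w0 <- pspa(ds, model = model, omega = 0)
    expect_equal(coef(w0), coef(cl), tolerance = 1e-10)
    expect_equal(vcov(w0), vcov(cl), tolerance = 1e-10)
    w1 <- pspa(ds, model = model, omega = 1)
    expect_equal(coef(w1), coef(pp), tolerance = 1e-10)
    expect_equal(vcov(w1), vcov(pp), tolerance = 1e-10)
  }
})

test_that("perfect predictions leave only the unlabeled variance term", {
  ds <- toy_ipd_data(n = 30, N = 400, seed = 3)
  ds$prediction <- ds$outcome # zero rectifier everywhere
  fit <- ppi(ds, model = "ols")
  nv <- benchmark_fit("naive", ds, model = "ols")
  expect_equal(coef(fit), coef(nv), tolerance = 1e-8)
  expect_equal(unname(fit$intermediates$rectifier),
               rep(0, 3), tolerance = 1e-12)
  # variance collapses to roughly the naive (1/N) term
  expect_equal(unname(diag(vcov(fit))), unname(diag(vcov(nv))),
               tolerance = 1e-8)
})

test_that("uninformative predictions drive the tuning weight to zero", {
  set.seed(123)
  lams <- numeric(200)
  excess <- numeric(200)
  for (r in seq_len(200)) {
    n <- 60; N <- 240
    X1 <- rnorm(n + N)
    Y <- 1 + X1 + rnorm(n + N)
    f <- rnorm(n + N) # independent of everything
    dat <- data.frame(Y = Y, f = f, X1 = X1,
                      set = rep(c(1, 0), c(n, N)))
    ds <- suppressMessages(ipd_data(Y - f ~ X1, dat, label = "set"))
    tuned <- ppi_plusplus(ds, model = "ols")
    plain <- ppi(ds, model = "ols")
    lams[r] <- tuned$intermediates$lam
    excess[r] <- vcov(plain)["X1", "X1"] - vcov(tuned)["X1", "X1"]
  }
  expect_lt(mean(lams), 0.15)
  # tuning never hurts on average relative to the raw rectifier
  expect_gt(mean(excess), 0)
})

test_that("per-coordinate weights beat both classic and ppi variances", {
  set.seed(321)
  reps <- 300
  ests <- matrix(NA_real_, reps, 3,
                 dimnames = list(NULL, c("classic", "ppi", "pspa")))
  for (r in seq_len(reps)) {
    ds <- toy_ipd_data(n = 100, N = 1000, seed = 10000 + r,
                       pred_noise = 0.5)
    ests[r, 1] <- coef(benchmark_fit("classic", ds))["X1"]
    ests[r, 2] <- coef(ppi(ds))["X1"]
    ests[r, 3] <- coef(pspa(ds))["X1"]
  }
  v <- apply(ests, 2, var)
  mc_tol <- 1.15 # variance ratios, generous to Monte-Carlo error
  expect_lt(v["pspa"], v["classic"] * mc_tol)
  expect_lt(v["pspa"], v["ppi"] * mc_tol)
  # in this informative-prediction design the gain is real, not a tie
  expect_lt(v["pspa"], v["classic"])
})

test_that("rectified quantile and logistic fits recover their targets", {
  # quantile: large-n consistency against the generating distribution
  set.seed(55)
  n <- 300; N <- 3000
  Y <- rnorm(n + N, mean = 2, sd = 1.5)
  f <- Y + rnorm(n + N, sd = 0.5)
  dat <- data.frame(Y = Y, f = f, set = rep(c(1, 0), c(n, N)))
  ds <- suppressMessages(ipd_data(Y - f ~ 1, dat, label = "set"))
  for (m in list(ppi, pspa)) {
    fit <- m(ds, model = "quantile", q = 0.75)
    expect_equal(unname(coef(fit)), qnorm(0.75, 2, 1.5), tolerance = 0.15)
    expect_true(fit$ci_lower < coef(fit) && coef(fit) < fit$ci_upper)
  }

  # logistic: the mean over seeds recovers the generating coefficients
  coefs2 <- coefs3 <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    ds2 <- toy_binary_data(n = 200, N = 2000, seed = 70 + s)
    coefs2[s, ] <- coef(ppi(ds2, model = "logistic"))
    coefs3[s, ] <- coef(pspa(ds2, model = "logistic"))
  }
  # per-seed sampling SD is about 0.2, so the mean has SD about 0.06
  expect_equal(unname(colMeans(coefs2)), c(-0.3, 0.9), tolerance = 0.25)
  expect_equal(unname(colMeans(coefs3)), c(-0.3, 0.9), tolerance = 0.25)
})

test_that("corrections refuse to run without unlabeled rows", {
  dat <- data.frame(Y = rnorm(10), f = rnorm(10), X1 = rnorm(10))
  ds <- ipd_data(Y - f ~ X1, dat, unlabeled_data = dat[0, -1])
  expect_error(ppi(ds), "unlabeled")
  expect_error(pspa(ds), "unlabeled")
})
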