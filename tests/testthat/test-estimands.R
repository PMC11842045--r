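test_that("scores have their roots at the population targets", {
  expect_equal(
    unname(drop(est_score(estimand_spec("mean"), 2, matrix(1), 2))), 0
  )
  expect_equal(
    unname(drop(est_score(estimand_spec("quantile", q = 0.5), 1,
                          matrix(1), 3))),
    0.5
  )
  x <- c(1, -2)
  expect_equal(
    drop(est_score(estimand_spec("logistic"), 1, rbind(x), c(0, 0))),
    x * 0.5
  )
  expect_error(est_score(estimand_spec("ols"), 1, rbind(x), 1),
               "length")
})

test_that("solvers reduce to closed forms", {
  ones <- matrix(1, 3, 1)
  expect_equal(unname(solve_m_estimate(estimand_spec("ols"), c(1, 2, 3),
                                       ones)), 2)
  expect_equal(unname(solve_m_estimate(estimand_spec("quantile", q = 0.5),
                                       c(3, 1, 2), ones)), 2)
  # inverted-CDF convention: ties and plateaus resolve to the smaller value
  expect_equal(unname(solve_m_estimate(estimand_spec("quantile", q = 0.5),
                                       c(1, 2, 3, 4), matrix(1, 4, 1))), 2)
  expect_equal(unname(solve_m_estimate(estimand_spec("mean"), c(0, 10),
                                       matrix(1, 2, 1), weights = c(3, 1))),
               2.5)
})

test_that("logistic solver agrees with a brute-force likelihood oracle", {
  set.seed(8)
  n <- 60
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 - 0.8 * x))
  X <- cbind(1, x)
  theta <- solve_m_estimate(estimand_spec("logistic"), y, X)

  # independent oracle: direct maximization of the Bernoulli likelihood
  nll <- function(b) -sum(y * (X %*% b) - log(1 + exp(X %*% b)))
  oracle <- optim(c(0, 0), nll, method = "BFGS",
                  control = list(reltol = 1e-14))$par
  expect_equal(unname(theta), oracle, tolerance = 1e-6)

  expect_error(solve_m_estimate(estimand_spec("logistic"), y + 1, X),
               "0/1")
})

test_that("solver roots drive the mean score to zero", {
  set.seed(21)
  n <- 50
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- rnorm(n, drop(X %*% c(1, 2, -1)))
  yb <- rbinom(n, 1, 0.5)
  cases <- list(
    list(est = estimand_spec("mean"), y = y, X = X[, 1, drop = FALSE]),
    list(est = estimand_spec("ols"), y = y, X = X),
    list(est = estimand_spec("logistic"), y = yb, X = X)
  )
  for (cs in cases) {
    theta <- solve_m_estimate(cs$est, cs$y, cs$X)
    score <- colMeans(est_score(cs$est, cs$y, cs$X, theta))
    expect_lt(sqrt(sum(score^2)), 1e-8)
  }
})

test_that("sandwich variance matches direct formula oracles", {
  set.seed(31)
  # mean: uncentered second moment of deviations over n^2
  y <- rnorm(20, 5, 2)
  V <- sandwich_vcov(estimand_spec("mean"), y, matrix(1, 20, 1), mean(y))
  expect_equal(drop(V), sum((y - mean(y))^2) / 20^2, tolerance = 1e-12)

  # ols: textbook HC0 on random fixtures
  for (rep in 1:5) {
    n <- 30 + 10 * rep
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    y <- drop(X %*% c(1, -1, 2)) + rnorm(n) * (1 + abs(X[, 2]))
    est <- estimand_spec("ols")
    theta <- solve_m_estimate(est, y, X)
    V <- sandwich_vcov(est, y, X, theta)
    e <- y - drop(X %*% theta)
    bread <- solve(crossprod(X))
    hc0 <- bread %*% crossprod(X * e) %*% bread
    expect_equal(unname(V), unname(hc0), tolerance = 1e-10)
  }

  # quantile: q(1-q) / (n * density^2) plug-in
  set.seed(32)
  y <- rnorm(400)
  est <- estimand_spec("quantile", q = 0.25)
  theta <- solve_m_estimate(est, y, matrix(1, 400, 1))
  V <- sandwich_vcov(est, y, matrix(1, 400, 1), theta)
  bw <- bw.nrd0(y)
  dens <- mean(dnorm((theta - y) / bw)) / bw
  plug <- 0.25 * 0.75 / (400 * dens^2)
  expect_equal(drop(V), plug, tolerance = 1e-6)
})

test_that("sandwich variance is symmetric PSD on random fits", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(25:80, 1)
    X <- cbind(1, rnorm(n))
    y <- drop(X %*% c(0.5, 1)) + rt(n, df = 4)
    est <- estimand_spec("ols")
    V <- sandwich_vcov(est, y, X, solve_m_estimate(est, y, X))
    expect_equal(V, t(V), tolerance = 1e-8)
    expect_gte(min(eigen(V, symmetric = TRUE)$values), -1e-8)
  }
})

test_that("mean and ols estimates are equivariant under outcome scaling", {
  set.seed(41)
  n <- 40
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  for (model in c("mean", "ols")) {
    est <- estimand_spec(model)
    Xm <- if (model == "mean") X[, 1, drop = FALSE] else X
    t1 <- solve_m_estimate(est, y, Xm)
    t2 <- solve_m_estimate(est, 3 * y, Xm)
    expect_equal(unname(t2), 3 * unname(t1), tolerance = 1e-10)
    expect_equal(unname(sandwich_vcov(est, 3 * y, Xm, t2)),
                 9 * unname(sandwich_vcov(est, y, Xm, t1)),
                 tolerance = 1e-8)
  }
})

test_that("estimated quantiles are nondecreasing in q", {
  set.seed(51)
  y <- rexp(75)
  ones <- matrix(1, 75, 1)
  qs <- seq(0.05, 0.95, by = 0.05)
  fits <- vapply(qs, function(q) {
    unname(solve_m_estimate(estimand_spec("quantile", q = q), y, ones))
  }, numeric(1))
  expect_true(all(diff(fits) >= 0))
})

test_that("benchmark fits use the right rows and flag the impossible", {
  ds <- toy_ipd_data(n = 30, N = 100, seed = 9)
  cl <- benchmark_fit("classic", ds)
  expect_identical(unname(cl$n_used), c(30L, 0L))
  or <- benchmark_fit("oracle", ds)
  expect_identical(unname(or$n_used), c(0L, 100L))

  # with perfect predictions the naive fit IS the oracle fit
  ds2 <- toy_ipd_data(n = 20, N = 60, seed = 10, pred_noise = 0)
  ds2$prediction <- ds2$outcome # f == Y everywhere
  nv <- benchmark_fit("naive", ds2)
  or2 <- benchmark_fit("oracle", ds2)
  expect_equal(coef(nv), coef(or2), tolerance = 1e-12)

  # oracle without unlabeled truths is a capability error
  ds3 <- ds
  ds3$outcome[!ds3$set_labeled] <- NA_real_
  expect_error(benchmark_fit("oracle", ds3), "true outcomes")

  # too few labeled rows for the parameter count is a rank error
  ds4 <- toy_ipd_data(n = 2, N = 50, seed = 11)
  expect_error(benchmark_fit("classic", ds4), "too few rows")
})

test_that("estimand specification is validated", {
  expect_error(estimand_spec("quantile"), "`q`")
  expect_error(estimand_spec("quantile", q = 1.2), "inside \\(0, 1\\)")
  expect_error(estimand_spec("mean", q = 0.5), "only meaningful")
})
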