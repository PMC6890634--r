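test_that("the Gaussian kernel has the textbook geometry", {
  expect_equal(rbf_kernel(c(0.2, 0.3, 0.1, 0.9), c(0.2, 0.3, 0.1, 0.9), 0.4), 1)

  # activation at distance h equals exp(-0.8326^2) ~ 0.5
  expect_equal(rbf_kernel(c(0.3, 0), c(0, 0), h = 0.3), exp(-0.8326^2))
  expect_lt(abs(rbf_kernel(c(0.3, 0), c(0, 0), h = 0.3) - 0.5), 1e-4)

  # essentially dead at ten spreads
  expect_lt(rbf_kernel(c(1, 0), c(0, 0), h = 0.1), 1e-20)

  # symmetry, monotone decay, wide-kernel limit
  a <- runif(4)
  b <- runif(4)
  expect_equal(rbf_kernel(a, b, 0.5), rbf_kernel(b, a, 0.5))
  d <- seq(0.1, 1, by = 0.1)
  vals <- vapply(d, function(x) rbf_kernel(c(x, 0), c(0, 0), 0.3), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_gt(rbf_kernel(c(1, 1), c(0, 0), h = 1e6), 1 - 1e-9)

  expect_error(rbf_kernel(a, b, 0), "positive")
  expect_error(rbf_kernel(a, b[1:3], 0.1), "equal length")
})

test_that("prediction evaluates the weighted kernel sum exactly", {
  sc <- treatment_scaler()

  # bias-only network is constant
  m0 <- manual_rbf(NULL, numeric(0), bias = 7.5, spread = 0.3, scaler = sc)
  x <- chrysanthemum_treatments()[c(1, 40, 81), ]
  expect_equal(predict(m0, x), rep(7.5, 3))

  # one center with weight w and bias 0 predicts w at the center
  ctr <- matrix(c(2.22, 0.25, 0.2, 87.64), 1)
  m1 <- manual_rbf(ctr, weights = 3.2, bias = 0, spread = 0.25, scaler = sc)
  expect_equal(predict(m1, ctr), 3.2)

  # two-center network vs. independent hand evaluation of the kernel sum
  ctrs <- rbind(c(0, 0, 0, 43.82), c(4.44, 0.49, 0.4, 131.46))
  w <- c(1.7, -0.9)
  m2 <- manual_rbf(ctrs, w, bias = 0.4, spread = 0.37, scaler = sc)
  probe <- matrix(c(2.22, 0.25, 0.2, 87.64), 1)
  ps <- scale_factors(sc, probe)
  cs <- scale_factors(sc, ctrs)
  by_hand <- 0.4 +
    w[1] * exp(-(sqrt(sum((ps - cs[1, ])^2)) * 0.8326 / 0.37)^2) +
    w[2] * exp(-(sqrt(sum((ps - cs[2, ])^2)) * 0.8326 / 0.37)^2)
  expect_equal(predict(m2, probe), by_hand)

  # linearity in the weights for fixed centers, spread and zero bias
  m_a <- manual_rbf(ctrs, c(1, 0), 0, 0.37, sc)
  m_b <- manual_rbf(ctrs, c(0, 1), 0, 0.37, sc)
  m_ab <- manual_rbf(ctrs, 2 * c(1, 0) + 5 * c(0, 1), 0, 0.37, sc)
  xs <- chrysanthemum_treatments()[seq(1, 81, by = 8), ]
  expect_equal(
    predict(m_ab, xs), 2 * predict(m_a, xs) + 5 * predict(m_b, xs)
  )
})

test_that("fitting interpolates distinct points in the all-centers limit", {
  withr::local_seed(31)
  n <- 25
  df <- tibble::tibble(
    bap_uM = runif(n, 0, 4.44), iba_uM = runif(n, 0, 0.49),
    pg_mM = runif(n, 0, 0.4), sucrose_mM = runif(n, 43.82, 131.46),
    sl = runif(n, 1, 6)
  )
  fit <- rbf_fit(df, "sl", control = rbf_control(
    spread_grid = 0.02, max_centers = n, ridge = 1e-12
  ))
  expect_equal(nrow(fit$centers), n)
  expect_lt(max(abs(predict(fit, df) - df$sl)), 1e-6)
})

test_that("fitting recovers a known RBF surface", {
  withr::local_seed(77)
  n <- 240
  X <- tibble::tibble(
    bap_uM = runif(n, 0, 4.44), iba_uM = runif(n, 0, 0.49),
    pg_mM = runif(n, 0, 0.4), sucrose_mM = runif(n, 43.82, 131.46)
  )
  sc <- fit_scaler(X)
  truth <- manual_rbf(
    rbind(
      c(1.1, 0.1, 0.1, 60), c(3.3, 0.4, 0.3, 110), c(2.2, 0.25, 0.2, 87)
    ),
    weights = c(2, -1.5, 3), bias = 1, spread = 0.5, scaler = sc
  )
  X$y <- predict(truth, X)
  test_idx <- seq(1, n, by = 4)
  train <- X[-test_idx, ]
  test <- X[test_idx, ]
  fit <- rbf_fit(train, "y", control = rbf_control(
    spread_grid = 0.5, max_centers = 150
  ))
  rmse <- sqrt(mean((predict(fit, test) - test$y)^2))
  expect_lt(rmse, 0.01 * sd(X$y))

  # a constant target is absorbed by the bias: zero error everywhere
  train$y <- 4.2
  cfit <- rbf_fit(train, "y", control = rbf_control(
    spread_grid = 0.5, max_centers = 10
  ))
  expect_lt(max(abs(predict(cfit, test) - 4.2)), 1e-8)
})

test_that("cross-validation folds are balanced, seeded and spread-selective", {
  reps <- simulate_replicates(chrysanthemum_treatments(), 9, seed = 3)
  ctl <- rbf_control(seed = 5)
  sc <- fit_scaler(reps)
  Xs <- scale_factors(sc, reps)

  # fold sizes for 729 records in 5 folds: 146 x 4 + 145
  fold <- withr::with_seed(5, sample(rep(1:5, length.out = 729)))
  expect_equal(sort(as.vector(table(fold)), decreasing = TRUE),
               c(146, 146, 146, 146, 145))

  # exported mean-CV value is an average of per-fold MSEs and is seeded
  v1 <- rbf_cv_mse(reps, "sl", 0.2, ctl)
  v2 <- rbf_cv_mse(reps, "sl", 0.2, ctl)
  expect_equal(v1, v2)
  expect_gt(v1, 0)

  # leave-one-out boundary: k = n single-record folds
  small <- reps[1:10 * 70, ]
  ctl_loo <- rbf_control(k_folds = 10, spread_grid = 0.3, seed = 1,
                         max_centers = 5)
  expect_silent(rbf_cv_mse(small, "sl", 0.3, ctl_loo))
  expect_error(
    rbf_cv_mse(small[1:4, ], "sl", 0.3, rbf_control(k_folds = 10)),
    "exceeds"
  )

  # CV recovers the generating spread's neighborhood on synthetic data
  withr::local_seed(13)
  n <- 300
  syn <- tibble::tibble(
    bap_uM = runif(n, 0, 4.44), iba_uM = runif(n, 0, 0.49),
    pg_mM = runif(n, 0, 0.4), sucrose_mM = runif(n, 43.82, 131.46)
  )
  scs <- fit_scaler(syn)
  gen <- manual_rbf(
    rbind(c(1, 0.1, 0.1, 60), c(3.5, 0.4, 0.35, 120)),
    weights = c(3, 2), bias = 0, spread = 0.4, scaler = scs
  )
  syn$y <- predict(gen, syn) + rnorm(n, 0, 0.05)
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  ctl_syn <- rbf_control(spread_grid = grid, max_centers = 30, seed = 2)
  cvs <- vapply(grid, function(h) rbf_cv_mse(syn, "y", h, ctl_syn),
                numeric(1))
  expect_true(grid[which.min(cvs)] %in% c(0.2, 0.4, 0.8))
})

test_that("spread selection is deterministic and avoids unstable solves", {
  reps <- small_replicates(seed = 9)
  ctl <- rbf_control(seed = 21)
  f1 <- rbf_fit(reps, "sn", control = ctl)
  f2 <- rbf_fit(reps, "sn", control = ctl)
  expect_equal(f1$spread, f2$spread)
  expect_equal(f1$weights, f2$weights)
  expect_equal(predict(f1, reps), predict(f2, reps))

  # the selected fit's normal equations respect the conditioning cap
  A <- cbind(1, mediumopt:::kernel_matrix(
    scale_factors(f1$scaler, reps), f1$centers, f1$spread
  ))
  expect_lte(kappa(A, exact = FALSE)^2, ctl$kappa_max * 1.01)
})

test_that("goodness-of-fit metrics match their definitions", {
  y <- c(1, 2, 3, 4)
  m <- regression_metrics(y, y)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mbe, 0)
  expect_equal(m$signed_bias, 0)

  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0)

  # hand arithmetic; constant observations leave R2 undefined but the
  # error metrics intact
  expect_warning(
    m2 <- regression_metrics(c(0, 0), c(3, 4)),
    "zero variance"
  )
  expect_true(is.na(m2$r2))
  expect_equal(m2$rmse, sqrt(25 / 2))
  expect_equal(m2$mbe, 3.5)
  expect_equal(m2$signed_bias, -3.5)

  # R2 invariant under common affine maps; RMSE bounds the signed bias
  withr::local_seed(2)
  yo <- rnorm(50)
  yp <- yo + rnorm(50, 0.2, 0.5)
  a <- regression_metrics(yo, yp)
  b <- regression_metrics(3 * yo + 7, 3 * yp + 7)
  expect_equal(a$r2, b$r2)
  expect_gte(a$rmse, abs(a$signed_bias))

  expect_error(regression_metrics(1:3, 1:4), "equal length")
  expect_warning(regression_metrics(rep(1, 3), 1:3), "zero variance")
})

test_that("fitted networks survive a JSON round-trip", {
  reps <- small_replicates(seed = 15)
  fit <- rbf_fit(reps, "bcw", control = rbf_control(
    spread_grid = 0.3, max_centers = 20
  ))
  path <- withr::local_tempfile(fileext = ".json")
  write_rbf(fit, path)
  back <- read_rbf(path)
  probe <- chrysanthemum_treatments()[seq(2, 80, by = 7), ]
  expect_equal(predict(back, probe), predict(fit, probe), tolerance = 1e-12)
  expect_equal(back$response, "bcw")
})
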