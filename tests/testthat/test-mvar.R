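test_that("Vieira-Morf recovers scalar and vector AR coefficients", {
  set.seed(1)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 1e4))
  f1 <- fit_mvar_vieira_morf(matrix(x, 1), 1)
  expect_equal(f1$A[1, 1, 1], 0.5, tolerance = 0.05)

  # long stationary bivariate VAR(1): agreement with least squares <= 1e-2
  A <- array(matrix(c(0.5, 0.3, 0.0, 0.4), 2, 2), c(2, 2, 1))
  X <- simulate_var(A, 1e4, seed = 2)
  fv <- fit_mvar_vieira_morf(X, 1)
  Y <- t(X[, 2:1e4]); Z <- t(X[, 1:(1e4 - 1)])
  ols <- t(solve(crossprod(Z), crossprod(Z, Y)))
  expect_lt(max(abs(fv$A[, , 1] - ols)), 1e-2)

  # order 0: just the sample covariance
  f0 <- fit_mvar_vieira_morf(X, 0)
  expect_equal(f0$Sigma,
               tcrossprod(X - rowMeans(X)) / ncol(X), tolerance = 1e-12)
  expect_equal(dim(f0$A), c(2, 2, 0))

  # multi-trial pooling reproduces the same process
  arr <- array(X[, 1:9600], c(2, 96, 100))
  fm <- fit_mvar_vieira_morf(arr, 1)
  expect_lt(max(abs(fm$A[, , 1] - A[, , 1])), 0.05)
  expect_error(fit_mvar_vieira_morf(X[, 1:3, drop = FALSE], 5), "insufficient")
})

test_that("stability is read off the companion matrix", {
  mk <- function(A1) structure(
    list(order = 1L, A = array(A1, c(nrow(A1), nrow(A1), 1)),
         Sigma = diag(nrow(A1)), M = nrow(A1), fs = 128),
    class = "mvar_model")
  s1 <- check_stability(mk(matrix(0.5)))
  expect_true(s1$stable); expect_equal(s1$spectral_radius, 0.5)
  s2 <- check_stability(mk(matrix(1.1)))
  expect_false(s2$stable); expect_equal(s2$spectral_radius, 1.1)
  s3 <- check_stability(mk(matrix(c(0.5, 0, 0.3, 0.4), 2, 2)))
  expect_equal(s3$spectral_radius, 0.5)   # triangular: eigenvalues on diagonal
  # companion of an order-2 scalar model
  C <- companion_matrix(array(c(0.3, 0.1), c(1, 1, 2)))
  expect_equal(C, matrix(c(0.3, 1, 0.1, 0), 2, 2))
})

test_that("portmanteau statistics match direct formula evaluation", {
  set.seed(3)
  e <- stats::rnorm(200)
  wr <- test_whiteness(matrix(e, 1), h = 6, alpha = 0.05)
  ec <- e - mean(e)
  n <- length(ec)
  r <- vapply(1:6, function(k) sum(ec[(k + 1):n] * ec[1:(n - k)]) / sum(ec^2), 0)
  q_lb <- n * (n + 2) * sum(r^2 / (n - 1:6))
  q_bp <- n * sum(r^2)
  tab <- wr$table
  expect_equal(tab$Q[tab$test == "ljung_box"], q_lb, tolerance = 1e-9)
  expect_equal(tab$Q[tab$test == "box_pierce"], q_bp, tolerance = 1e-9)
  e2 <- ec^2 - mean(ec^2)
  r2 <- vapply(1:6, function(k) sum(e2[(k + 1):n] * e2[1:(n - k)]) / sum(e2^2), 0)
  q_ml <- n * (n + 2) * sum(r2^2 / (n - 1:6))
  expect_equal(tab$Q[tab$test == "mcleod_li"], q_ml, tolerance = 1e-9)
  expect_error(test_whiteness(matrix(e, 1), h = 2, p = 2), "exceed")
})

test_that("whiteness battery holds its level and detects AR residuals", {
  set.seed(4)
  rates <- rowMeans(replicate(300, {
    e <- matrix(stats::rnorm(1000), 1)
    !test_whiteness(e, h = 12, alpha = 0.05)$pass
  }))
  # Ljung-Box / Box-Pierce / McLeod-Li near nominal; ACF at or below
  expect_true(all(rates[1:3] > 0.01 & rates[1:3] < 0.10))
  expect_lt(rates[4], 0.06)

  power <- mean(replicate(60, {
    e <- matrix(as.numeric(stats::arima.sim(list(ar = 0.8), 1000)), 1)
    !test_whiteness(e, h = 12, alpha = 0.05)$pass["ljung_box"]
  }))
  expect_gte(power, 0.99)
})

test_that("information criteria match their formulas", {
  Sigma <- matrix(c(2, 0.3, 0.3, 1.5), 2, 2)
  ic <- information_criteria(Sigma, p = 3, n_eff = 500)
  ld <- log(det(Sigma))
  expect_equal(unname(ic["logdet"]), ld)
  expect_equal(unname(ic["aic"]), ld + 2 * 3 * 4 / 500)
  expect_equal(unname(ic["sbc"]), ld + 3 * 4 * log(500) / 500)
  expect_equal(unname(ic["hq"]), ld + 2 * 3 * 4 * log(log(500)) / 500)
})

test_that("order selection finds the generating order", {
  A <- array(0, c(3, 3, 2))
  A[, , 1] <- matrix(c(0.4, 0.1, 0, 0, 0.3, 0.2, 0.1, 0, 0.35), 3, 3)
  A[, , 2] <- matrix(c(0.3, 0, 0, 0.05, 0.25, 0, 0, 0.1, 0.3), 3, 3)
  hits <- vapply(1:5, function(s) {
    X <- simulate_var(A, 40 * 60, seed = s)
    arr <- array(X, c(3, 60, 40))
    sel <- select_model_order(arr, candidates = 1:6, alpha = 0.05)
    sel$order
  }, 0L)
  expect_gte(mean(hits == 2L), 0.8)
  expect_true(all(hits <= 3L))

  # white noise selects the smallest candidate
  set.seed(6)
  W <- array(stats::rnorm(2 * 50 * 30), c(2, 50, 30))
  selw <- select_model_order(W, candidates = 1:4, alpha = 0.05)
  expect_equal(selw$order, 1L)
  expect_true(selw$passed)
  expect_error(select_model_order(W, candidates = integer(0)), "empty")
})
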