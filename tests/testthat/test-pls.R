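test_that("rank-1 noiseless data is fitted exactly with one component", {
  withr::local_seed(41)
  y <- rnorm(12)
  v <- rnorm(30)
  X <- outer(y, v)
  m <- fit_pls1(X, y, n_lv = 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-10)
})

test_that("PLS1 at full rank reproduces ordinary least squares", {
  withr::local_seed(42)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  m <- fit_pls1(X, y, n_lv = 5)
  ols <- unname(coef(lm(y ~ X))[-1])
  expect_lt(max(abs(m$b - ols)), 1e-8)
})

test_that("regression vector identity and score orthogonality hold", {
  withr::local_seed(43)
  X <- matrix(rnorm(20 * 80), 20, 80)
  y <- rnorm(20)
  m <- fit_pls1(X, y, n_lv = 4)
  b2 <- drop(m$W %*% solve(crossprod(m$P, m$W), m$q))
  expect_lt(max(abs(m$b - b2)), 1e-8)
  # scores recomputed as T = Xc W (P'W)^-1 are mutually orthogonal
  Xc <- sweep(X, 2, m$x_mean)
  T <- Xc %*% m$W %*% solve(crossprod(m$P, m$W))
  G <- crossprod(T)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
})

test_that("training RMSE never increases with more components", {
  withr::local_seed(44)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  rmse <- vapply(1:8, function(a) {
    m <- fit_pls1(X, y, n_lv = a)
    sqrt(mean((predict(m, X) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("prediction follows the centering identity and a dot-product oracle", {
  withr::local_seed(45)
  X <- matrix(rnorm(15 * 20), 15, 20)
  y <- rnorm(15)
  m <- fit_pls1(X, y, n_lv = 3)
  # a sample equal to the training mean predicts the training mean of y
  expect_equal(unname(predict(m, matrix(m$x_mean, 1))), m$y_mean,
               tolerance = 1e-12)
  Xnew <- matrix(rnorm(4 * 20), 4, 20)
  oracle <- drop(sweep(Xnew, 2, m$x_mean) %*% m$b) + m$y_mean
  expect_lt(max(abs(predict(m, Xnew) - oracle)), 1e-12)
  expect_error(predict(m, Xnew[, 1:10]), "channels")
})

test_that("deflation stops early when no covariance is left", {
  y <- c(-1, 0, 1, 2)
  X <- cbind(y, y * 2)            # rank 1: only one component exists
  expect_warning(m <- fit_pls1(X, y, n_lv = 2), "no covariance")
  expect_equal(m$n_lv, 1L)
})

test_that("selectivity ratio ranks an informative channel above noise", {
  withr::local_seed(46)
  y <- rnorm(30)
  X <- cbind(y, matrix(rnorm(30 * 9), 30, 9))
  m <- fit_pls1(X, y, n_lv = 1)
  sr <- selectivity_ratio(m, sweep(X, 2, m$x_mean))
  expect_true(sr$sr[1] > max(sr$sr[-1]))
})

test_that("zero-variance channels get SR 0 and degenerate models error", {
  withr::local_seed(47)
  y <- rnorm(20)
  X <- cbind(matrix(rnorm(20 * 5), 20, 5), 0)  # constant last column
  m <- fit_pls1(X, y, n_lv = 2)
  sr <- selectivity_ratio(m, sweep(X, 2, m$x_mean))
  expect_identical(sr$sr[6], 0)
  m$b[] <- 0
  expect_error(selectivity_ratio(m, sweep(X, 2, m$x_mean)), "degenerate")
})

test_that("SR is invariant to a global positive rescaling of X", {
  withr::local_seed(48)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- rnorm(20)
  m1 <- fit_pls1(X, y, n_lv = 3)
  m2 <- fit_pls1(7.3 * X, y, n_lv = 3)
  s1 <- selectivity_ratio(m1, sweep(X, 2, m1$x_mean))
  s2 <- selectivity_ratio(m2, sweep(7.3 * X, 2, m2$x_mean))
  expect_equal(s1$sr, s2$sr, tolerance = 1e-8)
})

test_that("region selection keeps contiguous runs and falls back sanely", {
  sr <- structure(list(wavenumbers = 1:6, sr = c(0, 0, 5, 5, 5, 0),
                       explained_ss = rep(1, 6), residual_ss = rep(1, 6)),
                  class = "sr_profile")
  expect_equal(select_regions(sr, threshold = 1, min_width = 2),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  # runs shorter than min_width vanish (then the fallback warns and fires)
  expect_warning(m4 <- select_regions(sr, threshold = 1, min_width = 4),
                 "top decile")
  expect_false(any(m4[1:2]))
  low <- sr; low$sr <- rep(0.1, 6)
  expect_warning(mask <- select_regions(low, threshold = 1), "top decile")
  expect_true(any(mask))
  empty <- sr; empty$sr <- numeric(); empty$wavenumbers <- numeric()
  expect_error(select_regions(empty), "empty")
})

test_that("a band carrying the only unsaturation signal is selected", {
  # single composition-linked band at 3006; free-acid bands are nuisance
  pt <- rbind(
    peak_spec(3006, 10, 0.05, c(double_bond_index = 0.01)),
    peak_spec(1710, 12, 0.02, c(ffa_fraction = 0.06)),
    peak_spec(1745, 10, 0.25, c(ester_density = 0.004))
  )
  ds <- generate_dataset(synthetic_config(n_samples = 40, seed = 49,
                                          peak_table = pt,
                                          trend_slopes = c(MCFA = 0)))
  refs <- compute_sum_parameters(ds$profile)
  d <- savgol_derivative(ds$spectra)
  y <- refs$UNSAT
  m0 <- fit_pls1(d$absorbance, y, n_lv = 2,
                 wavenumbers = d$wavenumbers)
  sr <- selectivity_ratio(m0, sweep(d$absorbance, 2, m0$x_mean))
  mask <- select_regions(sr)
  expect_true(any(mask & abs(sr$wavenumbers - 3006) <= 10))
})
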