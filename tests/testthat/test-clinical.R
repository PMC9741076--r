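test_that("collinear points give an exact line with zero residual", {
  tr <- suppressWarnings(trend_vs_lactation(c(1, 2, 3), c(0, 1, 2)))
  expect_equal(tr$slope, 1)
  expect_equal(tr$intercept, 1)
  expect_equal(tr$n, 3)
})

test_that("slope, SE and p match the closed-form regression oracle", {
  withr::local_seed(81)
  d <- runif(40, 0, 400)
  y <- 30 + 0.01 * d + rnorm(40, sd = 2)
  tr <- trend_vs_lactation(y, d)
  # independent hand computation
  sxx <- sum((d - mean(d))^2)
  slope <- sum((d - mean(d)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) - slope * mean(d)) - slope * d
  se <- sqrt(sum(resid^2) / (40 - 2) / sxx)
  p <- 2 * pt(abs(slope / se), 40 - 2, lower.tail = FALSE)
  expect_equal(tr$slope, slope, tolerance = 1e-10)
  expect_equal(tr$se, se, tolerance = 1e-10)
  expect_equal(tr$p, p, tolerance = 1e-10)

  expect_error(trend_vs_lactation(y[1:2], d[1:2]), "at least 3")
  expect_error(trend_vs_lactation(y, rep(1, 40)), "zero variance")
  expect_error(trend_vs_lactation(y, d - 500), "nonnegative")
})

test_that("the slope test keeps its nominal type-I error", {
  withr::local_seed(82)
  reps <- 500
  p <- vapply(seq_len(reps), function(i) {
    d <- runif(100, 0, 400)
    trend_vs_lactation(rnorm(100), d)$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("group comparison reports both tests and matches a Welch oracle", {
  withr::local_seed(83)
  a <- rnorm(20); b <- rnorm(20)
  gc <- group_compare(c(a, b), rep(c(FALSE, TRUE), each = 20))
  # hand-computed Welch statistic
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 20 + var(b) / 20)
  expect_equal(gc$welch$statistic, tstat, tolerance = 1e-10)
  expect_equal(nrow(gc$summary), 2)
  expect_true(all(c("median", "iqr") %in% colnames(gc$summary)))

  same <- group_compare(rep(c(1, 2, 3, 4), 2), rep(c(TRUE, FALSE), each = 4))
  expect_equal(same$welch$statistic, 0, tolerance = 1e-12)
  expect_gt(same$welch$p, 0.99)

  shifted <- group_compare(c(rnorm(20), rnorm(20) + 5),
                           rep(c(FALSE, TRUE), each = 20))
  expect_lt(shifted$welch$p, 1e-3)
  expect_lt(shifted$rank_sum$p, 1e-3)

  expect_error(group_compare(1:5, c(TRUE, rep(FALSE, 4))), "at least 2")
  expect_error(group_compare(1:5, rep(TRUE, 5)), "2 groups")
})

test_that("covariate screen flags a planted association and skips degenerates", {
  withr::local_seed(84)
  n <- 60
  prof <- data.frame(sample_id = sprintf("s%02d", 1:n),
                     SAT = rnorm(n, 30, 3), MCFA = rnorm(n, 25, 3),
                     check.names = FALSE)
  clin <- data.frame(sample_id = prof$sample_id,
                     maternal_age = prof$SAT,      # covariate = target copy
                     gestational_age = rnorm(n, 39, 1.5),
                     infant_sex = rep("female", n),  # single level
                     birth_weight = NA_real_,        # all missing
                     stringsAsFactors = FALSE)
  suppressWarnings(expect_warning(expect_warning(
    sc <- covariate_screen(prof, clin),
    "single level"), "missing or all NA"))
  expect_lt(sc$p[sc$target == "SAT" & sc$covariate == "maternal_age"], 1e-20)
  expect_true(all(c("p_adj") %in% colnames(sc)))
  expect_false("infant_sex" %in% sc$covariate)
})

test_that("a null covariate is significant at roughly the nominal rate", {
  withr::local_seed(85)
  hits <- 0; total <- 0
  for (r in 1:30) {
    n <- 200
    prof <- data.frame(sample_id = seq_len(n), A = rnorm(n), B = rnorm(n),
                       C = rnorm(n), D = rnorm(n))
    clin <- data.frame(sample_id = seq_len(n), maternal_age = rnorm(n, 35, 5))
    sc <- covariate_screen(prof, clin, covariates = "maternal_age")
    hits <- hits + sum(sc$p < 0.05); total <- total + nrow(sc)
  }
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.10)
})

test_that("the full clinical analysis recovers the imposed lactation pattern", {
  fx <- pipeline_fixture()
  all_spec <- fx$ds$spectra
  prof <- predict_profile(fx$reg, all_spec)
  ca <- clinical_analysis(prof, fx$ds$clinical,
                          targets = c("MCFA", "LCFA", "PUFA", "SAT"))
  tr <- ca$trends
  expect_gt(tr$slope[tr$target == "MCFA"], 0)
  expect_lt(tr$slope[tr$target == "LCFA"], 0)
  expect_lt(tr$slope[tr$target == "PUFA"], 0)
  expect_lt(tr$p[tr$target == "MCFA"], 0.05)
  expect_false(is.null(ca$hop))
  expect_true(all(c("welch_p", "rank_sum_p") %in% colnames(ca$hop)))
})
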