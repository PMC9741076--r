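test_that("degenerate ranges give identical compositions with exact closure", {
  fas <- fa_constants()
  # fix every acid at a constant; constants sum to 90
  vals <- c(0.1, 1, 5, 6, 18, 0.9, 4, 35, 20)
  rng <- data.frame(name = fas$name, low = vals, high = vals)
  cfg <- synthetic_config(n_samples = 5, seed = 61, composition_ranges = rng)
  p <- sample_compositions(cfg)
  for (i in seq_along(fas$name)) {
    expect_equal(p[[fas$name[i]]], rep(vals[i], 5))
  }
  expect_equal(p$OTHER, rep(10, 5), tolerance = 1e-12)
})

test_that("default sampling honours ranges and closes each row to 100", {
  cfg <- synthetic_config(n_samples = 1000, seed = 62)
  p <- sample_compositions(cfg)
  fas <- fa_constants()
  for (i in seq_len(nrow(fas))) {
    v <- p[[fas$name[i]]]
    expect_gte(min(v), fas$low[i])
    expect_lte(max(v), fas$high[i])
  }
  expect_gte(min(p$OTHER), 0)
  sums <- rowSums(p[, c(fas$name, "OTHER")])
  expect_lt(max(abs(sums - 100)), 1e-9)
  # determinism
  expect_identical(p, sample_compositions(cfg))
})

test_that("infeasible ranges fail before any sampling", {
  fas <- fa_constants()
  rng <- data.frame(name = fas$name, low = rep(15, 9), high = rep(20, 9))
  cfg <- synthetic_config(n_samples = 2, seed = 1, composition_ranges = rng)
  expect_error(sample_compositions(cfg), "infeasible")
})

test_that("composition descriptors follow the defining arithmetic", {
  d <- composition_descriptors(composition_vec("C18:1cis" = 100))
  expect_equal(unname(d["double_bond_index"]), 100)
  expect_equal(unname(d["mean_chain_proxy"]), 18)

  d2 <- composition_descriptors(composition_vec("C16:0" = 100))
  expect_equal(unname(d2["double_bond_index"]), 0)
  expect_equal(unname(d2["mean_chain_proxy"]), 16)

  # 50/50 mono/di-unsaturated: 50*1 + 50*2 = 150
  d3 <- composition_descriptors(
    composition_vec("C18:1cis" = 50, "C18:2cis" = 50))
  expect_equal(unname(d3["double_bond_index"]), 150)

  expect_equal(unname(d3["ester_density"]), 98)  # default ffa 2
  bad <- composition_vec()[-1]
  expect_error(composition_descriptors(bad), "missing fatty acid")
})

test_that("rendering is local, centred on configured bands, and nonnegative", {
  wn <- seq(600, 4000, by = 2)
  d <- composition_descriptors(composition_vec("C18:1cis" = 40,
                                               "C16:0" = 20, "C18:2cis" = 30))
  expect_identical(render_spectrum(d, default_peak_table()[0, ], wn),
                   numeric(length(wn)))

  # noiseless peaks sit at their configured centres (isolated bands)
  pt <- default_peak_table()
  for (centre in c(720, 1745, 3006)) {
    row <- pt[pt$center == centre, ]
    spec <- render_spectrum(d, row, wn)
    expect_lte(abs(wn[which.max(spec)] - centre), 2)
  }

  full <- render_spectrum(d, pt, wn)
  expect_gte(min(full), 0)

  # changing only the unsaturation descriptor moves only unsaturation bands
  d2 <- d; d2["double_bond_index"] <- d["double_bond_index"] + 30
  delta <- abs(render_spectrum(d2, pt, wn) - render_spectrum(d, pt, wn))
  dbi_centers <- pt$center[vapply(pt$weights, function(w)
    "double_bond_index" %in% names(w), logical(1))]
  near <- Reduce(`|`, lapply(dbi_centers, function(cc) abs(wn - cc) < 80))
  expect_lt(max(delta[!near]), 1e-12)
  expect_gt(max(delta[near]), 1e-4)
})

test_that("negative band amplitudes are clamped with a warning", {
  pt <- peak_spec(1500, 10, 0.05, c(double_bond_index = -1))
  d <- composition_descriptors(composition_vec("C18:1cis" = 50))
  expect_warning(spec <- render_spectrum(d, pt, seq(1400, 1600, 2)),
                 "clamped")
  expect_identical(spec, numeric(101))
})

test_that("generated datasets are deterministic and structurally sound", {
  cfg <- synthetic_config(n_samples = 30, seed = 63)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$spectra$absorbance, ds2$spectra$absorbance)
  expect_identical(ds1$profile, ds2$profile)
  expect_identical(ds1$clinical, ds2$clinical)

  expect_equal(sum(ds1$clinical$hop), 15)   # half pasteurized
  expect_true(all(ds1$clinical$days_postpartum >= 5 &
                  ds1$clinical$days_postpartum <= 400))
  sums <- rowSums(ds1$profile[, c(fa_names(), "OTHER")])
  expect_lt(max(abs(sums - 100)), 1e-9)
})

test_that("zero trend slopes leave no recoverable day dependence", {
  cfg <- synthetic_config(n_samples = 200, seed = 64,
                          trend_slopes = c(MCFA = 0, LCFA = 0, PUFA = 0))
  ds <- generate_dataset(cfg)
  prof <- compute_sum_parameters(ds$profile)
  tr <- trend_vs_lactation(prof$MCFA, ds$clinical$days_postpartum)
  ci <- tr$slope + c(-1, 1) * qt(0.975, tr$n - 2) * tr$se
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("default trend slopes preserve closure along lactation", {
  ds <- generate_dataset(synthetic_config(n_samples = 100, seed = 65))
  sums <- rowSums(ds$profile[, c(fa_names(), "OTHER")])
  expect_lt(max(abs(sums - 100)), 1e-9)
  # MCFA drifts up, long-chain members down, by construction
  prof <- compute_sum_parameters(ds$profile)
  d <- ds$clinical$days_postpartum
  expect_gt(cor(prof$MCFA, d), 0)
  expect_lt(cor(prof$LCFA, d), 0)
})
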