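#' Modelled fatty acids
#'
#' The nine individually modelled fatty acids with carbon number, number
#' of double bonds, molecular weight (free acid, g/mol) and the default
#' composition ranges (g/100 g fat) typical of mature human milk fat.
#'
#' @return data.frame with columns `name`, `carbons`, `double_bonds`,
#'   `mw`, `low`, `high`.
#' @export
fa_constants <- function() {
  data.frame(
    name = c("C8:0", "C10:0", "C12:0", "C14:0", "C16:0",
             "C16:1cis", "C18:0", "C18:1cis", "C18:2cis"),
    carbons = c(8, 10, 12, 14, 16, 16, 18, 18, 18),
    double_bonds = c(0, 0, 0, 0, 0, 1, 0, 1, 2),
    mw = c(144.21, 172.26, 200.32, 228.37, 256.42,
           254.41, 284.48, 282.46, 280.45),
    low = c(0.0, 0.40, 1.1, 1.5, 12, 0.0, 1.8, 28, 16),
    high = c(0.15, 1.5, 7.2, 7.9, 22, 1.2, 5.9, 51, 47),
    stringsAsFactors = FALSE
  )
}

fa_names <- function() fa_constants()$name

#' Construct a synthetic absorption band
#'
#' One Gaussian band whose amplitude responds linearly to composition
#' descriptors: `amplitude = base * (1 + sum(weights * descriptors))`.
#'
#' @param center band centre, cm^-1 (within 600-4000).
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param base base amplitude, AU.
#' @param weights named numeric vector of descriptor coefficients
#'   (dimensionless per descriptor unit); may be empty.
#' @return a one-row `peak_spec` data.frame (list column `weights`).
#' @export
peak_spec <- function(center, width, base, weights = numeric()) {
  if (width <= 0) abort("peak width must be > 0")
  if (center < 600 || center > 4000) {
    abort("peak center ", center, " outside 600-4000 cm^-1")
  }
  out <- data.frame(center = center, width = width, base = base)
  out$weights <- list(weights)
  class(out) <- c("peak_spec", class(out))
  out
}

#' Default synthetic band table
#'
#' Band centres sit inside the regions characteristic of triglyceride
#' ATR-FTIR spectra: C-H stretching (2850-3006 cm^-1), ester and
#' free-acid C=O stretching (1745, 1710, 1570 cm^-1), C-H deformation
#' (1377-1464, 720 cm^-1) and C-O stretching (1120-1160 cm^-1).
#' Composite bands respond to the degree of unsaturation
#' (`double_bond_index`), mean chain length (`mean_chain_proxy`), ester
#' density and free-fatty-acid content (`ffa_fraction`, a nuisance
#' descriptor carrying no composition information). The 1200-1350 cm^-1
#' CH2-wagging progression series and the C-O bands additionally carry
#' per-fatty-acid signatures (progression bands shift with chain length
#' and unsaturation in real fat spectra), which makes the
#' composition-to-spectrum map full rank over the nine modelled acids.
#'
#' @return a `peak_spec` table (one row per band).
#' @export
default_peak_table <- function() {
  rows <- list(
    peak_spec(3006, 10, 0.030, c(double_bond_index = 0.008)),
    peak_spec(2956, 12, 0.100, c(mean_chain_proxy = -0.010)),
    peak_spec(2922, 12, 0.180, c(mean_chain_proxy = 0.012,
                                 double_bond_index = -0.0012)),
    peak_spec(2852, 12, 0.120, c(mean_chain_proxy = 0.010,
                                 double_bond_index = -0.0010)),
    peak_spec(1745, 10, 0.250, c(ester_density = 0.004)),
    peak_spec(1710, 12, 0.020, c(ffa_fraction = 0.060)),
    peak_spec(1570, 14, 0.010, c(ffa_fraction = 0.050)),
    peak_spec(1464, 10, 0.080, c(mean_chain_proxy = 0.008)),
    # collective medium-chain deformation: MCFA members in equal measure
    peak_spec(1435, 9, 0.060, c("C12:0" = 0.005, "C14:0" = 0.005,
                                "C16:0" = 0.005, "C16:1cis" = 0.005)),
    peak_spec(1377, 10, 0.050, c(scfa_mass = 0.010,
                                 mean_chain_proxy = -0.004)),
    peak_spec(1160, 12, 0.150, c(ester_density = 0.003,
                                 double_bond_index = 0.0008)),
    peak_spec(720, 10, 0.040, c(mean_chain_proxy = 0.015)),
    # CH2 wagging progression: each acid's dominant band is shared only
    # with its chain-length neighbours, as in real progression series
    peak_spec(1350, 8, 0.060, c("C8:0" = 0.008, "C10:0" = 0.003)),
    peak_spec(1325, 8, 0.060, c("C10:0" = 0.008, "C12:0" = 0.003)),
    peak_spec(1300, 8, 0.060, c("C12:0" = 0.010, "C14:0" = 0.003)),
    peak_spec(1275, 8, 0.060, c("C14:0" = 0.008, "C16:0" = 0.003)),
    peak_spec(1250, 8, 0.060, c("C16:0" = 0.008, "C18:0" = 0.003)),
    peak_spec(1225, 8, 0.060, c("C18:0" = 0.008, "C16:1cis" = 0.003)),
    peak_spec(1200, 8, 0.060, c("C18:1cis" = 0.010, "C18:2cis" = 0.002)),
    peak_spec(1120, 10, 0.060, c("C18:2cis" = 0.008, "C16:1cis" = 0.004))
  )
  do.call(rbind, rows)
}

#' Synthetic dataset configuration
#'
#' Defaults describe the study conditions the pipeline is meant for:
#' 50 samples on a 600-4000 cm^-1 grid at 2 cm^-1, compositions uniform
#' within the per-acid ranges of mature human milk fat, lactation days
#' uniform on 5-400 (median ~200, IQR ~200), an imposed lactation trend
#' (MCFA up, LCFA and PUFA down, slopes summing to zero so closure is
#' preserved), pasteurization flags on half the samples with no
#' composition effect, and instrument noise/baseline levels typical of a
#' well-purged ATR accessory.
#'
#' @param n_samples number of samples (>= 1).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param composition_ranges data.frame `name`/`low`/`high` overriding
#'   the defaults from [fa_constants()].
#' @param peak_table a `peak_spec` table (default [default_peak_table()]).
#' @param noise_sd i.i.d. Gaussian noise, AU.
#' @param baseline_offset_sd per-sample baseline offset sd, AU.
#' @param baseline_slope_sd per-sample baseline slope sd, AU per cm^-1.
#' @param trend_slopes named vector (g/100 g fat per day): `MCFA` spread
#'   over C12:0/C14:0/C16:0/C16:1cis, `LCFA` over C18:0/C18:1cis, `PUFA`
#'   over C18:2cis, each proportionally to the sampled values. Applied
#'   about the midpoint of `days_range`.
#' @param days_range lactation-day range (uniform draw).
#' @param ffa_mean,ffa_sd free-fatty-acid nuisance descriptor (mean,
#'   per-sample jitter sd); feeds only the 1710/1570 cm^-1 bands.
#' @param hop_effect additive shift (g/100 g fat) applied to no target by
#'   default; kept at 0 (pasteurization leaves the relative profile
#'   unchanged) and exposed only so the null can be broken in studies.
#' @param wavenumber_range,wavenumber_step spectral grid.
#' @param other_carbons nominal carbon number assigned to the unmodelled
#'   remainder (`OTHER`) in the chain-length proxy.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 50L, seed = NULL,
                             composition_ranges = NULL,
                             peak_table = default_peak_table(),
                             noise_sd = 1e-4,
                             baseline_offset_sd = 5e-3,
                             baseline_slope_sd = 1e-6,
                             trend_slopes = c(MCFA = 0.055, LCFA = -0.015,
                                              PUFA = -0.040),
                             days_range = c(5, 400),
                             ffa_mean = 2, ffa_sd = 0.5,
                             hop_effect = 0,
                             wavenumber_range = c(600, 4000),
                             wavenumber_step = 2,
                             other_carbons = 18) {
  ranges <- fa_constants()[, c("name", "low", "high")]
  if (!is.null(composition_ranges)) {
    idx <- match(composition_ranges$name, ranges$name)
    if (anyNA(idx)) {
      abort("unknown fatty acid in composition_ranges: ",
            paste(composition_ranges$name[is.na(idx)], collapse = ", "))
    }
    ranges$low[idx] <- composition_ranges$low
    ranges$high[idx] <- composition_ranges$high
  }
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (any(ranges$low > ranges$high)) abort("composition range with low > high")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (days_range[1] > days_range[2] || days_range[1] < 0) {
    abort("invalid days_range")
  }
  structure(
    list(n_samples = as.integer(n_samples), seed = seed,
         composition_ranges = ranges, peak_table = peak_table,
         noise_sd = noise_sd, baseline_offset_sd = baseline_offset_sd,
         baseline_slope_sd = baseline_slope_sd,
         trend_slopes = trend_slopes, days_range = days_range,
         ffa_mean = ffa_mean, ffa_sd = ffa_sd, hop_effect = hop_effect,
         wavenumbers = seq(wavenumber_range[1], wavenumber_range[2],
                           by = wavenumber_step),
         other_carbons = other_carbons),
    class = "synthetic_config"
  )
}

#' Draw fatty-acid compositions
#'
#' Each named acid is drawn uniformly within its configured range;
#' `OTHER` (all unmodelled acids) takes `100 - sum` so every row closes
#' to 100 g/100 g fat. Draws that would make `OTHER` negative are
#' rejected and redrawn.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame: `sample_id`, the nine acids, `OTHER`.
#' @export
sample_compositions <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed_or_stream(cfg$seed, draw_compositions(cfg))
}

draw_compositions <- function(cfg) {
  r <- cfg$composition_ranges
  if (sum(r$low) > 100) {
    abort("infeasible composition ranges: lower bounds sum to ",
          sum(r$low), " > 100")
  }
  n <- cfg$n_samples
  acc <- matrix(NA_real_, 0, nrow(r))
  tries <- 0L
  while (nrow(acc) < n) {
    tries <- tries + 1L
    if (tries > 1000L) abort("composition rejection sampling did not converge")
    m <- max(2L * n, 100L)
    draw <- vapply(seq_len(nrow(r)),
                   function(j) stats::runif(m, r$low[j], r$high[j]),
                   numeric(m))
    draw <- draw[rowSums(draw) <= 100, , drop = FALSE]
    acc <- rbind(acc, draw)
  }
  acc <- acc[seq_len(n), , drop = FALSE]
  out <- data.frame(sample_id = sprintf("HM%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(r))) out[[r$name[j]]] <- acc[, j]
  out$OTHER <- 100 - rowSums(acc)
  out
}

#' Composition descriptors driving band intensities
#'
#' Maps one composition row to the descriptors the band table responds
#' to: `double_bond_index = MONO + 2 PUFA` (cis double bonds per
#' 100 g), `mean_chain_proxy = sum(carbons * conc) / 100` (with `OTHER`
#' at a nominal carbon number), `ffa_fraction` (supplied nuisance
#' value), `ester_density = 100 - ffa_fraction`, `scfa_mass`
#' (C8:0 + C10:0), and the individual acid concentrations themselves.
#' Sum parameters come from [compute_sum_parameters()].
#'
#' @param composition named numeric vector or one-row data.frame with
#'   the nine acid columns (and optionally `OTHER`).
#' @param ffa_fraction free-fatty-acid content, g/100 g fat.
#' @param other_carbons nominal carbon number for `OTHER`.
#' @return named numeric descriptor vector.
#' @export
composition_descriptors <- function(composition, ffa_fraction = 2,
                                    other_carbons = 18) {
  if (is.data.frame(composition)) {
    stopifnot(nrow(composition) == 1)
    composition <- unlist(composition[, setdiff(colnames(composition),
                                                "sample_id"), drop = FALSE])
  }
  fas <- fa_constants()
  missing <- setdiff(fas$name, names(composition))
  if (length(missing)) {
    abort("missing fatty acid column: ", paste(missing, collapse = ", "))
  }
  conc <- composition[fas$name]
  other <- if ("OTHER" %in% names(composition)) composition[["OTHER"]] else 0
  df <- as.data.frame(as.list(conc), check.names = FALSE)
  df$OTHER <- other
  sums <- compute_sum_parameters(df)
  c(
    double_bond_index = sums$MONO + 2 * sums$PUFA,
    mean_chain_proxy = (sum(fas$carbons * conc) + other_carbons * other) / 100,
    ffa_fraction = ffa_fraction,
    ester_density = 100 - ffa_fraction,
    scfa_mass = sums$SCFA,
    conc
  )
}

#' Render one synthetic spectrum
#'
#' Sum of Gaussian bands with amplitudes
#' `base * (1 + sum(weights * descriptors))` (negative amplitudes are
#' clamped to zero with a warning), plus a linear baseline
#' `offset + slope * wavenumber` and i.i.d. Gaussian noise.
#'
#' @param descriptors named vector from [composition_descriptors()].
#' @param peak_table a `peak_spec` table.
#' @param wavenumbers grid to render on.
#' @param noise_sd Gaussian noise sd, AU.
#' @param baseline numeric `c(offset, slope)`.
#' @param seed optional seed for the noise draw.
#' @return numeric spectrum (AU) over `wavenumbers`.
#' @export
render_spectrum <- function(descriptors, peak_table = default_peak_table(),
                            wavenumbers = seq(600, 4000, by = 2),
                            noise_sd = 0, baseline = c(0, 0), seed = NULL) {
  spec <- numeric(length(wavenumbers))
  for (i in seq_len(nrow(peak_table))) {
    w <- peak_table$weights[[i]]
    amp <- peak_table$base[i]
    if (length(w)) {
      unknown <- setdiff(names(w), names(descriptors))
      if (length(unknown)) {
        abort("peak references unknown descriptor: ",
              paste(unknown, collapse = ", "))
      }
      amp <- amp * (1 + sum(w * descriptors[names(w)]))
    }
    if (amp < 0) {
      warning("band at ", peak_table$center[i],
              " cm^-1 driven to negative amplitude; clamped to 0",
              call. = FALSE)
      amp <- 0
    }
    spec <- spec + amp *
      exp(-(wavenumbers - peak_table$center[i])^2 /
            (2 * peak_table$width[i]^2))
  }
  spec <- spec + baseline[1] + baseline[2] * wavenumbers
  if (noise_sd > 0) {
    spec <- spec + with_seed_or_stream(seed,
      stats::rnorm(length(wavenumbers), 0, noise_sd))
  }
  spec
}

#' Generate a complete synthetic dataset
#'
#' Draws compositions, imposes the lactation-day trend (MCFA members up,
#' LCFA/PUFA members down, about the midpoint of the day range,
#' distributed proportionally within each member set and re-closed to
#' 100), assigns pasteurization flags to half the samples with no
#' composition effect, draws clinical covariates, and renders one
#' spectrum per sample.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `spectra` (a [spectra_set()]), `profile`
#'   (composition data.frame) and `clinical` (metadata data.frame).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed_or_stream(cfg$seed, {
    n <- cfg$n_samples
    prof <- draw_compositions(cfg)
    days <- stats::runif(n, cfg$days_range[1], cfg$days_range[2])
    prof <- apply_lactation_trend(prof, days, cfg$trend_slopes,
                                  mid = mean(cfg$days_range))
    ffa <- stats::rnorm(n, cfg$ffa_mean, cfg$ffa_sd)
    hop <- rep(FALSE, n)
    hop[sample.int(n, n %/% 2)] <- TRUE
    clinical <- data.frame(
      sample_id = prof$sample_id,
      days_postpartum = days,
      hop = hop,
      infant_sex = sample(c("female", "male"), n, replace = TRUE),
      gestational_age = stats::rnorm(n, 39.3, 1.7),
      maternal_age = stats::rnorm(n, 35, 4.5),
      birth_weight = stats::rnorm(n, 2911, 583),
      stringsAsFactors = FALSE
    )
    absorb <- matrix(0, n, length(cfg$wavenumbers))
    for (i in seq_len(n)) {
      d <- composition_descriptors(prof[i, ], ffa_fraction = ffa[i],
                                   other_carbons = cfg$other_carbons)
      base <- c(stats::rnorm(1, 0, cfg$baseline_offset_sd),
                stats::rnorm(1, 0, cfg$baseline_slope_sd))
      absorb[i, ] <- render_spectrum(d, cfg$peak_table, cfg$wavenumbers,
                                     noise_sd = cfg$noise_sd,
                                     baseline = base)
    }
    spectra <- spectra_set(cfg$wavenumbers, absorb, prof$sample_id)
    list(spectra = spectra, profile = prof, clinical = clinical)
  })
}

# Shift MCFA members up and LCFA/PUFA members down with lactation day,
# proportionally to each sampled value; clamp at zero and re-close via OTHER.
apply_lactation_trend <- function(prof, days, slopes, mid) {
  member <- list(
    MCFA = c("C12:0", "C14:0", "C16:0", "C16:1cis"),
    LCFA = c("C18:0", "C18:1cis"),   # non-PUFA long-chain members
    PUFA = "C18:2cis"
  )
  dt <- days - mid
  for (grp in names(member)) {
    sl <- if (grp %in% names(slopes)) slopes[[grp]] else 0
    if (sl == 0) next
    cols <- member[[grp]]
    tot <- rowSums(prof[, cols, drop = FALSE])
    shift <- sl * dt
    for (cn in cols) {
      prof[[cn]] <- pmax(0, prof[[cn]] + shift * prof[[cn]] / tot)
    }
  }
  named <- fa_names()
  prof$OTHER <- pmax(0, 100 - rowSums(prof[, named]))
  prof
}

#' Write a generated dataset to a directory
#'
#' Writes `spectra.csv`, `fa_references.csv` and `clinical.csv` in the
#' formats read by [read_spectra()] and [read_sample_table()].
#'
#' @param ds list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spectra(ds$spectra, file.path(dir, "spectra.csv"))
  write_sample_table(ds$profile, file.path(dir, "fa_references.csv"))
  write_sample_table(ds$clinical, file.path(dir, "clinical.csv"))
  invisible(dir)
}
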