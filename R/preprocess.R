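#' Preprocessing parameters
#'
#' Savitzky-Golay differentiation settings plus the mean-centering flag.
#' Defaults follow common practice for lipid ATR-FTIR calibration: a
#' 15-point window, 2nd order polynomial, 2nd derivative, mean centering
#' on.
#'
#' @param window odd integer window length in channels (>= polyorder + 1).
#' @param polyorder polynomial order of the local fit.
#' @param derivative derivative order (<= polyorder); 0 or 2 supported
#'   downstream.
#' @param center logical; fit/apply per-channel mean centering.
#' @return an object of class `preprocess_params`.
#' @export
preprocess_params <- function(window = 15L, polyorder = 2L,
                              derivative = 2L, center = TRUE) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  derivative <- as.integer(derivative)
  if (window %% 2L == 0L) abort("window must be odd, got ", window)
  if (window < polyorder + 1L) abort("window must be >= polyorder + 1")
  if (derivative > polyorder) abort("derivative must be <= polyorder")
  if (derivative < 0L || polyorder < 0L) abort("orders must be nonnegative")
  structure(list(window = window, polyorder = polyorder,
                 derivative = derivative, center = isTRUE(center)),
            class = "preprocess_params")
}

#' Savitzky-Golay derivative of a spectra set
#'
#' Per channel, a `polyorder` polynomial is fitted over the centred
#' window and its `derivative`-th derivative evaluated at the centre
#' (implemented via the central row of the `signal::sgolay()` filter
#' matrix), then divided by the grid step to the derivative power so the
#' result is a physical per-wavenumber derivative (AU/(cm^-1)^d). The
#' (window-1)/2 channels at each edge have no complete window and are
#' dropped; the grid is trimmed to match.
#'
#' @param s a raw `spectra_set` (`derivative_order == 0`).
#' @param p a [preprocess_params()].
#' @return a `spectra_set` with `derivative_order = p$derivative` and
#'   `window - 1` fewer channels.
#' @export
savgol_derivative <- function(s, p = preprocess_params()) {
  stopifnot(inherits(s, "spectra_set"), inherits(p, "preprocess_params"))
  if (s$derivative_order != 0L) {
    abort("spectra already differentiated (derivative_order = ",
          s$derivative_order, ")")
  }
  nchan <- length(s$wavenumbers)
  if (nchan < p$window) {
    abort("need at least ", p$window, " channels, got ", nchan)
  }
  coefs <- savgol_coefficients(p)
  h <- (p$window - 1L) %/% 2L
  nv <- nchan - p$window + 1L
  out <- matrix(0, nrow(s$absorbance), nv)
  for (k in seq_len(p$window)) {
    out <- out + s$absorbance[, k:(k + nv - 1L), drop = FALSE] * coefs[k]
  }
  dnu <- if (nchan > 1) s$wavenumbers[2] - s$wavenumbers[1] else 1
  out <- out / dnu^p$derivative
  spectra_set(s$wavenumbers[(h + 1L):(nchan - h)], out, s$sample_ids,
              derivative_order = p$derivative)
}

# Central-row SG filter coefficients (derivative w.r.t. channel index;
# window is odd by construction so the centre row is (window + 1) / 2).
savgol_coefficients <- function(p) {
  F <- signal::sgolay(p = p$polyorder, n = p$window, m = p$derivative, ts = 1)
  as.numeric(F[(p$window + 1L) %/% 2L, ])
}

#' Fit per-channel centering means on a training set
#'
#' @param train a `spectra_set` holding training samples only.
#' @return numeric vector of per-channel means (the centering vector).
#' @export
fit_center <- function(train) {
  stopifnot(inherits(train, "spectra_set"))
  colMeans(train$absorbance)
}

#' Apply a fitted centering vector
#'
#' Validation/prediction spectra must be centred with the TRAINING means,
#' never their own; this function only ever subtracts the vector it is
#' given.
#'
#' @param s a `spectra_set` or numeric matrix.
#' @param centering numeric vector from [fit_center()].
#' @return same type as `s`, centred.
#' @export
apply_center <- function(s, centering) {
  m <- if (inherits(s, "spectra_set")) s$absorbance else as.matrix(s)
  if (ncol(m) != length(centering)) {
    abort("centering vector has ", length(centering),
          " channels but spectra have ", ncol(m))
  }
  out <- sweep(m, 2L, centering)
  if (inherits(s, "spectra_set")) {
    spectra_set(s$wavenumbers, out, s$sample_ids, s$derivative_order)
  } else {
    out
  }
}
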