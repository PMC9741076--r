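#' Construct a spectra set
#'
#' The core container for a batch of ATR-FTIR spectra sharing one
#' wavenumber grid. Rows of `absorbance` are samples, columns are spectral
#' channels. Raw spectra carry `derivative_order = 0` (absorbance units,
#' AU); Savitzky-Golay differentiated spectra carry `derivative_order = 2`
#' (units AU/(cm^-1)^2).
#'
#' @param wavenumbers numeric vector of channel positions in cm^-1;
#'   strictly increasing and uniformly spaced (relative tolerance 1e-9).
#' @param absorbance numeric matrix, `length(sample_ids)` rows by
#'   `length(wavenumbers)` columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param derivative_order integer, 0 (raw) or 2 (second derivative).
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids,
                        derivative_order = 0L) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  sample_ids <- as.character(sample_ids)
  derivative_order <- as.integer(derivative_order)

  if (nrow(absorbance) != length(sample_ids)) {
    abort("absorbance has ", nrow(absorbance), " rows but there are ",
          length(sample_ids), " sample ids")
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    abort("absorbance has ", ncol(absorbance), " columns but the grid has ",
          length(wavenumbers), " wavenumbers")
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample ids: ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  check_uniform_grid(wavenumbers)
  if (!derivative_order %in% c(0L, 2L)) {
    abort("derivative_order must be 0 or 2")
  }
  dimnames(absorbance) <- list(sample_ids, NULL)
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         sample_ids = sample_ids, derivative_order = derivative_order),
    class = "spectra_set"
  )
}

# Strictly increasing, uniform spacing within 1e-9 relative tolerance.
# Errors name the first offending index (1-based, position of the bad step).
check_uniform_grid <- function(w, rel_tol = 1e-9) {
  if (length(w) < 2) return(invisible(w))
  d <- diff(w)
  if (any(d <= 0)) {
    abort("wavenumber grid not strictly increasing at index ",
          which(d <= 0)[1] + 1L)
  }
  rel <- abs(d - d[1]) / abs(d[1])
  if (any(rel > rel_tol)) {
    abort("non-uniform wavenumber grid at index ",
          which(rel > rel_tol)[1] + 1L,
          " (relative deviation ", signif(max(rel), 3), ")")
  }
  invisible(w)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "spectra_set: %d samples x %d channels, %g-%g cm^-1 (step %g), derivative order %d\n",
    nrow(x$absorbance), ncol(x$absorbance),
    min(x$wavenumbers), max(x$wavenumbers),
    if (length(x$wavenumbers) > 1) diff(x$wavenumbers[1:2]) else NA_real_,
    x$derivative_order))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param ids character vector of sample ids (or integer indices) to keep.
#' @return a `spectra_set` with the selected rows, in the requested order.
#' @export
subset_samples <- function(x, ids) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.character(ids)) {
    missing <- setdiff(ids, x$sample_ids)
    if (length(missing)) {
      abort("unknown sample ids: ", paste(missing, collapse = ", "))
    }
    idx <- match(ids, x$sample_ids)
  } else {
    idx <- ids
  }
  spectra_set(x$wavenumbers, x$absorbance[idx, , drop = FALSE],
              x$sample_ids[idx], x$derivative_order)
}
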