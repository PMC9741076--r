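#' Read a spectra matrix from delimited text
#'
#' Expected layout: first column the wavenumber grid, one further column
#' per sample, header row of sample ids. Files written with a descending
#' grid (common FTIR export order) are accepted and flipped to the
#' ascending internal convention with a message.
#'
#' @param path file to read.
#' @param sep field separator (default comma).
#' @param dec decimal mark.
#' @return a [spectra_set()] with samples in file column order.
#' @export
read_spectra <- function(path, sep = ",", dec = ".") {
  if (!file.exists(path)) abort("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          check.names = FALSE, comment.char = "")
  if (ncol(df) < 1) abort("spectra file has no columns: ", path)
  w <- as.numeric(df[[1]])
  ids <- colnames(df)[-1]
  a <- t(as.matrix(df[, -1, drop = FALSE]))
  if (length(w) > 1 && all(diff(w) < 0)) {
    message("descending wavenumber grid in ", path, "; reversing to ascending")
    w <- rev(w)
    a <- a[, rev(seq_len(ncol(a))), drop = FALSE]
  }
  if (anyDuplicated(ids)) {
    abort("duplicate sample ids in ", path, ": ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  spectra_set(w, a, ids, derivative_order = 0L)
}

#' Write a spectra matrix as delimited text
#'
#' Numbers are written with 17 significant digits so a read/write
#' round-trip is lossless to within 1e-12 (in practice bit-exact).
#'
#' @param s a `spectra_set`.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, sep = ",") {
  stopifnot(inherits(s, "spectra_set"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort("cannot open for writing: ", path, " (", conditionMessage(e), ")")
  })
  on.exit(close(con))
  writeLines(paste(c("wavenumber", s$sample_ids), collapse = sep), con)
  m <- cbind(s$wavenumbers, t(s$absorbance))
  lines <- apply(m, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = sep)
  })
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Read a per-sample table (fatty acid references or clinical metadata)
#'
#' One row per sample, first column `sample_id`, remaining columns named
#' analytes (g/100 g fat) or covariates. Column names are kept verbatim
#' (e.g. `C16:1cis`).
#'
#' @param path file to read.
#' @param sep field separator.
#' @return a data.frame.
#' @export
read_sample_table <- function(path, sep = ",") {
  if (!file.exists(path)) abort("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample_id") {
    abort("first column of ", path, " must be 'sample_id'")
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in ", path)
  df
}

#' Write a per-sample table as delimited text
#'
#' @param df data.frame with a `sample_id` first column.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x)
    trimws(formatC(x, digits = 17, format = "g")))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- "milkfatir-pls-1"

#' Save a fitted PLS1 model to a self-describing text file
#'
#' The file is JSON with full-precision numbers, a format-version field,
#' and explicit shapes, so it can be reloaded (or parsed outside R)
#' without loss: predictions from a reloaded model agree with the
#' original to better than 1e-12.
#'
#' @param m a `pls_model` from [fit_pls1()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "pls_model"))
  if (!any(m$mask)) abort("refusing to save a model with an empty channel mask")
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    target_name = m$target_name,
    n_lv = m$n_lv,
    wavenumbers = m$wavenumbers,
    mask = which(m$mask),
    n_channels = length(m$mask),
    x_mean = m$x_mean,
    y_mean = m$y_mean,
    W = m$W, P = m$P, q = m$q, b = m$b,
    preprocess = unclass(m$preprocess)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' Load a PLS1 model saved by [save_model()]
#'
#' @param path file written by [save_model()].
#' @return a `pls_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort("no such file: ", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        abort("cannot parse model file ", path, ": ",
                              conditionMessage(e))
                      })
  if (!identical(payload$format_version, MODEL_FORMAT_VERSION)) {
    abort("model file ", path, " has format version '",
          payload$format_version %||% "<missing>",
          "', expected '", MODEL_FORMAT_VERSION, "'")
  }
  required <- c("n_lv", "wavenumbers", "mask", "n_channels", "x_mean",
                "y_mean", "W", "P", "q", "b")
  missing <- setdiff(required, names(payload))
  if (length(missing)) {
    abort("model file ", path, " is missing fields: ",
          paste(missing, collapse = ", "))
  }
  mask <- rep(FALSE, payload$n_channels)
  mask[payload$mask] <- TRUE
  pp <- payload$preprocess
  preprocess <- if (is.null(pp) || !length(pp)) NULL else {
    preprocess_params(window = pp$window, polyorder = pp$polyorder,
                      derivative = pp$derivative, center = pp$center)
  }
  new_pls_model(
    n_lv = as.integer(payload$n_lv),
    x_mean = as.numeric(payload$x_mean),
    y_mean = as.numeric(payload$y_mean),
    W = matrix(as.numeric(payload$W), ncol = payload$n_lv),
    P = matrix(as.numeric(payload$P), ncol = payload$n_lv),
    q = as.numeric(payload$q),
    b = as.numeric(payload$b),
    mask = mask,
    wavenumbers = as.numeric(payload$wavenumbers),
    preprocess = preprocess,
    target_name = payload$target_name %||% ""
  )
}
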