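#' Fit a PLS1 regression model (NIPALS)
#'
#' Single-response partial least squares fitted from first principles.
#' Per component: `w = X'y / ||X'y||`, `t = X w`, `p = X't / (t't)`,
#' `q_a = y't / (t't)`, then `X <- X - t p'`, `y <- y - t q_a`.
#' The regression vector is assembled as `b = W (P'W)^-1 q` so that
#' `yhat = y_mean + (x - x_mean) b`.
#'
#' If the residual covariance `X'y` vanishes before `n_lv` components the
#' fit stops early with a warning and returns the achieved number.
#'
#' @param X numeric matrix, samples x channels (preprocessed spectra;
#'   centred internally when `center = TRUE`).
#' @param y numeric response vector (g/100 g fat).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(nrow - 1, ncol)`.
#' @param center centre `X` and `y` internally (default). Pass `FALSE`
#'   for pre-centred input (means are then recorded as zero).
#' @param mask logical channel mask over the full grid that `X`'s columns
#'   correspond to; defaults to all channels.
#' @param wavenumbers optional grid (full, before masking) recorded for
#'   prediction-time checks.
#' @param preprocess optional [preprocess_params()] recorded so raw
#'   spectra can be auto-preprocessed at prediction time.
#' @param target_name label for reports.
#' @return an object of class `pls_model`.
#' @export
fit_pls1 <- function(X, y, n_lv, center = TRUE, mask = NULL,
                     wavenumbers = NULL, preprocess = NULL,
                     target_name = "") {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) abort("nrow(X) != length(y)")
  if (n < 2) abort("need at least 2 samples")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1 || n_lv > min(n - 1L, p)) {
    abort("n_lv must be in 1..min(nrow - 1, ncol) = ", min(n - 1L, p))
  }
  if (is.null(mask)) mask <- rep(TRUE, p)
  if (sum(mask) != p) abort("mask selects ", sum(mask),
                            " channels but X has ", p, " columns")

  if (center) {
    x_mean <- colMeans(X); y_mean <- mean(y)
  } else {
    x_mean <- numeric(p); y_mean <- 0
  }
  fit <- pls1_engine(sweep(X, 2L, x_mean), y - y_mean, n_lv)
  if (fit$achieved < n_lv) {
    warning("no covariance left after ", fit$achieved,
            " components; requested ", n_lv, call. = FALSE)
  }
  a <- fit$achieved
  b <- pls1_coef(fit$W, fit$P, fit$q, a)
  new_pls_model(
    n_lv = a, x_mean = x_mean, y_mean = y_mean,
    W = fit$W[, seq_len(a), drop = FALSE],
    P = fit$P[, seq_len(a), drop = FALSE],
    q = fit$q[seq_len(a)], b = b, mask = mask,
    wavenumbers = wavenumbers, preprocess = preprocess,
    target_name = target_name
  )
}

# Deflation loop shared by fit_pls1 and cross_validate.
pls1_engine <- function(Xc, yc, n_lv, tol = 1e-12) {
  p <- ncol(Xc)
  W <- P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  scale0 <- sqrt(sum(crossprod(Xc, yc)^2))
  achieved <- 0L
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw <= tol * max(scale0, 1)) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt <= 0) break
    pv <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - t * qa
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
    achieved <- a
  }
  list(W = W, P = P, q = q, achieved = achieved)
}

# b = W (P'W)^-1 q using the first `a` components.
pls1_coef <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

new_pls_model <- function(n_lv, x_mean, y_mean, W, P, q, b, mask,
                          wavenumbers = NULL, preprocess = NULL,
                          target_name = "") {
  structure(
    list(n_lv = n_lv, x_mean = x_mean, y_mean = y_mean, W = W, P = P,
         q = q, b = b, mask = as.logical(mask),
         wavenumbers = wavenumbers, preprocess = preprocess,
         target_name = target_name),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model%s: %d LV, %d/%d channels\n",
              if (nzchar(x$target_name)) paste0(" [", x$target_name, "]") else "",
              x$n_lv, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' Raw spectra (`derivative_order == 0`) are auto-preprocessed with the
#' model's stored Savitzky-Golay settings; already-differentiated spectra
#' are used as-is. The grid must match the model's grid exactly (after
#' differentiation); a mismatch is a hard error, not a warning.
#'
#' @param object a `pls_model`.
#' @param newdata a `spectra_set` or numeric matrix. A matrix must
#'   already be on the model's (unmasked) derivative-stage grid.
#' @param ... unused.
#' @return numeric vector of predictions, named by sample id when
#'   `newdata` is a `spectra_set`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) {
    s <- newdata
    if (s$derivative_order == 0L && !is.null(object$preprocess) &&
        object$preprocess$derivative > 0L) {
      s <- savgol_derivative(s, object$preprocess)
    }
    if (!is.null(object$wavenumbers)) {
      if (length(s$wavenumbers) != length(object$wavenumbers) ||
          max(abs(s$wavenumbers - object$wavenumbers)) > 1e-6) {
        abort("spectra grid does not match the model grid")
      }
    }
    m <- s$absorbance
    ids <- s$sample_ids
  } else {
    m <- as.matrix(newdata)
    ids <- rownames(m)
  }
  if (ncol(m) != length(object$mask)) {
    abort("expected ", length(object$mask), " channels, got ", ncol(m))
  }
  m <- m[, object$mask, drop = FALSE]
  out <- drop(sweep(m, 2L, object$x_mean) %*% object$b) + object$y_mean
  names(out) <- ids
  out
}

#' Selectivity ratio via target projection
#'
#' Projects the (centred) training matrix onto the direction of the
#' model's regression vector: `t_TP = X b / ||b||`,
#' `p_TP = X' t_TP / (t_TP' t_TP)`, `Xhat = t_TP p_TP'`, `E = X - Xhat`.
#' The selectivity ratio of channel j is the ratio of explained to
#' residual sum of squares, `SR_j = sum(Xhat[, j]^2) / sum(E[, j]^2)`.
#' Channels whose residual is below `1e-15` of the explained part are
#' capped at `1e15`; channels with zero total variance get `SR = 0`.
#'
#' @param m a fitted `pls_model`.
#' @param X the centred training matrix the model was fitted on
#'   (masked channels only).
#' @return an object of class `sr_profile` with fields `wavenumbers`,
#'   `sr`, `explained_ss`, `residual_ss`.
#' @export
selectivity_ratio <- function(m, X) {
  stopifnot(inherits(m, "pls_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(m$b)) {
    abort("X has ", ncol(X), " channels but the model has ", length(m$b))
  }
  nb <- sqrt(sum(m$b^2))
  if (nb == 0) abort("degenerate model: zero regression vector")
  t_tp <- drop(X %*% m$b) / nb
  tt <- sum(t_tp^2)
  if (tt == 0) abort("degenerate model: zero target-projection scores")
  p_tp <- drop(crossprod(X, t_tp)) / tt
  xhat <- tcrossprod(t_tp, p_tp)
  e <- X - xhat
  expl <- colSums(xhat^2)
  resid <- colSums(e^2)
  sr <- numeric(length(expl))
  zero_var <- (expl + resid) == 0
  capped <- !zero_var & resid < 1e-15 * expl
  ok <- !zero_var & !capped
  sr[ok] <- expl[ok] / resid[ok]
  sr[capped] <- 1e15
  wn <- if (!is.null(m$wavenumbers)) m$wavenumbers[m$mask] else seq_along(sr)
  structure(list(wavenumbers = wn, sr = sr,
                 explained_ss = expl, residual_ss = resid),
            class = "sr_profile")
}

#' Select contiguous wavenumber regions from a selectivity-ratio profile
#'
#' Channels with `SR >= threshold` are kept and grouped into contiguous
#' runs; runs shorter than `min_width` channels are discarded. If nothing
#' survives, the top decile of SR is selected instead (with a warning) so
#' a model can always be built.
#'
#' @param sr an `sr_profile`.
#' @param threshold minimum selectivity ratio (default 1: explained
#'   variance exceeds unexplained).
#' @param min_width minimum run length in channels (default 5, i.e.
#'   10 cm^-1 on a 2 cm^-1 grid).
#' @return logical channel mask over `sr$wavenumbers`.
#' @export
select_regions <- function(sr, threshold = 1, min_width = 5L) {
  stopifnot(inherits(sr, "sr_profile"))
  if (!length(sr$sr)) abort("empty selectivity-ratio profile")
  if (threshold <= 0) abort("threshold must be > 0")
  min_width <- as.integer(min_width)
  if (min_width < 1L) abort("min_width must be >= 1")
  mask <- sr$sr >= threshold
  if (any(mask)) {
    r <- rle(mask)
    r$values[r$values & r$lengths < min_width] <- FALSE
    mask <- inverse.rle(r)
  }
  if (!any(mask)) {
    warning("no region reached SR >= ", threshold,
            " at min_width ", min_width,
            "; falling back to the top decile of SR", call. = FALSE)
    cut <- stats::quantile(sr$sr, 0.9, names = FALSE)
    mask <- sr$sr >= cut
    if (!any(mask)) mask[which.max(sr$sr)] <- TRUE
  }
  mask
}
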