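#' Stratified training/validation split
#'
#' Samples are split so that pasteurized (HoP) and unpasteurized milk are
#' represented proportionally in both sets: within each stratum ids are
#' shuffled by a seeded RNG and allocated to the training set by
#' largest-remainder rounding of the stratum's proportional quota.
#'
#' @param ids character sample ids.
#' @param hop_flags logical/factor stratum labels (same length as `ids`);
#'   `NULL` for an unstratified random split.
#' @param n_train,n_val set sizes; must sum to `length(ids)`.
#' @param seed RNG seed for the shuffle.
#' @return list with character vectors `train` and `val`.
#' @export
split_train_validation <- function(ids, hop_flags = NULL, n_train = 35L,
                                   n_val = 15L, seed = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n_train + n_val != n) {
    abort("n_train + n_val = ", n_train + n_val, " but there are ", n, " ids")
  }
  if (is.null(hop_flags)) hop_flags <- rep(FALSE, n)
  if (length(hop_flags) != n) abort("hop_flags length mismatch")
  strata <- split(ids, hop_flags)
  sizes <- lengths(strata)
  quota <- sizes * n_train / n
  alloc <- floor(quota)
  rem <- n_train - sum(alloc)
  if (rem > 0) {
    frac_order <- order(quota - alloc, decreasing = TRUE)
    alloc[frac_order[seq_len(rem)]] <- alloc[frac_order[seq_len(rem)]] + 1
  }
  if (any(alloc > sizes)) {
    abort("stratum smaller than its training allocation")
  }
  picks <- with_seed_or_stream(seed, {
    lapply(seq_along(strata), function(i) {
      shuffled <- sample(strata[[i]])
      list(train = shuffled[seq_len(alloc[i])],
           val = shuffled[setdiff(seq_along(shuffled), seq_len(alloc[i]))])
    })
  })
  train <- unlist(lapply(picks, `[[`, "train"), use.names = FALSE)
  val <- unlist(lapply(picks, `[[`, "val"), use.names = FALSE)
  # keep file order inside each set: contiguous-blocks CV depends on it
  list(train = ids[sort(match(train, ids))], val = ids[sort(match(val, ids))])
}

#' Contiguous cross-validation blocks
#'
#' Indices `1..n` in their given (file) order are cut into `k` contiguous
#' runs; the first `n %% k` blocks get `ceiling(n/k)` elements, the rest
#' `floor(n/k)`.
#'
#' @param n number of samples.
#' @param k number of blocks (data splits), `2 <= k <= n`.
#' @return list of `k` integer vectors partitioning `1..n`.
#' @export
contiguous_blocks <- function(n, k = 10L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) abort("k must be >= 2")
  if (k > n) abort("k = ", k, " exceeds n = ", n)
  big <- n %% k
  sizes <- c(rep(ceiling(n / k), big), rep(floor(n / k), k - big))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) seq.int(starts[i], ends[i]))
}

#' Contiguous-blocks cross-validation of a PLS1 calibration
#'
#' The sample-wise Savitzky-Golay filter is applied once up front (it
#' uses no cross-sample statistics, so this leaks nothing); mean
#' centering is refit inside every fold on the retained samples only.
#' Held-out predictions are assembled for every component count up to
#' `max_lv`, giving RMSECV(LV) and R2_CV(LV) with the full training-set
#' mean as the R2 reference.
#'
#' @param X a `spectra_set` (raw spectra are differentiated with
#'   `params` first) or a numeric matrix of preprocessed spectra.
#' @param y numeric response for the training samples, in `X` row order.
#' @param params [preprocess_params()] used when `X` is raw.
#' @param max_lv largest component count to evaluate.
#' @param k number of contiguous blocks (default 10).
#' @return an object of class `cv_result`: `predictions` (n x max_lv
#'   matrix of out-of-fold predictions), `rmsecv`, `r2cv`, `blocks`,
#'   `chosen_lv`, `y`.
#' @export
cross_validate <- function(X, y, params = preprocess_params(),
                           max_lv = 10L, k = 10L) {
  if (inherits(X, "spectra_set")) {
    if (X$derivative_order == 0L && params$derivative > 0L) {
      X <- savgol_derivative(X, params)
    }
    X <- X$absorbance
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) abort("nrow(X) != length(y)")
  max_lv <- as.integer(max_lv)
  if (max_lv < 1L) abort("max_lv must be >= 1")
  blocks <- contiguous_blocks(n, k)
  preds <- matrix(NA_real_, n, max_lv)
  for (b in blocks) {
    keep <- setdiff(seq_len(n), b)
    lv_fold <- min(max_lv, length(keep) - 1L)
    if (lv_fold < max_lv) {
      warning("fold with ", length(keep),
              " training samples: capping LV at ", lv_fold, call. = FALSE)
    }
    xm <- colMeans(X[keep, , drop = FALSE])
    ym <- mean(y[keep])
    fit <- pls1_engine(sweep(X[keep, , drop = FALSE], 2L, xm),
                       y[keep] - ym, lv_fold)
    Xh <- sweep(X[b, , drop = FALSE], 2L, xm)
    for (a in seq_len(fit$achieved)) {
      preds[b, a] <- drop(Xh %*% pls1_coef(fit$W, fit$P, fit$q, a)) + ym
    }
    if (fit$achieved < max_lv && fit$achieved > 0L) {
      # no covariance left: later components predict like the last one
      for (a in seq.int(fit$achieved + 1L, max_lv)) {
        preds[b, a] <- preds[b, fit$achieved]
      }
    }
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  sstot <- sum((y - mean(y))^2)
  r2cv <- 1 - colSums((preds - y)^2) / sstot
  res <- structure(
    list(predictions = preds, rmsecv = rmsecv, r2cv = r2cv,
         blocks = blocks, y = y, chosen_lv = NA_integer_),
    class = "cv_result"
  )
  res$chosen_lv <- select_lv(res)
  res
}

#' Choose the number of latent variables from a cross-validation curve
#'
#' Parsimony rule: the smallest component count whose RMSECV is within
#' `tol` (default 2%) of the curve minimum. `rule = "min"` takes the
#' exact minimum; `force` overrides with a manual value.
#'
#' @param cv a `cv_result` (or anything with an `rmsecv` vector).
#' @param rule `"parsimony"` (default) or `"min"`.
#' @param tol relative slack for the parsimony rule.
#' @param force optional manual LV count.
#' @return integer LV count.
#' @export
select_lv <- function(cv, rule = c("parsimony", "min"), tol = 0.02,
                      force = NULL) {
  if (!is.null(force)) return(as.integer(force))
  rule <- match.arg(rule)
  r <- cv$rmsecv
  best <- which.min(r)
  chosen <- if (rule == "min") best else which(r <= (1 + tol) * r[best])[1]
  if (best == length(r) && length(r) > 1 && all(diff(r) < 0)) {
    warning("RMSECV still decreasing at max_lv = ", length(r),
            "; consider a larger max_lv", call. = FALSE)
  }
  as.integer(chosen)
}

#' Figures of merit for a set of predictions
#'
#' `RMSE = sqrt(mean((yhat - y)^2))` (no degrees-of-freedom correction)
#' and `R2 = 1 - SS_res / SS_tot` with `SS_tot` taken about
#' `reference_mean`: the training-set mean for calibration and
#' cross-validation, the validation-set mean for external prediction.
#'
#' @param y_true,y_hat numeric vectors of equal length >= 2.
#' @param reference_mean centre for `SS_tot` (default `mean(y_true)`).
#' @return list with `rmse` and `r2` (`r2` is `NA` with a warning when
#'   `y_true` has zero variance about `reference_mean`).
#' @export
figures_of_merit <- function(y_true, y_hat, reference_mean = mean(y_true)) {
  y_true <- as.numeric(y_true); y_hat <- as.numeric(y_hat)
  if (length(y_true) != length(y_hat)) abort("length mismatch")
  if (length(y_true) < 2) abort("need at least 2 observations")
  rmse <- sqrt(mean((y_hat - y_true)^2))
  sstot <- sum((y_true - reference_mean)^2)
  if (sstot == 0) {
    warning("zero variance in reference values: R2 undefined", call. = FALSE)
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((y_hat - y_true)^2) / sstot
  }
  list(rmse = rmse, r2 = r2)
}
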