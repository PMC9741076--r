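#' Target definitions: the 16 calibration targets
#'
#' Sum parameters group the nine modelled acids: SAT (all saturated),
#' MONO (C16:1cis, C18:1cis), PUFA (C18:2cis), UNSAT = MONO + PUFA, and
#' the chain-length classes SCFA (C10 and shorter), MCFA (C11-C16),
#' LCFA (C17 and longer). By default the unmodelled remainder (`OTHER`)
#' is counted as saturated, which closes SAT + UNSAT to 100 g/100 g fat
#' (the convention under which SAT and UNSAT calibrations are exact
#' mirror images); the chain classes leave `OTHER` unallocated, so
#' SCFA + MCFA + LCFA + OTHER = 100.
#'
#' @param include_other_in_sat count `OTHER` as saturated (default TRUE).
#' @return named list mapping each target to its member columns.
#' @export
target_definitions <- function(include_other_in_sat = TRUE) {
  sat <- c("C8:0", "C10:0", "C12:0", "C14:0", "C16:0", "C18:0")
  if (include_other_in_sat) sat <- c(sat, "OTHER")
  mono <- c("C16:1cis", "C18:1cis")
  pufa <- "C18:2cis"
  defs <- list(
    SAT = sat, MONO = mono, PUFA = pufa, UNSAT = c(mono, pufa),
    SCFA = c("C8:0", "C10:0"),
    MCFA = c("C12:0", "C14:0", "C16:0", "C16:1cis"),
    LCFA = c("C18:0", "C18:1cis", "C18:2cis")
  )
  for (fa in fa_names()) defs[[fa]] <- fa
  defs
}

#' Append fatty-acid sum parameters to a profile table
#'
#' @param t data.frame with the nine individual acid columns (and
#'   optionally `OTHER`; absent `OTHER` counts as 0).
#' @param include_other_in_sat see [target_definitions()].
#' @return `t` with columns SAT, MONO, PUFA, UNSAT, SCFA, MCFA, LCFA
#'   appended (existing columns of those names are overwritten).
#' @export
compute_sum_parameters <- function(t, include_other_in_sat = TRUE) {
  defs <- target_definitions(include_other_in_sat)
  sums <- c("SAT", "MONO", "PUFA", "UNSAT", "SCFA", "MCFA", "LCFA")
  for (s in sums) {
    members <- defs[[s]]
    optional <- members == "OTHER" & !("OTHER" %in% colnames(t))
    missing <- setdiff(members[!optional], colnames(t))
    if (length(missing)) {
      abort("missing member column for ", s, ": ",
            paste(missing, collapse = ", "))
    }
    t[[s]] <- rowSums(t[, members[members %in% colnames(t)], drop = FALSE])
  }
  t
}

#' Pipeline configuration
#'
#' @param seed seed for the training/validation split.
#' @param preprocess a [preprocess_params()].
#' @param sr_threshold,sr_min_width region selection settings, see
#'   [select_regions()].
#' @param max_lv largest latent-variable count evaluated in CV.
#' @param cv_folds contiguous blocks (data splits) in CV.
#' @param n_train,n_val split sizes.
#' @param lv_rule `"parsimony"` or `"min"`, see [select_lv()].
#' @param include_other_in_sat see [target_definitions()].
#' @param targets character vector of targets to fit (default all 16).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = NULL, preprocess = preprocess_params(),
                            sr_threshold = 1, sr_min_width = 5L,
                            max_lv = 10L, cv_folds = 10L,
                            n_train = 35L, n_val = 15L,
                            lv_rule = "parsimony",
                            include_other_in_sat = TRUE,
                            targets = NULL) {
  structure(
    list(seed = seed, preprocess = preprocess,
         sr_threshold = sr_threshold, sr_min_width = as.integer(sr_min_width),
         max_lv = as.integer(max_lv), cv_folds = as.integer(cv_folds),
         n_train = as.integer(n_train), n_val = as.integer(n_val),
         lv_rule = lv_rule,
         include_other_in_sat = isTRUE(include_other_in_sat),
         targets = targets %||% names(target_definitions())),
    class = "pipeline_config"
  )
}

#' Train PLS1 calibrations for all targets
#'
#' The full calibration workflow: stratified training/validation split,
#' Savitzky-Golay differentiation, then per target a full-spectrum
#' cross-validation (to pick the latent variables feeding the
#' selectivity ratio), selectivity-ratio region selection, a second
#' cross-validation on the selected regions, a refit on the whole
#' training set, and external prediction of the validation set. The
#' report has one row per target with LVs, training range, RMSEC, R2,
#' RMSECV, R2_CV, RMSEP and R2_P, all in g/100 g fat.
#'
#' @param spectra a raw [spectra_set()].
#' @param refs data.frame of reference concentrations (`sample_id` plus
#'   the nine acid columns and optionally `OTHER`); sum parameters are
#'   derived internally.
#' @param clinical optional data.frame with `sample_id` and `hop` used
#'   to stratify the split.
#' @param config a [pipeline_config()].
#' @return an object of class `target_registry`: `models` (named list of
#'   `pls_model`), `report` (data.frame), `cv` (named list of
#'   `cv_result` on the selected regions), `sr` (named list of
#'   `sr_profile`), `split`, `config`, `wavenumbers` (derivative grid).
#' @export
train_all_targets <- function(spectra, refs, clinical = NULL,
                              config = pipeline_config()) {
  stopifnot(inherits(spectra, "spectra_set"),
            inherits(config, "pipeline_config"))
  ids <- spectra$sample_ids
  if (!all(ids %in% refs$sample_id)) {
    abort("reference table is missing samples: ",
          paste(setdiff(ids, refs$sample_id), collapse = ", "))
  }
  refs <- refs[match(ids, refs$sample_id), , drop = FALSE]
  hop <- NULL
  if (!is.null(clinical) && "hop" %in% colnames(clinical)) {
    hop <- clinical$hop[match(ids, clinical$sample_id)]
  }
  refs <- compute_sum_parameters(refs, config$include_other_in_sat)

  split <- split_train_validation(ids, hop, config$n_train, config$n_val,
                                  seed = config$seed)
  deriv <- if (config$preprocess$derivative > 0L) {
    savgol_derivative(spectra, config$preprocess)
  } else {
    spectra
  }
  tr <- match(split$train, ids)
  va <- match(split$val, ids)
  Xtr <- deriv$absorbance[tr, , drop = FALSE]
  Xva <- deriv$absorbance[va, , drop = FALSE]
  max_lv <- min(config$max_lv, length(tr) - 1L)

  models <- cvs <- srs <- list()
  rows <- list()
  for (target in config$targets) {
    y <- refs[[target]][tr]
    if (stats::var(y) == 0) {
      warning("target ", target, " has zero variance in training refs; skipped",
              call. = FALSE)
      next
    }
    # pass 1: full spectrum, CV only to size the SR model
    cv0 <- cross_validate(Xtr, y, config$preprocess, max_lv, config$cv_folds)
    lv0 <- select_lv(cv0, rule = config$lv_rule)
    m0 <- fit_pls1(Xtr, y, lv0, wavenumbers = deriv$wavenumbers,
                   preprocess = config$preprocess, target_name = target)
    srp <- selectivity_ratio(m0, sweep(Xtr, 2L, m0$x_mean))
    mask <- select_regions(srp, config$sr_threshold, config$sr_min_width)
    # pass 2: selected regions only
    cvm <- cross_validate(Xtr[, mask, drop = FALSE], y, config$preprocess,
                          max_lv, config$cv_folds)
    lv <- select_lv(cvm, rule = config$lv_rule)
    m <- fit_pls1(Xtr[, mask, drop = FALSE], y, lv, mask = mask,
                  wavenumbers = deriv$wavenumbers,
                  preprocess = config$preprocess, target_name = target)
    fitted_tr <- predict(m, Xtr)
    cal <- figures_of_merit(y, fitted_tr, mean(y))
    yv <- refs[[target]][va]
    pred_va <- predict(m, Xva)
    val <- figures_of_merit(yv, pred_va, mean(yv))
    models[[target]] <- m
    cvs[[target]] <- cvm
    srs[[target]] <- srp
    rows[[target]] <- data.frame(
      target = target, lv = m$n_lv,
      range_low = min(y), range_high = max(y),
      rmsec = cal$rmse, r2 = cal$r2,
      rmsecv = cvm$rmsecv[lv], r2_cv = cvm$r2cv[lv],
      rmsep = val$rmse, r2_p = val$r2,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(models = models,
         report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         cv = cvs, sr = srs, split = split, config = config,
         wavenumbers = deriv$wavenumbers),
    class = "target_registry"
  )
}

#' @export
print.target_registry <- function(x, ...) {
  cat("PLS1 calibrations (g/100 g fat), training n =",
      length(x$split$train), ", validation n =", length(x$split$val), "\n")
  rep <- x$report
  rep$range <- sprintf("%.3g-%.3g", rep$range_low, rep$range_high)
  num <- c("rmsec", "r2", "rmsecv", "r2_cv", "rmsep", "r2_p")
  rep[num] <- lapply(rep[num], signif, 3)
  print(rep[, c("target", "lv", "range", num)], row.names = FALSE)
  invisible(x)
}

#' Write a calibration report as delimited text
#'
#' Deterministic formatting (15 significant digits) so identical runs
#' produce byte-identical files.
#'
#' @param reg a `target_registry` (or its `report` data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(reg, path) {
  rep <- if (inherits(reg, "target_registry")) reg$report else reg
  write_sample_table_generic(rep, path)
}

write_sample_table_generic <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x)
    trimws(formatC(x, digits = 15, format = "g")))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Predict a full fatty-acid profile
#'
#' Applies every fitted calibration to the spectra. Predictions are
#' independent per model: no closure is enforced. The returned table
#' carries a `consistency` attribute with `|UNSAT - MONO - PUFA|` per
#' sample when those three models are present.
#'
#' @param reg a `target_registry`.
#' @param spectra a `spectra_set` on the training grid (raw spectra are
#'   auto-preprocessed).
#' @return data.frame `sample_id` plus one column per fitted target.
#' @export
predict_profile <- function(reg, spectra) {
  stopifnot(inherits(reg, "target_registry"))
  out <- data.frame(sample_id = spectra$sample_ids,
                    stringsAsFactors = FALSE)
  for (target in names(reg$models)) {
    out[[target]] <- unname(predict(reg$models[[target]], spectra))
  }
  if (all(c("UNSAT", "MONO", "PUFA") %in% colnames(out))) {
    attr(out, "consistency") <- data.frame(
      sample_id = out$sample_id,
      unsat_gap = abs(out$UNSAT - out$MONO - out$PUFA),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' PCA concordance of measured and predicted profiles
#'
#' Mean-centred PCA (via SVD) is run on each table separately; for the
#' leading components the loading vectors are compared by the congruence
#' coefficient (normalised inner product, sign-aligned), together with
#' each component's explained-variance fraction.
#'
#' @param measured,predicted data.frames over the same samples and the
#'   same analyte columns (a `sample_id` column is ignored).
#' @param n_comp number of components to compare (default 2).
#' @return data.frame: `component`, `congruence`, `evf_measured`,
#'   `evf_predicted`.
#' @export
pca_concordance <- function(measured, predicted, n_comp = 2L) {
  num <- function(df) {
    as.matrix(df[, setdiff(colnames(df), "sample_id"), drop = FALSE])
  }
  m <- num(measured); p <- num(predicted)
  common <- intersect(colnames(m), colnames(p))
  if (!length(common)) abort("no shared analyte columns")
  m <- m[, common, drop = FALSE]; p <- p[, common, drop = FALSE]
  if (nrow(m) != nrow(p)) abort("sample count mismatch")
  if (nrow(m) < 3) abort("need at least 3 samples for PCA")
  sm <- svd(scale(m, scale = FALSE))
  sp <- svd(scale(p, scale = FALSE))
  n_comp <- min(n_comp, ncol(sm$v), ncol(sp$v))
  cong <- vapply(seq_len(n_comp), function(k) {
    abs(sum(sm$v[, k] * sp$v[, k]))
  }, numeric(1))
  data.frame(
    component = seq_len(n_comp),
    congruence = cong,
    evf_measured = (sm$d^2 / sum(sm$d^2))[seq_len(n_comp)],
    evf_predicted = (sp$d^2 / sum(sp$d^2))[seq_len(n_comp)]
  )
}
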