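#' Linear trend of a fatty-acid parameter over lactation
#'
#' Ordinary least-squares line of concentration against days after
#' delivery; the slope's two-tailed p-value comes from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param values numeric concentrations (g/100 g fat).
#' @param days days postpartum (nonnegative).
#' @param target optional label carried into the result.
#' @return one-row data.frame (class `trend_result`): `target`, `slope`,
#'   `intercept`, `se`, `t`, `p`, `n`.
#' @export
trend_vs_lactation <- function(values, days, target = "") {
  ok <- stats::complete.cases(values, days)
  values <- values[ok]; days <- days[ok]
  if (length(values) < 3) abort("need at least 3 paired observations")
  if (any(days < 0)) abort("days must be nonnegative")
  if (stats::var(days) == 0) abort("zero variance in days")
  fit <- stats::lm(values ~ days)
  sm <- summary(fit)$coefficients
  out <- data.frame(
    target = target,
    slope = sm["days", "Estimate"],
    intercept = sm["(Intercept)", "Estimate"],
    se = sm["days", "Std. Error"],
    t = sm["days", "t value"],
    p = sm["days", "Pr(>|t|)"],
    n = length(values),
    stringsAsFactors = FALSE
  )
  class(out) <- c("trend_result", class(out))
  out
}

#' Compare a parameter between pasteurized and unpasteurized milk
#'
#' Reports both a Welch two-sample t test and a Wilcoxon rank-sum test
#' (two-tailed), plus per-group medians and interquartile ranges for a
#' boxplot-style summary.
#'
#' @param values numeric concentrations.
#' @param hop_flags two-group labels (logical or factor).
#' @param target optional label.
#' @return list (class `group_comparison`): `target`, `welch`
#'   (statistic, p), `rank_sum` (statistic, p), `summary` data.frame
#'   (group, n, median, iqr).
#' @export
group_compare <- function(values, hop_flags, target = "") {
  ok <- stats::complete.cases(values, hop_flags)
  values <- values[ok]; hop_flags <- hop_flags[ok]
  g <- split(values, hop_flags)
  if (length(g) != 2) abort("need exactly 2 groups, got ", length(g))
  if (any(lengths(g) < 2)) abort("each group needs at least 2 observations")
  wt <- stats::t.test(g[[1]], g[[2]], var.equal = FALSE)
  rs <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]], exact = FALSE))
  structure(
    list(
      target = target,
      welch = list(statistic = unname(wt$statistic), p = wt$p.value),
      rank_sum = list(statistic = unname(rs$statistic), p = rs$p.value),
      summary = data.frame(
        group = names(g), n = lengths(g),
        median = vapply(g, stats::median, numeric(1)),
        iqr = vapply(g, stats::IQR, numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE
      )
    ),
    class = "group_comparison"
  )
}

#' Screen clinical covariates against the fatty-acid profile
#'
#' Continuous covariates are tested by the OLS slope machinery of
#' [trend_vs_lactation()] (equivalent to testing the Pearson
#' correlation); categorical covariates by [group_compare()]'s Welch
#' test. One row per (target, covariate). No multiplicity correction is
#' applied to `p`; a Benjamini-Hochberg adjusted column `p_adj` is
#' appended for reference.
#'
#' @param profile data.frame with `sample_id` and target columns.
#' @param clinical data.frame with `sample_id` and covariate columns.
#' @param covariates covariate names to screen (default: gestational
#'   age, maternal age, birth weight, infant sex).
#' @param targets target columns to screen (default: all numeric
#'   columns of `profile`).
#' @return data.frame: `target`, `covariate`, `type`, `estimate`,
#'   `statistic`, `p`, `p_adj`, `n`.
#' @export
covariate_screen <- function(profile, clinical,
                             covariates = c("gestational_age",
                                            "maternal_age",
                                            "birth_weight", "infant_sex"),
                             targets = NULL) {
  clinical <- clinical[match(profile$sample_id, clinical$sample_id), ,
                       drop = FALSE]
  if (is.null(targets)) {
    targets <- colnames(profile)[vapply(profile, is.numeric, logical(1))]
  }
  rows <- list()
  for (cov in covariates) {
    x <- clinical[[cov]]
    if (is.null(x) || all(is.na(x))) {
      warning("covariate ", cov, " missing or all NA; skipped", call. = FALSE)
      next
    }
    categorical <- is.character(x) || is.factor(x) || is.logical(x)
    if (categorical && length(unique(x[!is.na(x)])) < 2) {
      warning("covariate ", cov, " has a single level; skipped",
              call. = FALSE)
      next
    }
    for (target in targets) {
      y <- profile[[target]]
      ok <- stats::complete.cases(y, x)
      if (sum(ok) < 3) {
        warning("fewer than 3 complete cases for ", target, " ~ ", cov,
                "; skipped", call. = FALSE)
        next
      }
      if (categorical) {
        gc <- group_compare(y[ok], x[ok], target = target)
        md <- diff(gc$summary$median)
        rows[[length(rows) + 1L]] <- data.frame(
          target = target, covariate = cov, type = "group",
          estimate = md, statistic = gc$welch$statistic,
          p = gc$welch$p, n = sum(ok), stringsAsFactors = FALSE)
      } else {
        # reuse the OLS slope machinery; shift covariate so the
        # nonnegativity guard for lactation days does not bite
        tr <- trend_vs_lactation(y[ok], x[ok] - min(x[ok]), target = target)
        rows[[length(rows) + 1L]] <- data.frame(
          target = target, covariate = cov, type = "trend",
          estimate = tr$slope, statistic = tr$t, p = tr$p,
          n = tr$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Run the full clinical analysis on a predicted profile
#'
#' Lactation-day trends for every target, the pre/post-pasteurization
#' comparison, and the covariate screen, mirroring how the calibrations
#' are used after training.
#'
#' @param profile data.frame with `sample_id` and target columns
#'   (typically from [predict_profile()]).
#' @param clinical data.frame with `sample_id`, `days_postpartum`,
#'   `hop` and optional covariates.
#' @param targets targets to analyse (default: all numeric columns).
#' @return list with `trends` (data.frame), `hop` (data.frame with both
#'   tests per target) and `screen` (from [covariate_screen()]).
#' @export
clinical_analysis <- function(profile, clinical, targets = NULL) {
  clinical <- clinical[match(profile$sample_id, clinical$sample_id), ,
                       drop = FALSE]
  if (is.null(targets)) {
    targets <- colnames(profile)[vapply(profile, is.numeric, logical(1))]
  }
  trends <- do.call(rbind, lapply(targets, function(tg) {
    trend_vs_lactation(profile[[tg]], clinical$days_postpartum, target = tg)
  }))
  hop <- NULL
  if ("hop" %in% colnames(clinical) &&
      length(unique(clinical$hop[!is.na(clinical$hop)])) == 2) {
    hop <- do.call(rbind, lapply(targets, function(tg) {
      gc <- group_compare(profile[[tg]], clinical$hop, target = tg)
      data.frame(target = tg,
                 welch_t = gc$welch$statistic, welch_p = gc$welch$p,
                 rank_sum_w = gc$rank_sum$statistic,
                 rank_sum_p = gc$rank_sum$p,
                 stringsAsFactors = FALSE)
    }))
  }
  screen <- covariate_screen(profile, clinical, targets = targets)
  list(trends = trends, hop = hop, screen = screen)
}
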