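# Fold-error model-validation statistics (AFE, AAFE, GMFE) and the ratio
# paired t-test comparing predicted with observed PK outputs.

check_positive_vec <- function(x, what) {
  if (length(x) < 1 || any(!is.finite(x)) || any(x <= 0))
    stop_user(what, " must be a non-empty vector of positive values")
  invisible(x)
}

check_pair <- function(predicted, observed) {
  check_positive_vec(predicted, "predicted")
  check_positive_vec(observed, "observed")
  if (length(predicted) != length(observed))
    stop_user("predicted and observed must have equal length")
}

#' Average fold error
#'
#' `AFE = 10^(mean(log10 ratio))`: the geometric-mean bias of a set of
#' predictions. The source validation tables report the ratio as
#' observed/predicted (an AFE below 1 means over-prediction); that
#' orientation is the default. `orientation = "pred_over_obs"` gives the
#' literal predicted/observed direction (the reciprocal).
#'
#' @param predicted,observed Positive vectors of equal length.
#' @param orientation `"obs_over_pred"` (default) or `"pred_over_obs"`.
#' @return Dimensionless fold error (> 0).
#' @examples
#' afe(38.41, 30.73)  # 0.80: over-prediction
#' @export
afe <- function(predicted, observed,
                orientation = c("obs_over_pred", "pred_over_obs")) {
  orientation <- match.arg(orientation)
  check_pair(predicted, observed)
  ratio <- if (orientation == "obs_over_pred") observed / predicted
           else predicted / observed
  10^mean(log10(ratio))
}

#' Absolute average fold error
#'
#' `AAFE = 10^(mean(|log10 ratio|))`: the typical magnitude of
#' prediction error irrespective of direction; always >= 1 and symmetric in
#' its arguments. An AAFE of 2 means predictions are on average 2-fold off.
#'
#' @inheritParams afe
#' @return Dimensionless fold error (>= 1).
#' @examples
#' aafe(14.83, 17.45)  # 1.18
#' @export
aafe <- function(predicted, observed) {
  check_pair(predicted, observed)
  10^mean(abs(log10(predicted / observed)))
}

#' Geometric mean fold error across the three PK outputs
#'
#' `GMFE = (AAFE_AUC * AAFE_tmax * AAFE_Cmax)^(1/3)`, the summary accuracy
#' statistic reported per compound/route fit.
#'
#' @param aafe_auc,aafe_tmax,aafe_cmax Per-output AAFE values (each >= 1).
#' @return Dimensionless fold error (>= 1).
#' @examples
#' gmfe(1.18, 1.00, 1.04)  # 1.07
#' @export
gmfe <- function(aafe_auc, aafe_tmax, aafe_cmax) {
  x <- c(aafe_auc, aafe_tmax, aafe_cmax)
  if (any(!is.finite(x)) || any(x < 1))
    stop_user("AAFE inputs must all be >= 1")
  (aafe_auc * aafe_tmax * aafe_cmax)^(1 / 3)
}

#' Ratio paired t-test
#'
#' Two-sided paired t-test on the log-transformed predicted/observed pairs
#' (the standard construction of a "ratio paired" test): under the null the
#' geometric mean of the ratios is 1.
#'
#' If every pair is in an identical constant ratio the log-differences have
#' zero variance and the t statistic is undefined; the test then returns
#' p = 1 when the ratio is exactly 1 (all differences zero) and p = 0 with
#' `degenerate = TRUE` otherwise.
#'
#' @param predicted,observed Positive vectors (n >= 2), matched pairwise.
#' @return A list of class `ratio_ttest`: `p_value`, `statistic`, `df`,
#'   `geometric_mean_ratio` (predicted/observed), `n`, `degenerate`.
#' @examples
#' ratio_paired_ttest(c(1, 2, 4), c(1.1, 1.9, 4.4))
#' @export
ratio_paired_ttest <- function(predicted, observed) {
  check_pair(predicted, observed)
  n <- length(predicted)
  if (n < 2) stop_user("ratio paired t-test requires at least 2 pairs")
  d <- log(predicted) - log(observed)
  gmr <- exp(mean(d))
  degenerate <- isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0
  if (degenerate) {
    p <- if (all(d == 0)) 1 else 0
    res <- list(p_value = p, statistic = if (all(d == 0)) 0 else Inf,
                df = n - 1, geometric_mean_ratio = gmr, n = n,
                degenerate = TRUE)
  } else {
    ht <- stats::t.test(d, mu = 0)
    res <- list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
                df = unname(ht$parameter), geometric_mean_ratio = gmr, n = n,
                degenerate = FALSE)
  }
  structure(res, class = "ratio_ttest")
}

#' @export
print.ratio_ttest <- function(x, ...) {
  cat(sprintf(
    "<ratio_ttest> n %d | GMR %.4g | t %.4g (df %g) | p %.4g%s\n",
    x$n, x$geometric_mean_ratio, x$statistic, x$df, x$p_value,
    if (x$degenerate) " [degenerate: zero-variance log-ratios]" else ""))
  invisible(x)
}

#' Fold-error validation report for a predicted-vs-observed comparison
#'
#' Bundles AFE, AAFE and (for n >= 2) the ratio paired t-test p-value for a
#' set of matched predicted/observed values. n = 1 is permitted: per-output
#' validation table cells are exactly single-pair AAFEs.
#'
#' @inheritParams afe
#' @return A list of class `fold_error_report`: `afe`, `aafe`, `p_value`
#'   (`NA` for n = 1), `n`.
#' @export
fold_error_report <- function(predicted, observed,
                              orientation = c("obs_over_pred", "pred_over_obs")) {
  orientation <- match.arg(orientation)
  check_pair(predicted, observed)
  n <- length(predicted)
  p <- if (n >= 2) ratio_paired_ttest(predicted, observed)$p_value else NA_real_
  structure(list(afe = afe(predicted, observed, orientation),
                 aafe = aafe(predicted, observed),
                 p_value = p, n = n, orientation = orientation),
            class = "fold_error_report")
}

#' @export
print.fold_error_report <- function(x, ...) {
  cat(sprintf("<fold_error_report> n %d | AFE %.4g (%s) | AAFE %.4g | p %s\n",
              x$n, x$afe, x$orientation, x$aafe,
              if (is.na(x$p_value)) "NA" else sprintf("%.4g", x$p_value)))
  invisible(x)
}

#' Recompute the study fold-error table from its printed value pairs
#'
#' For every compound/route column of the packaged validation table, applies
#' the fold-error definitions to the printed calculated (observed) and
#' predicted PK outputs: per-output AAFE and AFE, and the column GMFE from
#' the three recomputed AAFEs. The printed statistics are carried alongside
#' for golden comparison; cells flagged `rounding_limited` in the fixture
#' cannot be recovered from the printed concentration pairs at 2 decimal
#' places (the source computed them from unrounded values).
#'
#' @return A list with data frames `cells` (per compound/route/metric:
#'   recomputed `aafe`, `afe` and the printed values) and `columns` (per
#'   compound/route: recomputed `gmfe`, the printed GMFE, and the per-output
#'   AAFEs used).
#' @export
recompute_study_fold_errors <- function() {
  cells <- study_fold_error_cells()
  cells$aafe <- mapply(aafe, cells$predicted, cells$calculated)
  cells$afe <- mapply(function(p, o) afe(p, o), cells$predicted,
                      cells$calculated)
  cols <- study_fold_error_columns()
  pick <- function(cmp, rt, metric)
    cells$aafe[cells$compound == cmp & cells$route == rt &
               cells$metric == metric]
  cols$aafe_auc <- mapply(pick, cols$compound, cols$route, "auc_0t")
  cols$aafe_cmax <- mapply(pick, cols$compound, cols$route, "cmax")
  cols$aafe_tmax <- mapply(pick, cols$compound, cols$route, "tmax")
  cols$gmfe <- mapply(gmfe, cols$aafe_auc, cols$aafe_tmax, cols$aafe_cmax)
  list(cells = cells, columns = cols)
}
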