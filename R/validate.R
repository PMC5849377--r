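#' Align two daily series at a lag
#'
#' Pairs exposure at day `t` with outcome at day `t + lag` (the lag runs
#' from the day of exposure forward).  Pairs with a missing member are
#' dropped and counted.
#'
#' @param x Numeric series (e.g. exposure or model prediction), daily.
#' @param y Numeric series on the same calendar (e.g. observed counts).
#' @param lag Non-negative integer number of days, `lag < length(x)`.
#' @return List with `x`, `y` (the aligned pairs), `n_pairs` and
#'   `n_dropped`.
#' @export
lag_align <- function(x, y, lag = 0L) {
  stopifnot(length(x) == length(y))
  lag <- as.integer(lag)
  if (lag < 0L) stop("lag must be non-negative", call. = FALSE)
  if (lag >= length(x)) {
    stop(sprintf("lag (%d) must be smaller than the series length (%d)",
                 lag, length(x)), call. = FALSE)
  }
  n <- length(x)
  xi <- x[seq_len(n - lag)]
  yi <- y[seq_len(n - lag) + lag]
  keep <- !is.na(xi) & !is.na(yi)
  list(x = xi[keep], y = yi[keep],
       n_pairs = sum(keep), n_dropped = sum(!keep))
}

#' Pearson correlation with its t-based p-value
#'
#' Sample Pearson correlation of aligned pairs and the two-sided p-value
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param pairs A list with numeric `x` and `y` of equal length, as from
#'   [lag_align()].
#' @return List with `r`, `p_value`, `n_pairs`.
#' @export
pearson_with_p <- function(pairs) {
  x <- pairs$x; y <- pairs$y
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    stop("Pearson correlation needs at least 3 pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    which_const <- if (stats::sd(x) == 0) "x" else "y"
    stop(sprintf("correlation undefined: series '%s' is constant",
                 which_const), call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = length(x))
}

#' Dichotomize daily counts at a cutoff
#'
#' Splits counts into a binary outcome.  With the default reading,
#' "up to `cutoff` hospitalizations" delimits the negative class, so a
#' day is positive when its count strictly exceeds the cutoff.
#'
#' @param counts Non-negative integer daily counts.
#' @param cutoff Non-negative integer (default 2).
#' @param strict If `TRUE` (default) positive means `count > cutoff`;
#'   if `FALSE`, `count >= cutoff`.
#' @return Integer vector of 0/1 with attributes `n_pos` and `n_neg`.
#'   A degenerate all-one-class outcome triggers a warning.
#' @export
dichotomize <- function(counts, cutoff = 2L, strict = TRUE) {
  if (cutoff < 0) stop("cutoff must be non-negative", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  cls <- if (strict) as.integer(counts > cutoff) else as.integer(counts >= cutoff)
  n_pos <- sum(cls == 1L, na.rm = TRUE)
  n_neg <- sum(cls == 0L, na.rm = TRUE)
  if (n_pos == 0L || n_neg == 0L) {
    warning(sprintf("dichotomized outcome is one-class (pos=%d, neg=%d); ROC analysis will be refused",
                    n_pos, n_neg), call. = FALSE)
  }
  structure(cls, n_pos = n_pos, n_neg = n_neg)
}

#' ROC area under the curve with a 95\% confidence interval
#'
#' AUC is computed as the normalized Mann-Whitney statistic (probability
#' that a random positive day scores above a random negative day, ties
#' counted one half), which equals the trapezoidal integral of the
#' empirical ROC curve.  The default confidence interval uses the
#' Hanley-McNeil standard error; `ci_method = "delong"` delegates to
#' `pROC::ci.auc()`.
#'
#' @param predictor Numeric scores (pollutant concentration or model
#'   prediction), finite.
#' @param outcome Binary 0/1 outcome of the same length, both classes
#'   present.
#' @param ci_method `"hanley"` (default, closed form) or `"delong"`.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`,
#'   `ci_method`.
#' @export
roc_auc_ci <- function(predictor, outcome, ci_method = c("hanley", "delong"),
                       conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(predictor) & !is.na(outcome)
  predictor <- predictor[keep]; outcome <- as.integer(outcome[keep])
  if (any(!is.finite(predictor))) {
    stop("predictor contains non-finite values", call. = FALSE)
  }
  if (!all(outcome %in% c(0L, 1L))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  n1 <- sum(outcome == 1L); n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop(sprintf("ROC needs both classes; got %d positive and %d negative",
                 n1, n0), call. = FALSE)
  }
  # Mann-Whitney via mid-ranks: ties contribute 1/2 automatically
  r <- rank(predictor)
  auc <- (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (ci_method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(auc - z * se, auc + z * se)
  } else {
    if (!requireNamespace("pROC", quietly = TRUE)) {
      stop("ci_method = \"delong\" requires the pROC package", call. = FALSE)
    }
    roc <- pROC::roc(response = outcome, predictor = predictor,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(roc, method = "delong",
                                  conf.level = conf_level))[c(1, 3)]
  }
  ci <- pmin(pmax(ci, 0), 1)
  list(auc = auc, ci_low = min(ci[1], auc), ci_high = max(ci[2], auc),
       n_pos = n1, n_neg = n0, ci_method = ci_method)
}

#' Validate the model against observed counts
#'
#' Runs [predict_series()], then for each lag computes (i) the Pearson
#' correlation between the model prediction at day `t` and the observed
#' count at day `t + lag`, and (ii) the ROC AUC of each pollutant and of
#' the model prediction against the observed counts dichotomized at the
#' cutoff.
#'
#' @param series Data frame with the exposure columns and an observed
#'   `hospitalizations` count column.
#' @param fis Model to validate (default [respiratory_fis()]).
#' @param lags Integer vector of day lags (default `0:3`).
#' @param cutoff Count cutoff for dichotomization (default 2; positive
#'   class is `count > cutoff`).
#' @param ci_method Confidence-interval method for [roc_auc_ci()].
#' @param predictors Character vector of ROC predictor columns; the
#'   model prediction is always included as `model_prediction`.
#' @param warn_clamp Passed to [predict_series()].
#' @return An object of class `validation_report`: list with `pearson`
#'   (data frame lag/r/p_value/n_pairs), `roc` (data frame
#'   predictor/lag/auc/ci_low/ci_high/n_pos/n_neg), `cutoff`,
#'   `ci_method`, `predictions` and `schema_version`.
#' @export
validate_series <- function(series, fis = respiratory_fis(), lags = 0:3,
                            cutoff = 2L, ci_method = c("hanley", "delong"),
                            predictors = c("pm10", "no2"),
                            warn_clamp = FALSE) {
  ci_method <- match.arg(ci_method)
  if (!"hospitalizations" %in% names(series)) {
    stop("series must contain an observed `hospitalizations` column",
         call. = FALSE)
  }
  obs <- series$hospitalizations
  pred <- predict_series(fis, series, warn_clamp = warn_clamp)

  pearson <- do.call(rbind, lapply(lags, function(l) {
    pr <- pearson_with_p(lag_align(pred, obs, l))
    data.frame(lag = l, r = pr$r, p_value = pr$p_value,
               n_pairs = pr$n_pairs)
  }))

  roc_predictors <- c(predictors, "model_prediction")
  roc <- do.call(rbind, lapply(roc_predictors, function(p) {
    score <- if (p == "model_prediction") pred else series[[p]]
    if (is.null(score)) {
      stop(sprintf("predictor column '%s' not found", p), call. = FALSE)
    }
    do.call(rbind, lapply(lags, function(l) {
      al <- lag_align(score, obs, l)
      cls <- dichotomize(al$y, cutoff = cutoff)
      rr <- roc_auc_ci(al$x, as.integer(cls), ci_method = ci_method)
      data.frame(predictor = p, lag = l, auc = rr$auc,
                 ci_low = rr$ci_low, ci_high = rr$ci_high,
                 n_pos = rr$n_pos, n_neg = rr$n_neg)
    }))
  }))

  structure(list(pearson = pearson, roc = roc, cutoff = as.integer(cutoff),
                 ci_method = ci_method, predictions = pred,
                 schema_version = "1.0"),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (cutoff > %d, %s CI)\n", x$cutoff,
              x$ci_method))
  cat("Lagged Pearson correlation (model prediction vs observed):\n")
  print(transform(x$pearson, r = round(r, 3), p_value = signif(p_value, 4)),
        row.names = FALSE)
  cat("ROC AUC by predictor and lag:\n")
  print(transform(x$roc, auc = round(auc, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3)), row.names = FALSE)
  invisible(x)
}

#' Serialize / restore a validation report as JSON
#'
#' @param report A `validation_report` from [validate_series()].
#' @param path Output (or input) JSON file path.
#' @return `write_report_json()` returns `path` invisibly;
#'   `read_report_json()` returns the restored report.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$pearson <- as.data.frame(obj$pearson)
  obj$roc <- as.data.frame(obj$roc)
  obj$cutoff <- as.integer(obj$cutoff)
  structure(obj, class = "validation_report")
}
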