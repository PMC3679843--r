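#' Predictive squared correlation coefficient
#'
#' \deqn{Q^2 = 1 - \frac{\sum_j (\hat y_j - y_j)^2 / n_{TS}}
#'                     {\sum_i (y_i - \bar y_{TR})^2 / n_{TR}}}
#' The numerator is the mean squared prediction error over the test samples;
#' the denominator is the mean squared deviation of the *training* responses
#' around the *training* mean — each sum is divided by its own sample count.
#'
#' @param y_test Measured test responses.
#' @param yhat_test Predicted test responses (same length).
#' @param y_train Measured training responses (defines the reference mean
#'   and variance).
#' @return The scalar Q^2 (1 for perfect predictions; can be negative).
#' @export
q_squared <- function(y_test, yhat_test, y_train) {
  if (length(y_test) != length(yhat_test)) stop("test vectors differ in length.")
  if (length(y_test) < 1L) stop("need at least one test sample.")
  denom <- mean((y_train - mean(y_train))^2)
  if (denom == 0) stop("training responses have zero variance; Q^2 undefined.")
  1 - mean((yhat_test - y_test)^2) / denom
}

#' Absolute standardized prediction errors
#'
#' \deqn{SE_j = |y_j - \hat y_j| / s_Y}
#' where `s_Y` is the standard error of estimate of the underlying model on
#' its training set. Values above 2 (conventionally 2-3) flag
#' response-domain outliers.
#'
#' @param y Measured responses.
#' @param yhat Predicted responses.
#' @param s_Y Training standard error of estimate, strictly positive.
#' @return Nonnegative numeric vector.
#' @export
standardized_errors <- function(y, yhat, s_Y) {
  if (!is.numeric(s_Y) || length(s_Y) != 1L || s_Y <= 0)
    stop("s_Y must be a single positive number.")
  if (length(y) != length(yhat)) stop("y and yhat differ in length.")
  abs(y - yhat) / s_Y
}

#' Training standard error of estimate
#'
#' Root mean squared training residual
#' \eqn{\sqrt{\sum_i (y_i - \hat y_i)^2 / n_{TR}}} (RMSE convention). Pass
#' an externally reported value to [build_report()] via `s_Y_override` when
#' the original model's own statistic should be used instead.
#'
#' @param y_train Measured training responses.
#' @param yhat_train Predicted training responses.
#' @return The scalar RMSE (0 for a perfect fit, in which case standardized
#'   errors are undefined and must not be computed from it).
#' @export
training_standard_error <- function(y_train, yhat_train) {
  if (length(y_train) != length(yhat_train)) stop("training vectors differ in length.")
  if (length(y_train) < 2L) stop("need at least 2 training samples.")
  sqrt(mean((y_train - yhat_train)^2))
}

#' Build a reliability report for AD decisions
#'
#' Combines the descriptor-space AD decisions with the response domain:
#' Q^2 is computed over the retained (in-AD) test samples only — samples
#' outside the AD are unreliably predicted and excluded from the model
#' statistic — while the absolute standardized error `SE_j` and the
#' reliability count `K_j` are reported for every scored sample. Samples
#' with `SE_j` above `se_warning` (default 2) are flagged as response-domain
#' outliers.
#'
#' @param decisions Data frame from [apply_ad()] (columns `sample_id`,
#'   `in_ad`, `K_j`).
#' @param query The scored [descriptor_table()]; must carry `y` and `y_hat`.
#' @param y_train Measured training responses (for the Q^2 denominator).
#' @param yhat_train Optional predicted training responses, used to derive
#'   `s_Y` when no override is given.
#' @param s_Y_override Optional externally supplied standard error of
#'   estimate (e.g. the published RMSE of the model under study).
#' @param se_warning Standardized-error warning threshold (default 2;
#'   3 is the lenient convention).
#' @return An object of class `reliability_report`: `n_retained`,
#'   `q2_retained` (`NA` when no sample is retained), `excluded_ids`,
#'   `per_sample` data frame, `s_Y`, `se_warning_ids`.
#' @export
build_report <- function(decisions, query, y_train, yhat_train = NULL,
                         s_Y_override = NULL, se_warning = 2) {
  stopifnot(inherits(query, "descriptor_table"))
  if (is.null(query$y) || is.null(query$y_hat))
    stop("query table must carry measured (y) and predicted (y_hat) responses.")
  if (!all(c("sample_id", "in_ad", "K_j") %in% names(decisions)))
    stop("`decisions` must come from apply_ad().")
  ord <- match(query$ids, decisions$sample_id)
  if (anyNA(ord)) stop("decisions are missing some query samples.")
  dec <- decisions[ord, ]
  s_Y <- if (!is.null(s_Y_override)) s_Y_override
         else if (!is.null(yhat_train)) training_standard_error(y_train, yhat_train)
         else stop("supply yhat_train or s_Y_override to derive s_Y.")
  if (s_Y <= 0) stop("s_Y is not positive; standardized errors are undefined.")
  se <- standardized_errors(query$y, query$y_hat, s_Y)
  retained <- dec$in_ad
  q2 <- if (any(retained))
    q_squared(query$y[retained], query$y_hat[retained], y_train) else NA_real_
  per_sample <- data.frame(sample_id = query$ids, in_ad = dec$in_ad,
                           K_j = dec$K_j, SE_j = se, y = query$y,
                           y_hat = query$y_hat, stringsAsFactors = FALSE,
                           row.names = NULL)
  structure(list(n_retained = sum(retained), q2_retained = q2,
                 excluded_ids = query$ids[!retained], per_sample = per_sample,
                 s_Y = s_Y, se_warning = se_warning,
                 se_warning_ids = query$ids[se > se_warning]),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  n <- nrow(x$per_sample)
  cat(sprintf("<reliability_report> %d scored samples\n", n))
  cat(sprintf("  retained in AD: %d   Q^2 (retained): %s\n", x$n_retained,
              if (is.na(x$q2_retained)) "undefined" else sprintf("%.3f", x$q2_retained)))
  cat(sprintf("  outside AD: %s\n",
              if (length(x$excluded_ids)) paste(x$excluded_ids, collapse = " ") else "none"))
  cat(sprintf("  SE_j > %g (response-domain outliers): %s\n", x$se_warning,
              if (length(x$se_warning_ids)) paste(x$se_warning_ids, collapse = " ") else "none"))
  invisible(x)
}

#' Write a reliability report
#'
#' Writes the per-sample table as delimited text and the summary as JSON.
#'
#' @param report A [build_report()] result.
#' @param table_path,summary_path Output paths (either may be `NULL`).
#' @param delimiter Field delimiter.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, table_path = NULL, summary_path = NULL,
                         delimiter = ",") {
  stopifnot(inherits(report, "reliability_report"))
  if (!is.null(table_path))
    utils::write.table(report$per_sample, table_path, sep = delimiter,
                       row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(list(
      n_retained = report$n_retained, q2_retained = report$q2_retained,
      excluded_ids = as.list(report$excluded_ids), s_Y = report$s_Y,
      se_warning = report$se_warning,
      se_warning_ids = as.list(report$se_warning_ids)),
      summary_path, digits = NA, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(report)
}

#' Scatter plot of standardized error against the reliability count
#'
#' @param report A [build_report()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `report`, invisibly.
#' @export
plot_se_vs_kj <- function(report, ...) {
  stopifnot(inherits(report, "reliability_report"))
  ps <- report$per_sample
  graphics::plot(ps$K_j, ps$SE_j, xlab = expression(K[j]),
                 ylab = "absolute standardized error",
                 pch = ifelse(ps$in_ad, 16, 4),
                 col = ifelse(ps$in_ad, "black", "red"), ...)
  graphics::abline(h = report$se_warning, lty = 2, col = "grey40")
  invisible(report)
}
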