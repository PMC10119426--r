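#' External-validation R-squared
#'
#' `R2ext = 1 - sum((y_i - yhat_i)^2) / sum((y_i - ybar_train)^2)` over the
#' test set, where `ybar_train` is the mean activity of the *training*
#' compounds.  Values above 0.5 are the conventional evidence of stable
#' external predictive power.
#'
#' @param y_test Observed test-set activities.
#' @param yhat_test Predicted test-set activities.
#' @param ytrain_mean Mean of the training-set activities.
#' @return Numeric R2ext.
#' @export
r2_ext <- function(y_test, yhat_test, ytrain_mean) {
  y_test <- as.numeric(y_test); yhat_test <- as.numeric(yhat_test)
  if (length(y_test) == 0L) stop("test set is empty")
  if (length(y_test) != length(yhat_test)) stop("length mismatch")
  den <- sum((y_test - ytrain_mean)^2)
  if (den <= 0)
    stop("all test activities equal the training mean: R2ext undefined")
  1 - sum((y_test - yhat_test)^2) / den
}

#' Standard model-quality metrics
#'
#' Computes, with their conventional QSAR definitions: `r2 = 1 - RSS/TSS`,
#' `SEE = sqrt(RSS / (n - n_params - 1))`, the overall F statistic
#' `(r2/n_params) / ((1 - r2)/(n - n_params - 1))`, the Pearson correlation
#' between observed and predicted, the mean absolute error, and the RMSE
#' (so "average error" can be read either way).
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @param n_params Number of predictors or latent components consumed.
#' @return Named list: `r2`, `see`, `f`, `pearson_r`, `mae`, `rmse`, `n`,
#'   `n_params`.
#' @export
summary_metrics <- function(y, yhat, n_params) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("length mismatch")
  n <- length(y)
  if (n <= n_params + 1L) stop("need n > n_params + 1 observations")
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("zero-variance observations: metrics undefined")
  rss <- sum((y - yhat)^2)
  r2 <- 1 - rss / tss
  dof <- n - n_params - 1L
  see <- sqrt(rss / dof)
  f <- if (r2 < 1) (r2 / n_params) / ((1 - r2) / dof) else Inf
  pr <- if (stats::sd(yhat) > 0) stats::cor(y, yhat) else NA_real_
  list(r2 = r2, see = see, f = f, pearson_r = pr,
       mae = mean(abs(y - yhat)), rmse = sqrt(mean((y - yhat)^2)),
       n = n, n_params = as.integer(n_params))
}

#' External-validation verdict
#'
#' Pass if and only if R2ext strictly exceeds 0.5.
#'
#' @param r2ext Numeric R2ext value.
#' @return `"pass"` or `"fail"`.
#' @export
verdict <- function(r2ext) {
  if (!is.finite(r2ext)) stop("R2ext must be finite")
  if (r2ext > 0.5) "pass" else "fail"
}

#' Assemble a full validation report
#'
#' @param y_train,yhat_train Training observations and predictions.
#' @param y_test,yhat_test Test observations and predictions.
#' @param n_params Predictors/components used by the model.
#' @return List of class `validation_report`: `r2_ext`, per-set
#'   [summary_metrics()], and the pass/fail `verdict`.
#' @export
validation_report <- function(y_train, yhat_train, y_test, yhat_test,
                              n_params) {
  r2e <- r2_ext(y_test, yhat_test, mean(y_train))
  structure(list(r2_ext = r2e,
                 train = summary_metrics(y_train, yhat_train, n_params),
                 test = summary_metrics(y_test, yhat_test, n_params),
                 verdict = verdict(r2e)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> R2ext = ", format(x$r2_ext, digits = 4), " (",
      x$verdict, ")\n", sep = "")
  cat(sprintf("  train: r2 = %.4f, r = %.4f, MAE = %.4f, RMSE = %.4f\n",
              x$train$r2, x$train$pearson_r, x$train$mae, x$train$rmse))
  cat(sprintf("  test:  r2 = %.4f, r = %.4f, MAE = %.4f, RMSE = %.4f\n",
              x$test$r2, x$test$pearson_r, x$test$mae, x$test$rmse))
  invisible(x)
}
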