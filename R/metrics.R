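#' Shared regression metrics
#'
#' Single implementation of the evaluation metrics used throughout the
#' package (model fits, cross-validation, map ROI comparisons):
#' `rmse = sqrt(mean((obs - pred)^2))`,
#' `r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, and the mean
#' absolute percentage error `mape = mean(|100 (pred - obs) / obs|)`.
#'
#' @param obs Observed values.
#' @param pred Predicted values.
#' @return List with `rmse`, `r2`, `mape`, `n`.
#' @export
regression_metrics <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  rss <- sum((obs - pred)^2)
  tss <- sum((obs - mean(obs))^2)
  list(
    rmse = sqrt(rss / length(obs)),
    r2 = if (tss > 0) 1 - rss / tss else NA_real_,
    mape = if (any(obs == 0)) NA_real_ else mean(abs(100 * (pred - obs) / obs)),
    n = length(obs)
  )
}
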