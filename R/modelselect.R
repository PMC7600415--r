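## Fit diagnostics and model-selection criteria; ranking of candidate
## lactation-curve models per trait.

#' Selection criteria for one fitted lactation curve
#'
#' Least-squares information criteria (constants common to all models are
#' omitted, which preserves ranking):
#' RSS, MSPE = RSS/n, adjusted R-squared, AIC = n log(RSS/n) + 2k,
#' AICc = AIC + 2k(k+1)/(n-k-1), BIC = n log(RSS/n) + k log(n), the
#' Durbin-Watson statistic of the DIM-ordered residuals and the
#' Shapiro-Francia normality test of the residuals.
#'
#' @param fit a `"lactation_fit"` from [fit_lactation()].
#' @return one-row data.frame of class `"fit_criteria"`.
#' @export
fit_criteria <- function(fit) {
  stopifnot(inherits(fit, "lactation_fit"))
  n <- fit$n; k <- fit$k
  if (n < k + 2)
    stop_caprihap("criteria need n >= k + 2 observations", "caprihap_insufficient_data")
  rss <- fit$rss
  tss <- sum((fit$y - mean(fit$y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - k - 1)
  if (rss <= 1e-12 * max(tss, 1)) {   # numerically perfect fit
    warning("perfect fit: AIC family undefined (log of zero RSS)")
    aic <- aicc <- bic <- -Inf
    adj_r2 <- 1
  } else {
    aic <- n * log(rss / n) + 2 * k
    aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
    bic <- n * log(rss / n) + k * log(n)
  }
  sf <- tryCatch(shapiro_francia(fit$residuals),
                 error = function(e) list(w = NA_real_, p = NA_real_))
  dw <- tryCatch(durbin_watson(fit$residuals), error = function(e) NA_real_)
  structure(data.frame(model_id = fit$model_id, n = n, k = k, rss = rss,
                       mspe = rss / n, adj_r2 = adj_r2, aic = aic, aicc = aicc,
                       bic = bic, durbin_watson = dw,
                       shapiro_francia_w = sf$w, shapiro_francia_p = sf$p,
                       fitted_ok = isTRUE(fit$converged),
                       stringsAsFactors = FALSE),
            class = c("fit_criteria", "data.frame"))
}

#' Durbin-Watson statistic
#'
#' First-order autocorrelation diagnostic
#' \eqn{DW = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2} on residuals ordered by
#' days in milk. Values near 2 indicate no first-order autocorrelation.
#'
#' @param residuals residual vector in time order, `n >= 2`.
#' @return the statistic in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  n <- length(residuals)
  if (n < 2) stop_caprihap("Durbin-Watson needs n >= 2", "caprihap_insufficient_data")
  denom <- sum(residuals^2)
  if (denom == 0)
    stop_caprihap("Durbin-Watson undefined for all-zero residuals", "caprihap_domain_error")
  sum(diff(residuals)^2) / denom
}

#' Average residuals by day in milk
#'
#' The Durbin-Watson diagnostic is applied to the average residual of each
#' lactation day rather than the raw per-record residuals; this helper
#' performs that aggregation.
#'
#' @param dim days in milk per residual.
#' @param residuals residuals.
#' @return data.frame `dim`, `mean_residual`, sorted by `dim`.
#' @export
residuals_by_dim <- function(dim, residuals) {
  stopifnot(length(dim) == length(residuals))
  agg <- tapply(residuals, dim, mean)
  data.frame(dim = as.integer(names(agg)), mean_residual = as.numeric(agg))
}

#' Shapiro-Francia normality test
#'
#' W' is the squared correlation between the order statistics of `x` and the
#' Blom normal scores \eqn{m_i = \Phi^{-1}((i - 3/8)/(n + 1/4))}; the p-value
#' uses Royston's normal approximation for \eqn{\log(1 - W')} (valid for
#' 5 <= n <= ~5000).
#'
#' @param x numeric sample, `n >= 5`, not constant.
#' @return list with `w` and `p`.
#' @export
shapiro_francia <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop_caprihap("Shapiro-Francia needs n >= 5", "caprihap_insufficient_data")
  if (stats::sd(x) == 0)
    stop_caprihap("Shapiro-Francia undefined for a constant sample", "caprihap_domain_error")
  xs <- sort(x)
  m <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  w <- stats::cor(xs, m)^2
  u <- log(n); v <- log(u)
  mu <- -1.2725 + 1.0521 * (v - u)
  sig <- 1.0308 - 0.26758 * (v + 2 / u)
  z <- (log(1 - w) - mu) / sig
  list(w = w, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Rank candidate models by aggregated selection criteria
#'
#' Candidates that did not converge on every lactation (fit success below
#' 100%) are excluded. The rest are ranked by the sum of ranks over mean
#' MSPE (lower better), mean adjusted R-squared (higher better), mean AIC,
#' mean AICc and mean BIC (lower better); ties broken by fewer parameters,
#' then lexical model id.
#'
#' @param criteria data.frame of per-lactation [fit_criteria()] rows (column
#'   `model_id` identifies the candidate), or a pre-aggregated data.frame
#'   with one row per model and columns `model_id, k, mspe, adj_r2, aic,
#'   aicc, bic, pct_fitted`.
#' @param aggregated set `TRUE` when passing the pre-aggregated form.
#' @return data.frame ranked best-first with the aggregated criteria, rank
#'   sum and final `rank`; attribute `"selected"` holds the winning id.
#' @export
select_best <- function(criteria, aggregated = FALSE) {
  if (!aggregated) {
    agg <- do.call(rbind, lapply(split(criteria, criteria$model_id), function(g) {
      data.frame(model_id = g$model_id[1], k = g$k[1],
                 mspe = mean(g$mspe), adj_r2 = mean(g$adj_r2),
                 aic = mean(g$aic), aicc = mean(g$aicc), bic = mean(g$bic),
                 pct_fitted = 100 * mean(g$fitted_ok), stringsAsFactors = FALSE)
    }))
  } else agg <- criteria
  ok <- agg[agg$pct_fitted >= 100, , drop = FALSE]
  if (!nrow(ok)) {
    best_partial <- agg$model_id[which.max(agg$pct_fitted)]
    stop_caprihap(sprintf(
      "no candidate reached 100%% fit success (best partial coverage: '%s' at %.1f%%)",
      best_partial, max(agg$pct_fitted)), "caprihap_selection_error")
  }
  rk <- rank(ok$mspe, ties.method = "average") +
    rank(-ok$adj_r2, ties.method = "average") +
    rank(ok$aic, ties.method = "average") +
    rank(ok$aicc, ties.method = "average") +
    rank(ok$bic, ties.method = "average")
  ok$rank_sum <- rk
  ord <- order(ok$rank_sum, ok$k, ok$model_id)
  ok <- ok[ord, , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  rownames(ok) <- NULL
  attr(ok, "selected") <- ok$model_id[1]
  ok
}
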