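## One-way ANOVA across haplotype groups: frequentist SS/F/p decomposition,
## JZS (Jeffreys-Zellner-Siow) Bayes factor by quadrature over the g mixing
## parameter, and reference-prior posterior summaries of group deviations
## with credible-interval significance flags.

#' One-way ANOVA decomposition
#'
#' Definitional sums of squares:
#' \eqn{SS_B = \sum_j n_j (\bar y_j - \bar y)^2},
#' \eqn{SS_W = \sum_j \sum_i (y_{ij} - \bar y_j)^2}, with
#' \eqn{df_B = J - 1}, \eqn{df_W = N - J}, mean squares \eqn{MS = SS/df},
#' \eqn{F = MS_B / MS_W} and p from the F distribution.
#'
#' @param groups named list of numeric vectors (one per group, each
#'   non-empty; at least two groups and `N > J`).
#' @return list of class `"anova_decomposition"` with the fields above plus
#'   `group_means`, `group_n`, `grand_mean`.
#' @export
anova_decompose <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop_caprihap("need >= 2 non-empty groups", "caprihap_data_error")
  n <- lengths(groups)
  N <- sum(n)
  J <- length(groups)
  if (N <= J) stop_caprihap("need more observations than groups", "caprihap_data_error")
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_between <- J - 1
  df_within <- N - J
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  if (ss_within == 0) {
    warning("zero within-group variance: F undefined")
    f <- NA_real_; p <- NA_real_
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, df_between, df_within, lower.tail = FALSE)
  }
  structure(list(ss_between = ss_between, ss_within = ss_within,
                 df_between = df_between, df_within = df_within,
                 ms_between = ms_between, ms_within = ms_within,
                 f = f, p = p, group_means = means, group_n = n,
                 grand_mean = grand, n_total = N),
            class = "anova_decomposition")
}

#' Mean squares and F ratio from printed sums of squares
#'
#' Reconstructs the mean-square and F arithmetic of a published ANOVA table
#' row: `ms = ss/df`, `f = ms_between/ms_within`.
#'
#' @param ss_between,df_between,ss_within,df_within positive numbers.
#' @return list `ms_between`, `ms_within`, `f`.
#' @export
#' @examples
#' f_from_ss(18562.178, 86, 37643.494, 3020)$f  # 17.316 at 3 d.p.
f_from_ss <- function(ss_between, df_between, ss_within, df_within) {
  for (v in c(ss_between, df_between, ss_within, df_within))
    check_number(v, "f_from_ss inputs", lower = .Machine$double.xmin)
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  list(ms_between = ms_b, ms_within = ms_w, f = ms_b / ms_w)
}

#' JZS Bayes factor for a one-way design
#'
#' Bayes factor of the group-effects model against the grand-mean-only null
#' under the Jeffreys-Zellner-Siow prior: Jeffreys priors on the grand mean
#' and error variance, a g-prior on the standardized group effects with
#' \eqn{g \sim \mathrm{InvGamma}(1/2,\ N r^2/2)} (equivalently a Cauchy
#' prior of scale \eqn{r} on effects), giving
#' \deqn{BF_{10} = \int_0^\infty (1+g)^{(N-1-p)/2}
#'   \left[1 + g(1-R^2)\right]^{-(N-1)/2} \pi(g)\, dg,}
#' with \eqn{p = J - 1} and \eqn{R^2 = SS_B/(SS_B+SS_W)}. The integral is
#' evaluated by deterministic one-dimensional quadrature, so the result
#' depends only on \eqn{(N, J, R^2)} and is location- and scale-invariant.
#'
#' @param groups named list of numeric group vectors, or an
#'   `"anova_decomposition"`.
#' @param rscale prior scale \eqn{r} (default 1).
#' @return `bf10`, the Bayes factor in favour of group effects.
#' @export
jzs_bf <- function(groups, rscale = 1) {
  dec <- if (inherits(groups, "anova_decomposition")) groups else anova_decompose(groups)
  N <- dec$n_total
  p <- dec$df_between
  sst <- dec$ss_between + dec$ss_within
  if (sst <= 0) stop_caprihap("zero total variance", "caprihap_data_error")
  r2 <- dec$ss_between / sst
  b <- N * rscale^2 / 2
  ## integrand on the log scale; InvGamma(1/2, b) density in g
  log_f <- function(g)
    (N - 1 - p) / 2 * log1p(g) - (N - 1) / 2 * log1p(g * (1 - r2)) +
      0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g
  ## substitute g = exp(u) to stabilize both tails: dg = e^u du; the
  ## integrand vanishes at both tails, so over/underflowing g maps to 0
  h <- function(u) {
    g <- exp(u)
    v <- ifelse(is.finite(g) & g > 0, exp(log_f(g) + u), 0)
    ifelse(is.finite(v), v, 0)
  }
  int <- tryCatch(
    stats::integrate(h, lower = -Inf, upper = Inf, rel.tol = 1e-10,
                     subdivisions = 500L),
    error = function(e) stop_caprihap(
      paste0("Bayes factor quadrature failed: ", conditionMessage(e)),
      "caprihap_quadrature_error"))
  if (int$message != "OK" || !is.finite(int$value) || int$value <= 0)
    stop_caprihap(paste0("Bayes factor quadrature did not converge (",
                         int$message, ")"), "caprihap_quadrature_error")
  int$value
}

#' Posterior group-deviation summaries with credible intervals
#'
#' Under the reference prior \eqn{p(\mu_1..\mu_J, \sigma^2) \propto
#' 1/\sigma^2} for the homoscedastic one-way model, the deviation of each
#' group mean from the observation-weighted grand mean,
#' \eqn{d_j = \mu_j - \sum_k n_k \mu_k / N}, has the Student-t posterior
#' \deqn{d_j \mid y \sim \bar y_j - \bar y_{\cdot\cdot}
#'   + \sqrt{MS_W (1/n_j - 1/N)}\; t_{N-J}.}
#' The central 95\% credible interval flags a group as significant when 0
#' falls outside it.
#'
#' @param groups named list of numeric group vectors (each `n >= 2`; smaller
#'   groups are skipped with a warning).
#' @param level credible level (default 0.95).
#' @return data.frame, one row per group: `group`, `n`, `mean`,
#'   `deviation`, `post_sd`, `ci_lower`, `ci_upper`, `significant`.
#' @export
group_posteriors <- function(groups, level = 0.95) {
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) {
    warning("skipping group(s) with n < 2: ", paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2]
  }
  dec <- anova_decompose(groups)
  if (dec$ss_within == 0)
    stop_caprihap("zero within-group variance: posterior scale undefined",
                  "caprihap_data_error")
  alpha <- (1 - level) / 2
  tq <- stats::qt(1 - alpha, dec$df_within)
  dev <- dec$group_means - dec$grand_mean
  sd_post <- sqrt(dec$ms_within * (1 / dec$group_n - 1 / dec$n_total)) *
    sqrt(dec$df_within / max(dec$df_within - 2, 1))
  scale <- sqrt(dec$ms_within * (1 / dec$group_n - 1 / dec$n_total))
  lo <- dev - tq * scale
  hi <- dev + tq * scale
  data.frame(group = names(groups), n = dec$group_n, mean = dec$group_means,
             deviation = dev, post_sd = sd_post, ci_lower = lo, ci_upper = hi,
             significant = lo > 0 | hi < 0, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full Bayesian-and-frequentist one-way analysis of one response
#'
#' Convenience wrapper: decomposition, F/p, JZS Bayes factor and group
#' posteriors for one trait or curve-shape parameter across haplotype
#' groups.
#'
#' @param values numeric response vector.
#' @param group group label per value.
#' @param trait,parameter labels carried into the result.
#' @param rscale JZS prior scale.
#' @param level credible level.
#' @return list of class `"haplotype_anova"`: `trait`, `parameter`,
#'   `anova` (decomposition), `bf10`, `posteriors`, `significant`
#'   (frequentist p < 0.05).
#' @export
haplotype_anova <- function(values, group, trait = "trait", parameter = "level",
                            rscale = 1, level = 0.95) {
  stopifnot(length(values) == length(group))
  ok <- is.finite(values) & !is.na(group)
  groups <- split(values[ok], as.character(group[ok]))
  dec <- anova_decompose(groups)
  bf <- tryCatch(jzs_bf(dec, rscale = rscale), error = function(e) NA_real_)
  post <- tryCatch(group_posteriors(groups, level = level),
                   error = function(e) NULL)
  structure(list(trait = trait, parameter = parameter, anova = dec, bf10 = bf,
                 posteriors = post,
                 significant = is.finite(dec$p) && dec$p < 0.05),
            class = "haplotype_anova")
}

#' @export
print.haplotype_anova <- function(x, ...) {
  a <- x$anova
  cat(sprintf("<haplotype_anova %s / %s>\n", x$trait, x$parameter))
  cat(sprintf("  Between: SS = %.3f, df = %d, MS = %.3f\n",
              a$ss_between, a$df_between, a$ms_between))
  cat(sprintf("  Within:  SS = %.3f, df = %d, MS = %.3f\n",
              a$ss_within, a$df_within, a$ms_within))
  cat(sprintf("  F = %.3f, p = %.4g, BF10 = %.4g\n", a$f, a$p, x$bf10))
  invisible(x)
}

#' ANOVA results as a publication-style table
#'
#' One Between and one Within row per analysis, mirroring the usual one-way
#' report layout (SS, df, MS, F, p, BF10).
#'
#' @param analyses list of `"haplotype_anova"` objects.
#' @return data.frame.
#' @export
anova_table <- function(analyses) {
  rows <- lapply(analyses, function(x) {
    a <- x$anova
    data.frame(trait = x$trait, parameter = x$parameter,
               source = c("Between", "Within"),
               sum_sq = c(a$ss_between, a$ss_within),
               df = c(a$df_between, a$df_within),
               mean_sq = c(a$ms_between, a$ms_within),
               f = c(a$f, NA), p = c(a$p, NA), bf10 = c(x$bf10, NA),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
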