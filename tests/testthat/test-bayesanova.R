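test_that("ANOVA decomposition matches the definitional brute force", {
  set.seed(19)
  groups <- list(a = rnorm(5, 1), b = rnorm(5, 1.4), c = rnorm(5, 0.6))
  dec <- anova_decompose(groups)

  ## brute force over every observation
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ssb <- ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (y in g) ssw <- ssw + (y - mean(g))^2
  }
  expect_equal(dec$ss_between, ssb, tolerance = 1e-12)
  expect_equal(dec$ss_within, ssw, tolerance = 1e-12)
  expect_equal(dec$df_between, 2L)
  expect_equal(dec$df_within, 12L)
  expect_identical(dec$ms_between, dec$ss_between / dec$df_between)
  expect_identical(dec$f, dec$ms_between / dec$ms_within)
  expect_equal(dec$p, pf(dec$f, 2, 12, lower.tail = FALSE))

  ## conservation: SS_between + SS_within = total SS
  sst <- sum((all_y - grand)^2)
  expect_equal(dec$ss_between + dec$ss_within, sst, tolerance = 1e-9 * sst)

  ## cross-check against R's own one-way fit
  fit <- anova(lm(all_y ~ rep(names(groups), lengths(groups))))
  expect_equal(dec$f, fit$`F value`[1], tolerance = 1e-10)

  ## all means equal: SS_between 0 (up to rounding), F ~ 0
  eq <- list(a = c(1, 2, 3), b = c(2, 1, 3))
  expect_lt(anova_decompose(eq)$ss_between, 1e-12)

  ## degenerate zero within-variance is signalled
  expect_warning(d0 <- anova_decompose(list(a = c(0, 0), b = c(1, 1))),
                 "F undefined")
  expect_equal(d0$ss_between, 1)
  expect_true(is.na(d0$f))

  expect_error(anova_decompose(list(a = 1:3)), class = "caprihap_data_error")
})

test_that("f_from_ss reproduces mean squares and the F ratio", {
  r <- f_from_ss(18562.178, 86, 37643.494, 3020)
  expect_equal(r$ms_between, 18562.178 / 86)
  expect_equal(r$ms_within, 37643.494 / 3020)
  expect_equal(r$f, r$ms_between / r$ms_within)

  ## identity: equal numerator and denominator
  expect_equal(f_from_ss(7.5, 3, 7.5, 3)$f, 1)
  expect_error(f_from_ss(1, 0, 1, 1), class = "caprihap_config_error")

  ## consistency with anova_decompose's own SS
  set.seed(4)
  dec <- anova_decompose(list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8)))
  r2 <- f_from_ss(dec$ss_between, dec$df_between, dec$ss_within, dec$df_within)
  expect_identical(r2$f, dec$f)
})

test_that("JZS Bayes factor: invariance, monotonicity and null behaviour", {
  set.seed(41)
  groups <- list(a = rnorm(10), b = rnorm(10, 0.5), c = rnorm(10, 1))
  bf <- jzs_bf(groups)

  ## location-scale invariance
  expect_equal(jzs_bf(lapply(groups, function(x) 4.2 * x - 3)), bf,
               tolerance = 1e-9)

  ## strictly increasing in the evidence: shift one group mean outward
  shifts <- c(0, 0.5, 1, 2, 4)
  bfs <- vapply(shifts, function(s) {
    g <- groups; g$c <- groups$c + s
    jzs_bf(g)
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))

  ## null data: bf10 < 1 with high probability
  n_below <- 0
  for (i in 1:20) {
    set.seed(100 + i)
    g0 <- list(a = rnorm(25), b = rnorm(25), c = rnorm(25))
    if (jzs_bf(g0) < 1) n_below <- n_below + 1
  }
  expect_gte(n_below, 16)   # ~90% expected under H0

  ## determinism
  expect_identical(jzs_bf(groups), jzs_bf(groups))
})

test_that("JZS Bayes factor agrees with a Monte-Carlo marginal-likelihood oracle", {
  set.seed(53)
  groups <- list(g1 = rnorm(10, 0), g2 = rnorm(10, 0.8), g3 = rnorm(10, 0.3))
  bf <- jzs_bf(groups)

  ## oracle: MC average over the InvGamma(1/2, N/2) prior on g of the
  ## conditional Bayes factor derived independently via the projection
  ## identity V_g = I + g P (P the centered group-space projector):
  ## |V_g| = (1+g)^p and y' V_g^{-1} y = SST - g/(1+g) SSB
  y <- unlist(groups)
  lab <- rep(names(groups), lengths(groups))
  N <- length(y); J <- 3; p <- J - 1
  grand <- mean(y)
  sst <- sum((y - grand)^2)
  ssb <- sum(tapply(y, lab, function(g) length(g) * (mean(g) - grand)^2))
  set.seed(54)
  gdraw <- 1 / rgamma(1e5, shape = 0.5, rate = N / 2)
  log_bf_g <- -p / 2 * log1p(gdraw) -
    (N - 1) / 2 * log(1 - gdraw / (1 + gdraw) * ssb / sst)
  mx <- max(log_bf_g)
  bf_mc <- exp(mx) * mean(exp(log_bf_g - mx))
  expect_equal(bf, bf_mc, tolerance = 0.02)
})

test_that("group posteriors have calibrated t-form credible intervals", {
  set.seed(61)
  groups <- list(a = rnorm(12, 5), b = rnorm(12, 5), c = rnorm(12, 5))
  post <- group_posteriors(groups)
  expect_equal(nrow(post), 3L)
  expect_true(all(post$ci_lower < post$ci_upper))

  ## a group equal to the grand mean has its CI centered at ~0
  dec <- anova_decompose(groups)
  expect_equal(post$deviation, unname(dec$group_means - dec$grand_mean))

  ## a strong planted shift is flagged
  groups$d <- rnorm(20, 5 + 10 * sd(unlist(groups)))
  post2 <- group_posteriors(groups)
  expect_true(post2$significant[post2$group == "d"])

  ## endpoints match a brute-force joint posterior sampling oracle
  set.seed(62)
  g3 <- list(a = rnorm(8, 2), b = rnorm(15, 2.6), c = rnorm(5, 1.9))
  post3 <- group_posteriors(g3)
  dec3 <- anova_decompose(g3)
  ndraw <- 1e5
  sig2 <- dec3$ss_within / rchisq(ndraw, dec3$df_within)
  devs <- sapply(seq_along(g3), function(j) {
    mus <- sapply(seq_along(g3), function(k)
      rnorm(ndraw, mean(g3[[k]]), sqrt(sig2 / length(g3[[k]]))))
    mus[, j] - mus %*% (lengths(g3) / dec3$n_total)
  })
  for (j in seq_along(g3)) {
    qs <- quantile(devs[, j], c(0.025, 0.975))
    expect_lt(abs(post3$ci_lower[j] - qs[1]), 0.02)
    expect_lt(abs(post3$ci_upper[j] - qs[2]), 0.02)
  }

  ## small groups are skipped with a warning
  expect_warning(p4 <- group_posteriors(list(a = rnorm(5), b = 1, c = rnorm(5))),
                 "skipping")
  expect_equal(nrow(p4), 2L)
})

test_that("haplotype_anova bundles decomposition, BF and posteriors", {
  set.seed(71)
  vals <- c(rnorm(20, 3), rnorm(20, 3.5))
  grp <- rep(c("H1", "H2"), each = 20)
  res <- haplotype_anova(vals, grp, trait = "milk_kg")
  expect_s3_class(res, "haplotype_anova")
  expect_equal(res$anova$df_between, 1L)
  expect_true(is.finite(res$bf10))
  expect_equal(nrow(res$posteriors), 2L)

  tab <- anova_table(list(res))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$mean_sq, tab$sum_sq / tab$df)
  expect_equal(tab$f[1], tab$mean_sq[1] / tab$mean_sq[2])
})
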