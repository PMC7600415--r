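test_that("configuration invariants are enforced", {
  expect_error(sim_config(haplotype_freqs = c(A = 0.6, B = 0.5)),
               class = "caprihap_config_error")
  expect_error(sim_config(n_goats = 0), class = "caprihap_config_error")
  expect_error(sim_config(control_interval_range = c(42, 28)),
               class = "caprihap_config_error")
  expect_error(sim_config(noise_sd = c(default_noise_sd()[-1], milk_kg = -1)),
               class = "caprihap_config_error")
  expect_error(assign_diplotypes(numeric(0), 10), class = "caprihap_config_error")
})

test_that("diplotype draws follow Hardy-Weinberg and are seed-reproducible", {
  freqs <- c(H1 = 1)
  dip <- assign_diplotypes(freqs, 10, seed = 4)
  expect_true(all(dip == "H1"))

  a <- assign_diplotypes(c(A = 0.25, B = 0.75), 500, seed = 99)
  b <- assign_diplotypes(c(A = 0.25, B = 0.75), 500, seed = 99)
  expect_identical(a, b)

  ## homozygote/heterozygote proportions near p^2 : 2pq : q^2
  big <- assign_diplotypes(c(A = 0.3, B = 0.7), 6000, seed = 8)
  het <- mean(big[, 1] != big[, 2])
  expect_equal(het, 2 * 0.3 * 0.7, tolerance = 3 * sqrt(0.42 * 0.58 / 6000) / 0.42)
})

test_that("the generated herd matches its configured structure", {
  cfg <- sim_config(seed = 17)  # defaults: 159 goats, 3.91 lact, 5 controls
  ds <- simulate_herd(cfg)

  n_goats <- length(unique(ds$records$animal_id))
  expect_equal(n_goats, 159L)
  expect_in(unique(ds$records$farm_id), sprintf("F%02d", 1:28))

  ## expected record count ~ 159 * 3.91 * 5 = 3108; Poisson lactation
  ## counts give SD ~ sqrt(159 * 2.91) * 5 ~ 108
  expect_gt(nrow(ds$records), 3108 - 4 * 108)
  expect_lt(nrow(ds$records), 3108 + 4 * 108)

  lact <- build_lactations(ds$records)
  per_goat <- table(vapply(lact, `[[`, "", "animal_id"))
  expect_equal(mean(per_goat), 3.91, tolerance = 4 * sqrt(2.91 / 159))

  ## ~5 controls per lactation, first control near day 21
  n_controls <- vapply(lact, function(s) nrow(s$records), numeric(1))
  expect_equal(mean(n_controls), 5, tolerance = 0.05)
  d1 <- vapply(lact, `[[`, numeric(1), "d1")
  expect_equal(mean(d1), 21, tolerance = 4 * 4 / sqrt(length(d1)))

  ## control dates inside the animal's lactation window
  expect_true(all(ds$records$dim >= 1 & ds$records$dim <= 240))

  ## every record's animal appears in the assignments
  expect_in(ds$records$animal_id, ds$assignments$animal_id)

  ## determinism: identical seed, identical dataset
  ds2 <- simulate_herd(cfg)
  expect_identical(ds$records, ds2$records)
  expect_identical(ds$assignments$haplotype, ds2$assignments$haplotype)
  ds3 <- simulate_herd(sim_config(seed = 18))
  expect_false(identical(ds$records$milk_kg, ds3$records$milk_kg))
})

test_that("noiseless single-haplotype records sit exactly on the base curve", {
  cfg <- sim_config(n_goats = 12, n_farms = 3,
                    haplotype_freqs = c(H1 = 1),
                    noise_sd = c(milk_kg = 0, fat_pct = 0, protein_pct = 0,
                                 dry_matter_pct = 0, lactose_pct = 0, scc = 0),
                    seed = 2)
  ds <- simulate_herd(cfg)
  base <- cfg$base_curve_params
  expect_equal(ds$records$milk_kg,
               ali_schaeffer(ds$records$dim, base$milk_kg), tolerance = 1e-12)
  expect_equal(ds$records$protein_pct,
               ali_schaeffer(ds$records$dim, base$protein_pct), tolerance = 1e-12)
  expect_equal(ds$records$scc,
               parabolic_yield_density(ds$records$dim, base$scc), tolerance = 1e-12)
})

test_that("fitting noiseless lactations recovers the generating parameters", {
  cfg <- sim_config(n_goats = 6, n_farms = 2, haplotype_freqs = c(H1 = 1),
                    controls_per_lactation = 7,
                    control_interval_range = c(25, 28),
                    noise_sd = c(milk_kg = 0, fat_pct = 0, protein_pct = 0,
                                 dry_matter_pct = 0, lactose_pct = 0, scc = 0),
                    seed = 23)
  ds <- simulate_herd(cfg)
  lact <- build_lactations(ds$records)
  for (s in lact[1:5]) {
    fit <- fit_lactation(s$records$dim, s$records$milk_kg, "ali_schaeffer")
    expect_true(fit$converged)
    expect_equal(fit$b, cfg$base_curve_params$milk_kg, tolerance = 1e-6)
    fit2 <- fit_lactation(s$records$dim, s$records$scc, "parabolic_yield_density")
    expect_equal(fit2$b, cfg$base_curve_params$scc, tolerance = 1e-6)
  }
})

test_that("a planted b0 shift is recovered in group mean standardized yields", {
  shift <- 0.5
  cfg <- sim_config(n_goats = 200, n_farms = 10,
                    haplotype_freqs = c(Base = 0.5, Plus = 0.5),
                    effect_sizes = list(Plus = c(milk_kg = shift / 2)),
                    noise_sd = c(milk_kg = 0.1, fat_pct = 0.1, protein_pct = 0.1,
                                 dry_matter_pct = 0.1, lactose_pct = 0.1, scc = 0.1),
                    seed = 77)
  ## each Plus copy adds shift/2 to b0, so Plus/Plus vs Base/Base differ by
  ## `shift` kg/day, i.e. 210*shift kg of standardized yield
  ds <- simulate_herd(cfg)
  lact <- build_lactations(ds$records)
  yt <- lactation_table(lact)
  dip <- ds$diplotypes
  hom_plus <- dip$animal_id[dip$hap1 == "Plus" & dip$hap2 == "Plus"]
  hom_base <- dip$animal_id[dip$hap1 == "Base" & dip$hap2 == "Base"]
  ya <- yt$yield210_milk_kg[yt$animal_id %in% hom_plus]
  yb <- yt$yield210_milk_kg[yt$animal_id %in% hom_base]
  diff_hat <- mean(ya) - mean(yb)
  se <- sqrt(var(ya) / length(ya) + var(yb) / length(yb))
  expect_lt(abs(diff_hat - 210 * shift), 3 * se)
})
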