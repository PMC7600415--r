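## Synthetic herd generator. Emulates the milk-recording structure the
## analysis assumes: 159 goats on 28 farms, about 3.91 lactations per goat,
## about 5 controls per lactation starting ~21 days after kidding at 4-6
## week intervals, lactations of 210-240 days, and casein-complex
## diplotypes drawn under Hardy-Weinberg proportions with additive
## haplotype effects on the curve level (b0) of each trait.

SIM_TRAITS <- c("milk_kg", "fat_pct", "protein_pct", "dry_matter_pct",
                "lactose_pct", "scc")

#' Simulation configuration
#'
#' Defaults restate the structure of the herd the pipeline targets:
#' 159 goats, 28 farms, mean 3.91 lactations per goat, 5 controls per
#' lactation, first control around day 21, 4-6 week control intervals,
#' 210-240 day lactations. Milk and component curves follow the
#' Ali-Schaeffer form; somatic cell count follows the parabolic
#' yield-density form with multiplicative lognormal noise (SCC is strictly
#' positive and right-skewed). Residual noise levels are package defaults
#' chosen to be realistic for goat test-day data, not study estimates.
#'
#' @param n_goats,n_farms herd dimensions.
#' @param haplotype_freqs named numeric vector of haplotype frequencies
#'   (must sum to 1).
#' @param effect_sizes named list: haplotype label -> named numeric vector
#'   of additive shifts on the curve level (`b0`) per trait. Omitted
#'   haplotypes/traits have zero effect.
#' @param base_curve_params named list of per-trait parameter vectors:
#'   5-vectors (Ali-Schaeffer) for milk/components, 3-vector (parabolic
#'   yield-density) for `scc`.
#' @param noise_sd named per-trait residual SD (trait units; log scale for
#'   `scc`).
#' @param mean_lactations_per_goat mean lactation count (lactations per goat
#'   are drawn as 1 + Poisson(mean - 1)).
#' @param controls_per_lactation controls per lactation.
#' @param first_control_day_mean,first_control_day_sd days from kidding to
#'   first control.
#' @param control_interval_range (low, high) days between consecutive
#'   controls.
#' @param lactation_length_range (low, high) lactation length in days.
#' @param seed integer root seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_goats = 159, n_farms = 28,
                       haplotype_freqs = c(HapA = 0.4, HapB = 0.3, HapC = 0.2, HapD = 0.1),
                       effect_sizes = list(),
                       base_curve_params = default_base_curves(),
                       noise_sd = default_noise_sd(),
                       mean_lactations_per_goat = 3.91,
                       controls_per_lactation = 5,
                       first_control_day_mean = 21,
                       first_control_day_sd = 4,
                       control_interval_range = c(28, 42),
                       lactation_length_range = c(210, 240),
                       seed = 1L) {
  n_goats <- check_count(n_goats, "n_goats")
  n_farms <- check_count(n_farms, "n_farms")
  controls_per_lactation <- check_count(controls_per_lactation, "controls_per_lactation")
  check_number(mean_lactations_per_goat, "mean_lactations_per_goat", lower = 1)
  check_number(first_control_day_mean, "first_control_day_mean", lower = 1)
  if (is.null(names(haplotype_freqs)) || any(!nzchar(names(haplotype_freqs))))
    stop_caprihap("haplotype_freqs must be named", "caprihap_config_error")
  if (!length(haplotype_freqs) || any(haplotype_freqs < 0))
    stop_caprihap("haplotype frequencies must be non-negative and non-empty",
                  "caprihap_config_error")
  if (abs(sum(haplotype_freqs) - 1) > 1e-9)
    stop_caprihap("haplotype frequencies must sum to 1", "caprihap_config_error")
  if (control_interval_range[1] > control_interval_range[2] ||
      lactation_length_range[1] > lactation_length_range[2])
    stop_caprihap("interval range low must be <= high", "caprihap_config_error")
  if (any(unlist(noise_sd) < 0))
    stop_caprihap("noise_sd must be >= 0", "caprihap_config_error")
  for (tr in SIM_TRAITS) {
    want <- if (tr == "scc") 3L else 5L
    if (length(base_curve_params[[tr]]) != want)
      stop_caprihap(sprintf("base_curve_params$%s must have length %d", tr, want),
                    "caprihap_config_error")
  }
  structure(list(n_goats = n_goats, n_farms = n_farms,
                 haplotype_freqs = haplotype_freqs, effect_sizes = effect_sizes,
                 base_curve_params = base_curve_params, noise_sd = noise_sd,
                 mean_lactations_per_goat = mean_lactations_per_goat,
                 controls_per_lactation = controls_per_lactation,
                 first_control_day_mean = first_control_day_mean,
                 first_control_day_sd = first_control_day_sd,
                 control_interval_range = control_interval_range,
                 lactation_length_range = lactation_length_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default per-trait base curves
#'
#' Ali-Schaeffer parameter vectors giving typical Murciano-Granadina goat
#' test-day levels (milk around 2-3 kg/day peaking early; fat ~5%, protein
#' ~3.5%, dry matter ~14.5%, lactose ~4.9%) and a parabolic yield-density
#' curve for SCC in the several-hundred-thousand cells/mL range.
#'
#' @return named list of parameter vectors.
#' @export
default_base_curves <- function() {
  list(milk_kg = c(3.2, -2.0, 0.3, 0.4, -0.25),
       fat_pct = c(5.0, 1.2, -0.3, -0.15, 0.12),
       protein_pct = c(3.3, 0.9, -0.2, -0.10, 0.08),
       dry_matter_pct = c(14.0, 1.5, -0.4, -0.20, 0.15),
       lactose_pct = c(4.9, -0.3, 0.05, 0.05, -0.03),
       ## 1/scc quadratic: SCC rises from ~700e3 toward ~2e6 cells/mL late
       scc = c(1.6e-3, -6e-6, 1.2e-8))
}

#' Default per-trait residual SDs
#'
#' Additive Gaussian SD in trait units for milk and components; SD of the
#' log for SCC. These are package defaults (the study does not report
#' residual variances).
#'
#' @return named numeric vector.
#' @export
default_noise_sd <- function() {
  c(milk_kg = 0.35, fat_pct = 0.45, protein_pct = 0.2, dry_matter_pct = 0.6,
    lactose_pct = 0.15, scc = 0.6)
}

#' Draw diplotypes under Hardy-Weinberg proportions
#'
#' Pairs of haplotype labels drawn i.i.d. with replacement from the
#' frequency vector; reproducible under `seed`.
#'
#' @param freqs named frequency vector summing to 1.
#' @param n number of animals.
#' @param seed integer seed.
#' @return n x 2 character matrix of haplotype labels.
#' @export
assign_diplotypes <- function(freqs, n, seed = 1L) {
  if (!length(freqs)) stop_caprihap("empty frequency list", "caprihap_config_error")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop_caprihap("frequencies must sum to 1", "caprihap_config_error")
  n <- check_count(n, "n")
  labels <- names(freqs)
  set.seed(seed)
  m <- matrix(sample(labels, 2 * n, replace = TRUE, prob = freqs), ncol = 2)
  colnames(m) <- c("hap1", "hap2")
  m
}

#' Simulate a synthetic herd
#'
#' Draws a diplotype per goat, builds per-animal trait curves (base curve
#' plus the sum of the two carried haplotypes' additive `b0` effects),
#' generates the control schedule (first control, then uniform intervals,
#' truncated at the lactation length) and adds residual noise: Gaussian per
#' control for milk/components, multiplicative lognormal for SCC. Identical
#' seed, identical dataset.
#'
#' @param config a [sim_config()].
#' @return list of class `"synthetic_dataset"`: `records` (validated
#'   test-day data.frame), `assignments` (a `"haplotype_assignments"`
#'   data.frame), `diplotypes` (per-goat labels), and `truth` (the config,
#'   per-animal realized curve parameters, and the haplotype label-to-token
#'   map).
#' @export
simulate_herd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  labels <- names(config$haplotype_freqs)
  dip <- assign_diplotypes(config$haplotype_freqs, config$n_goats,
                           seed = derive_seed(config$seed, "diplotypes"))
  set.seed(derive_seed(config$seed, "structure"))
  ids <- sprintf("G%04d", seq_len(config$n_goats))
  farms <- sprintf("F%02d", sample.int(config$n_farms, config$n_goats, replace = TRUE))
  n_lact <- 1L + stats::rpois(config$n_goats, config$mean_lactations_per_goat - 1)

  ## per-animal curve parameters: base + additive haplotype effects on b0
  eff <- function(goat, trait) {
    s <- 0
    for (h in dip[goat, ]) {
      e <- config$effect_sizes[[h]]
      if (!is.null(e) && !is.na(e[trait])) s <- s + unname(e[trait])
    }
    s
  }
  truth_params <- vector("list", config$n_goats)
  for (g in seq_len(config$n_goats)) {
    pars <- config$base_curve_params
    for (tr in SIM_TRAITS) {
      shift <- eff(g, tr)
      if (tr == "scc") {
        ## effect shifts the curve level: scale the denominator so that
        ## 1/den moves by `shift` at day 1 (level effects on SCC are rare;
        ## zero by default)
        if (shift != 0) {
          base1 <- parabolic_yield_density(1, pars$scc)
          pars$scc <- pars$scc * base1 / (base1 + shift)
        }
      } else pars[[tr]][1] <- pars[[tr]][1] + shift
    }
    truth_params[[g]] <- pars
  }

  ## control schedules
  rows <- vector("list", sum(n_lact))
  ri <- 0L
  origin <- as.Date("2010-01-15")
  for (g in seq_len(config$n_goats)) {
    kidding <- origin + round(stats::runif(1, 0, 365))
    for (l in seq_len(n_lact[g])) {
      len <- round(stats::runif(1, config$lactation_length_range[1],
                                config$lactation_length_range[2]))
      d1 <- max(1, round(stats::rnorm(1, config$first_control_day_mean,
                                      config$first_control_day_sd)))
      gaps <- round(stats::runif(config$controls_per_lactation - 1,
                                 config$control_interval_range[1],
                                 config$control_interval_range[2]))
      days <- cumsum(c(d1, gaps))
      days <- days[days <= len]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(animal_id = ids[g], farm_id = farms[g],
                               lactation_no = l, kidding_date = kidding,
                               dim = days, stringsAsFactors = FALSE)
      kidding <- kidding + len + round(stats::runif(1, 30, 90))  # dry period
    }
  }
  sched <- do.call(rbind, rows)
  sched$control_date <- sched$kidding_date + sched$dim

  ## trait values
  set.seed(derive_seed(config$seed, "noise"))
  gidx <- match(sched$animal_id, ids)
  for (tr in SIM_TRAITS) {
    mu <- vapply(seq_len(nrow(sched)), function(i) {
      pars <- truth_params[[gidx[i]]][[tr]]
      if (tr == "scc") parabolic_yield_density(sched$dim[i], pars)
      else ali_schaeffer(sched$dim[i], pars)
    }, numeric(1))
    if (tr == "scc") {
      val <- mu * stats::rlnorm(nrow(sched), 0, config$noise_sd[["scc"]])
    } else {
      val <- mu + stats::rnorm(nrow(sched), 0, config$noise_sd[[tr]])
      val <- pmax(val, 0)
    }
    sched[[tr]] <- val
  }
  records <- sched[c("animal_id", "farm_id", "lactation_no", "kidding_date",
                     "control_date", SIM_TRAITS)]
  records <- validate_records(records)

  ## haplotype token sequences per label, then per-animal assignments
  tokens <- haplotype_token_map(labels, derive_seed(config$seed, "haplotype_tokens"))
  blocks <- attr(tokens, "blocks")
  adf <- data.frame(animal_id = rep(ids, each = 2), phase = rep(1:2, config$n_goats),
                    stringsAsFactors = FALSE)
  hap_of_row <- as.vector(t(dip))
  for (bl in names(blocks))
    adf[[bl]] <- vapply(hap_of_row, function(h) paste(tokens[[h]][[bl]], collapse = " "), "")
  assignments <- build_assignments(adf, blocks)

  structure(list(records = records, assignments = assignments,
                 diplotypes = data.frame(animal_id = ids, hap1 = dip[, 1],
                                         hap2 = dip[, 2], farm_id = farms,
                                         stringsAsFactors = FALSE),
                 truth = list(config = config, curve_params = stats::setNames(truth_params, ids),
                              token_map = tokens)),
            class = "synthetic_dataset")
}

## Distinct token sequences for each haplotype label over the default
## casein blocks; includes the deletion token ".-" and one multi-base
## insertion token to exercise indel handling.
haplotype_token_map <- function(labels, seed) {
  set.seed(seed)
  blocks <- default_blocks()
  base <- lapply(blocks, function(b) sample(c("A", "C", "G", "T"), b$n_positions,
                                            replace = TRUE))
  base$CSN1S2[3] <- ".-"    # shared deletion position
  base$CSN3[5] <- "AATC"    # shared insertion position
  out <- list()
  seen <- character()
  for (i in seq_along(labels)) {
    toks <- base
    ## mutate a label-specific position until the sequence is distinct
    bl <- names(blocks)[1 + (i - 1) %% length(blocks)]
    pos <- 1 + ((i - 1) %/% length(blocks)) %% blocks[[bl]]$n_positions
    alt <- setdiff(c("A", "C", "G", "T"), toks[[bl]][pos])
    toks[[bl]][pos] <- alt[1 + i %% 3]
    if (i %% 2 == 0) toks$CSN1S2[3] <- "T"  # flip the indel state
    key <- paste(unlist(toks), collapse = "|")
    while (key %in% seen) {
      pos <- 1 + pos %% blocks[[bl]]$n_positions
      toks[[bl]][pos] <- sample(setdiff(c("A", "C", "G", "T"), toks[[bl]][pos]), 1)
      key <- paste(unlist(toks), collapse = "|")
    }
    seen <- c(seen, key)
    out[[labels[i]]] <- toks
  }
  attr(out, "blocks") <- blocks
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d records, %d goats, %d haplotype labels>\n",
              nrow(x$records), length(unique(x$records$animal_id)),
              length(x$truth$config$haplotype_freqs)))
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' @param dataset a `"synthetic_dataset"`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- file.path(dir, "records.csv")
  hap <- file.path(dir, "haplotypes.csv")
  write_records(dataset$records, rec)
  write_haplotypes(dataset$assignments, hap)
  c(records = rec, haplotypes = hap)
}
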