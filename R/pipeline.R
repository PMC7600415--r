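## End-to-end orchestration: read or simulate a herd, standardize yields,
## fit lactation curves, extract shapes, group by haplotype and run the
## Bayesian/frequentist one-way analyses; emit report tables and a run
## manifest.

#' Pipeline configuration
#'
#' Either a pair of input paths (`records`, `haplotypes`) or a `simulate`
#' block (a [sim_config()]) must be supplied, never neither.
#'
#' @param records,haplotypes input CSV paths.
#' @param simulate a [sim_config()] for synthetic input.
#' @param traits traits to analyse.
#' @param models `"reproduction"` (pin Ali-Schaeffer for milk/components and
#'   parabolic yield-density for SCC, the published selection outcome) or
#'   `"select"` (run the model-selection stage over the registry).
#' @param rscale JZS prior scale for the Bayes factors.
#' @param ci_level credible level for group posteriors.
#' @param homozygous_only restrict haplotype groups to homozygous carriers.
#' @param min_group_n groups with fewer observations are dropped from each
#'   analysis.
#' @param out_dir output directory (`NULL` to skip writing).
#' @param seed root seed for any simulation.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(records = NULL, haplotypes = NULL, simulate = NULL,
                            traits = SIM_TRAITS, models = c("reproduction", "select"),
                            rscale = 1, ci_level = 0.95, homozygous_only = FALSE,
                            min_group_n = 2, out_dir = NULL, seed = 1L) {
  models <- match.arg(models)
  have_paths <- !is.null(records) && !is.null(haplotypes)
  if (!have_paths && is.null(simulate))
    stop_caprihap("supply input paths (records + haplotypes) or a simulate block",
                  "caprihap_config_error")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(records = records, haplotypes = haplotypes, simulate = simulate,
                 traits = traits, models = models, rscale = rscale,
                 ci_level = ci_level, homozygous_only = homozygous_only,
                 min_group_n = min_group_n, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load or simulate the herd; assemble lactations and standardized
#' 210-day yields; fit the per-trait lactation-curve models (pinned
#' reproduction set or registry selection); extract peak/persistency curve
#' shapes per lactation; group animals by casein haplotype; run the one-way
#' analyses (trait level per test-day record, curve-shape parameters per
#' lactation) with F, p, JZS Bayes factor and credible-interval group
#' effects. When `out_dir` is set, writes `criteria.csv`, `shapes.csv`,
#' `anova.csv`, `group_posteriors.csv` and `manifest.json`; identical
#' config and seed give byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return list of class `"pipeline_run"` with `lactations` (summary
#'   table), `criteria`, `selection`, `shapes`, `grouping`, `anova`
#'   (table), `posteriors`, `analyses` and `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop_caprihap(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                    "caprihap_stage_error"))
    say("stage %-12s %6.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  dat <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- derive_seed(config$seed, "pipeline")
      ds <- simulate_herd(sim)
      list(records = ds$records, assignments = ds$assignments,
           diplotypes = ds$diplotypes)
    } else {
      recs <- read_records(config$records)
      asg <- parse_haplotypes(config$haplotypes)
      list(records = recs, assignments = asg, diplotypes = NULL)
    }
  })

  lact <- stage("lactations", build_lactations(dat$records, traits = "milk_kg"))

  model_for_trait <- function(trait)
    if (trait == "scc") "parabolic_yield_density" else "ali_schaeffer"

  fits <- stage("fit", {
    out <- list()
    for (trait in config$traits) {
      if (config$models == "select" && trait != "scc") {
        cand <- names(Filter(function(m) m$k <= 5, lactation_models()))
      } else cand <- model_for_trait(trait)
      for (mid in cand) {
        k <- lactation_models()[[mid]]$k
        for (s in lact) {
          tt <- s$records$dim; yy <- s$records[[trait]]
          if (length(tt) < k) next
          fit <- tryCatch(fit_lactation(tt, yy, mid), error = function(e) NULL)
          if (is.null(fit)) next
          out[[length(out) + 1L]] <- list(animal_id = s$animal_id,
                                          lactation_no = s$lactation_no,
                                          trait = trait, fit = fit)
        }
      }
    }
    out
  })

  crit <- stage("criteria", {
    rows <- lapply(fits, function(f) {
      cr <- tryCatch(suppressWarnings(fit_criteria(f$fit)), error = function(e) NULL)
      if (is.null(cr)) return(NULL)
      cbind(data.frame(animal_id = f$animal_id, lactation_no = f$lactation_no,
                       trait = f$trait, stringsAsFactors = FALSE), cr)
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) out <- data.frame()
    rownames(out) <- NULL
    out
  })

  selection <- stage("select", {
    if (config$models != "select") NULL else {
      sel <- list()
      for (trait in setdiff(config$traits, "scc")) {
        if (!nrow(crit)) break
        cc <- crit[crit$trait == trait, , drop = FALSE]
        if (!nrow(cc)) next
        sel[[trait]] <- tryCatch(select_best(cc), error = function(e) NULL)
      }
      sel
    }
  })

  shapes <- stage("shapes", {
    rows <- lapply(fits, function(f) {
      if (!f$fit$model_id %in% c("ali_schaeffer", "parabolic_yield_density")) return(NULL)
      sh <- tryCatch(curve_shape(f$fit), error = function(e) NULL)
      if (is.null(sh)) return(NULL)
      data.frame(animal_id = f$animal_id, lactation_no = f$lactation_no,
                 trait = f$trait, model_id = sh$model_id, peak = sh$peak,
                 persistency_b1 = if (is.null(sh$persistency_b1)) NA_real_ else sh$persistency_b1,
                 persistency_b2 = if (is.null(sh$persistency_b2)) NA_real_ else sh$persistency_b2,
                 persistency = if (is.null(sh$persistency)) NA_real_ else sh$persistency,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(out)) out <- data.frame()
    rownames(out) <- NULL
    out
  })

  grouping <- stage("grouping", group_by_haplotype(dat$assignments,
                                                   homozygous_only = config$homozygous_only))

  analyses <- stage("anova", {
    memb <- group_membership(grouping)
    res <- list()
    for (trait in config$traits) {
      ## trait level: one observation per test-day record (per carried group)
      lev <- join_groups(dat$records$animal_id, dat$records[[trait]], memb)
      res[[paste(trait, "level")]] <- try_anova(lev$values, lev$group, trait,
                                                "level", config)
      ## curve shapes: one observation per lactation
      sh <- if (nrow(shapes)) shapes[shapes$trait == trait, , drop = FALSE] else shapes
      if (!is.null(sh) && nrow(sh)) {
        for (par in c("peak", "persistency_b1", "persistency_b2", "persistency")) {
          v <- sh[[par]]
          if (all(is.na(v))) next
          sj <- join_groups(sh$animal_id, v, memb)
          res[[paste(trait, par)]] <- try_anova(sj$values, sj$group, trait, par, config)
        }
      }
    }
    Filter(Negate(is.null), res)
  })

  run <- structure(list(lactations = lactation_table(lact),
                        criteria = crit, selection = selection, shapes = shapes,
                        grouping = grouping, analyses = analyses,
                        anova = anova_table(analyses),
                        posteriors = posterior_table(analyses),
                        config = config),
                   class = "pipeline_run")
  audit_anova_table(run$anova)
  if (!is.null(config$out_dir)) stage("write", write_pipeline_outputs(run))
  run
}

## map animal id -> carried haplotype group labels
group_membership <- function(grouping) {
  g <- grouping$groups
  data.frame(animal_id = unlist(g, use.names = FALSE),
             group = rep(names(g), lengths(g)), stringsAsFactors = FALSE)
}

join_groups <- function(animal_id, values, memb) {
  idx <- split(seq_along(animal_id), animal_id)
  rows_id <- memb$animal_id[memb$animal_id %in% names(idx)]
  rows_gr <- memb$group[memb$animal_id %in% names(idx)]
  take <- unlist(idx[rows_id], use.names = FALSE)
  reps <- lengths(idx[rows_id])
  list(values = values[take], group = rep(rows_gr, reps))
}

try_anova <- function(values, group, trait, parameter, config) {
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  keep <- names(which(table(group) >= config$min_group_n))
  if (length(keep) < 2) return(NULL)
  sel <- group %in% keep
  tryCatch(suppressWarnings(
    haplotype_anova(values[sel], group[sel], trait = trait,
                    parameter = parameter, rscale = config$rscale,
                    level = config$ci_level)),
    error = function(e) NULL)
}

posterior_table <- function(analyses) {
  rows <- lapply(analyses, function(x) {
    if (is.null(x$posteriors)) return(NULL)
    cbind(data.frame(trait = x$trait, parameter = x$parameter,
                     stringsAsFactors = FALSE), x$posteriors)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

## self-consistency audit: every output row must satisfy ms = ss/df and
## f = ms ratio
audit_anova_table <- function(tab) {
  if (is.null(tab) || !nrow(tab)) return(invisible(TRUE))
  stopifnot(all(abs(tab$mean_sq - tab$sum_sq / tab$df) <=
                  1e-9 * pmax(tab$mean_sq, 1)))
  bt <- tab[tab$source == "Between", ]
  wt <- tab[tab$source == "Within", ]
  ok <- is.finite(bt$f)
  stopifnot(all(abs(bt$f[ok] - bt$mean_sq[ok] / wt$mean_sq[ok]) <=
                  1e-9 * pmax(abs(bt$f[ok]), 1)))
  invisible(TRUE)
}

write_pipeline_outputs <- function(run) {
  dir.create(run$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(run$config$out_dir, f)
  utils::write.csv(run$lactations, p("lactations.csv"), row.names = FALSE)
  utils::write.csv(run$criteria, p("criteria.csv"), row.names = FALSE)
  if (!is.null(run$shapes)) utils::write.csv(run$shapes, p("shapes.csv"), row.names = FALSE)
  utils::write.csv(run$anova, p("anova.csv"), row.names = FALSE)
  if (!is.null(run$posteriors))
    utils::write.csv(run$posteriors, p("group_posteriors.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("caprihap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = run$config$seed, models = run$config$models,
    traits = run$config$traits, rscale = run$config$rscale,
    ci_level = run$config$ci_level,
    homozygous_only = run$config$homozygous_only,
    simulated = !is.null(run$config$simulate),
    n_lactations = nrow(run$lactations),
    n_analyses = length(run$analyses))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(run$config$out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d lactations, %d fits, %d analyses>\n",
              nrow(x$lactations), nrow(x$criteria), length(x$analyses)))
  invisible(x)
}
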