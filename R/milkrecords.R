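## Test-day record I/O, validation, lactation assembly and 210-day
## standardized yield (Fleischmann-style interval weighting).

RECORD_COLUMNS <- c("animal_id", "farm_id", "lactation_no", "kidding_date",
                    "control_date", "milk_kg", "fat_pct", "protein_pct",
                    "dry_matter_pct", "lactose_pct", "scc")

#' Read and validate test-day milk records
#'
#' Reads the standard record CSV (one row per milk control, ISO-8601 dates).
#' Rows violating the record invariants (negative yields, percentages outside
#' \[0, 100\], control date before kidding date, non-positive days in milk)
#' are rejected; by default rejection aborts with row-level diagnostics.
#'
#' @param path CSV file with header columns `animal_id, farm_id,
#'   lactation_no, kidding_date, control_date, milk_kg, fat_pct, protein_pct,
#'   dry_matter_pct, lactose_pct, scc` (SCC in 1000 cells/mL).
#' @param on_invalid `"error"` (default) or `"drop"`: drop invalid rows with
#'   a warning listing each rejected row and its reason.
#' @return `data.frame` of validated records with `Date` columns and a `dim`
#'   column (days in milk of the control).
#' @export
read_records <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing))
    stop_caprihap(paste0("record file missing required column(s): ",
                         paste(missing, collapse = ", ")), "caprihap_format_error")
  df <- df[RECORD_COLUMNS]
  df$kidding_date <- as.Date(df$kidding_date)
  df$control_date <- as.Date(df$control_date)
  validate_records(df, on_invalid = on_invalid)
}

#' Validate a test-day record data frame
#'
#' @param df data.frame with the columns of [read_records()].
#' @param on_invalid `"error"` or `"drop"`.
#' @return validated data.frame with a `dim` column appended.
#' @export
validate_records <- function(df, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  dim_days <- as.integer(df$control_date - df$kidding_date)
  pct_cols <- c("fat_pct", "protein_pct", "dry_matter_pct", "lactose_pct")
  reasons <- character(nrow(df))
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  flag(is.na(df$kidding_date) | is.na(df$control_date), "unparseable date")
  flag(!is.na(dim_days) & dim_days < 1, "control date not after kidding date")
  flag(!is.finite(df$milk_kg) | df$milk_kg < 0, "negative or missing milk yield")
  for (pc in pct_cols)
    flag(!is.finite(df[[pc]]) | df[[pc]] < 0 | df[[pc]] > 100,
         paste(pc, "outside [0, 100]"))
  flag(!is.finite(df$scc) | df$scc < 0, "negative or missing SCC")

  bad <- which(nzchar(reasons))
  if (length(bad)) {
    diag <- paste0("row ", bad, ": ", reasons[bad], collapse = "; ")
    if (on_invalid == "error")
      stop_caprihap(paste0("invalid test-day record(s): ", diag),
                    "caprihap_validation_error")
    warning("dropped ", length(bad), " invalid record(s): ", diag)
    df <- df[-bad, , drop = FALSE]
    dim_days <- dim_days[-bad]
  }
  df$dim <- dim_days
  rownames(df) <- NULL
  df
}

#' Write test-day records to CSV
#' @param records validated record data.frame.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  out <- records[RECORD_COLUMNS]
  out$kidding_date <- format(out$kidding_date, "%Y-%m-%d")
  out$control_date <- format(out$control_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble per-lactation series from test-day records
#'
#' Groups records by (animal, lactation number), sorts each group by control
#' date, and computes the kidding-to-first-control interval `d1`, the
#' penultimate-to-last-control interval `d2`, and the 210-day standardized
#' yield of each trait.
#'
#' @param records validated record data.frame (see [read_records()]).
#' @param traits trait columns to standardize to 210 days.
#' @return list of `"lactation_series"` objects; each holds `animal_id`,
#'   `farm_id`, `lactation_no`, `kidding_date`, the sorted `records`, `d1`,
#'   `d2`, and `total_yield_210` (named by trait).
#' @export
build_lactations <- function(records, traits = "milk_kg") {
  if (!nrow(records)) return(list())
  if (is.null(records$dim))
    records$dim <- as.integer(records$control_date - records$kidding_date)
  key <- interaction(records$animal_id, records$lactation_no, drop = TRUE)
  dup <- duplicated(records[c("animal_id", "lactation_no", "control_date")])
  if (any(dup)) {
    d <- records[dup, c("animal_id", "lactation_no", "control_date")]
    stop_caprihap(paste0("duplicate control(s): ",
                         paste(sprintf("%s/lact%s/%s", d$animal_id, d$lactation_no,
                                       d$control_date), collapse = ", ")),
                  "caprihap_validation_error")
  }
  out <- lapply(split(records, key), function(g) {
    g <- g[order(g$control_date), , drop = FALSE]
    ty <- vapply(traits, function(tr) standardize_210(g$dim, g[[tr]]), numeric(1))
    structure(list(animal_id = g$animal_id[1], farm_id = g$farm_id[1],
                   lactation_no = g$lactation_no[1],
                   kidding_date = g$kidding_date[1], records = g,
                   d1 = g$dim[1],
                   d2 = if (nrow(g) >= 2) g$dim[nrow(g)] - g$dim[nrow(g) - 1] else NA_integer_,
                   total_yield_210 = ty),
              class = "lactation_series")
  })
  names(out) <- NULL
  out[order(vapply(out, function(s) paste(s$animal_id, s$lactation_no), ""))]
}

#' @export
print.lactation_series <- function(x, ...) {
  cat(sprintf("<lactation_series %s lact %s: %d controls, d1 = %d, 210-d milk = %.1f kg>\n",
              x$animal_id, x$lactation_no, nrow(x$records), x$d1,
              x$total_yield_210[["milk_kg"]]))
  invisible(x)
}

#' Standardize a lactation yield to 210 days in milk
#'
#' Fleischmann-style interval weighting: with controls at days in milk
#' \eqn{t_1 < \dots < t_m} (controls past day 210 are discarded) and daily
#' yields \eqn{M_i},
#' \deqn{Y_{210} = M_1 t_1 + \sum_{i<m} \frac{M_i + M_{i+1}}{2}(t_{i+1}-t_i)
#'       + M_m (210 - t_m).}
#' The first control's yield is carried back to kidding, consecutive controls
#' are trapezoid-weighted, and the last within-horizon control is carried
#' forward to day 210. The rule is linear in the yields and unaffected by
#' records beyond day 210.
#'
#' @param dim days in milk of each control (positive, strictly increasing) or
#'   a `"lactation_series"`.
#' @param yields daily yields at the controls (same units as the result per
#'   day; kg/day for milk).
#' @param horizon standardization horizon in days.
#' @return total standardized yield over `horizon` days.
#' @export
#' @examples
#' standardize_210(c(21, 51, 81, 111, 141, 171, 201), rep(3, 7))  # 630
standardize_210 <- function(dim, yields, horizon = 210) {
  if (inherits(dim, "lactation_series")) {
    s <- dim
    return(standardize_210(s$records$dim, s$records$milk_kg, horizon))
  }
  stopifnot(length(dim) == length(yields), length(dim) >= 1)
  if (any(dim < 1)) stop_caprihap("days in milk must be >= 1", "caprihap_validation_error")
  if (any(diff(dim) <= 0)) stop_caprihap("control days must be strictly increasing",
                                         "caprihap_validation_error")
  keep <- dim <= horizon
  if (!any(keep)) {
    ## every control past the horizon: carry the first control back over the
    ## whole horizon (degenerate, flagged to the caller via warning)
    warning("all controls beyond day ", horizon, "; using first control only")
    return(yields[1] * horizon)
  }
  t <- dim[keep]; m <- yields[keep]
  n <- length(t)
  total <- m[1] * t[1]
  if (n > 1) total <- total + sum((m[-n] + m[-1]) / 2 * diff(t))
  total + m[n] * (horizon - t[n])
}

#' Lactation summary table
#'
#' One row per lactation with `d1`, `d2`, control count and the standardized
#' 210-day yields.
#'
#' @param lactations list from [build_lactations()].
#' @return data.frame keyed by (`animal_id`, `lactation_no`).
#' @export
lactation_table <- function(lactations) {
  if (!length(lactations)) return(data.frame())
  rows <- lapply(lactations, function(s) {
    base <- data.frame(animal_id = s$animal_id, farm_id = s$farm_id,
                       lactation_no = s$lactation_no,
                       kidding_date = s$kidding_date, n_controls = nrow(s$records),
                       d1 = s$d1, d2 = s$d2, stringsAsFactors = FALSE)
    for (tr in names(s$total_yield_210))
      base[[paste0("yield210_", tr)]] <- s$total_yield_210[[tr]]
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
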