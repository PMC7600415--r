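#' @keywords internal
"_PACKAGE"

## internal helpers shared across modules

stop_caprihap <- function(msg, class) {
  stop(structure(class = c(class, "caprihap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_caprihap(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper),
                  "caprihap_config_error")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop_caprihap(sprintf("'%s' must be an integer >= %d", name, min),
                  "caprihap_config_error")
  invisible(as.integer(x))
}

## deterministic child seed below 2^31 - 1 (double arithmetic: exact to 2^53)
derive_seed <- function(seed, stage) {
  idx <- match(stage, c("diplotypes", "structure", "noise",
                        "haplotype_tokens", "pipeline"))
  as.integer((as.numeric(seed) * 48271 + idx * 9973) %% 2147483629)
}
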