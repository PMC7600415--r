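## shared fixture builders (all fixtures are generated in code)

## a small validated record data.frame: one animal, one lactation,
## controls at the given days with the given milk yields
make_records <- function(dim_days, milk,
                         animal_id = "G0001", farm_id = "F01",
                         lactation_no = 1, kidding = as.Date("2015-03-01")) {
  n <- length(dim_days)
  data.frame(animal_id = animal_id, farm_id = farm_id,
             lactation_no = lactation_no, kidding_date = kidding,
             control_date = kidding + dim_days,
             milk_kg = milk, fat_pct = 5.2, protein_pct = 3.5,
             dry_matter_pct = 14.5, lactose_pct = 4.9, scc = 500,
             stringsAsFactors = FALSE)
}

## write a token-delimited haplotype CSV for animals given their two
## full-complex sequences (list: animal_id -> list(hap1 = list(block ->
## tokens), hap2 = ...)); blocks default to tiny 2/2/2/2 layout
tiny_blocks <- function() {
  list(CSN1S1 = locus_block("CSN1S1", 2), CSN1S2 = locus_block("CSN1S2", 2),
       CSN2 = locus_block("CSN2", 2), CSN3 = locus_block("CSN3", 2))
}

write_tiny_haplotypes <- function(path, animals) {
  rows <- list()
  for (id in names(animals)) {
    for (ph in 1:2) {
      h <- animals[[id]][[ph]]
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, phase = ph,
        CSN1S1 = paste(h$CSN1S1, collapse = " "),
        CSN1S2 = paste(h$CSN1S2, collapse = " "),
        CSN2 = paste(h$CSN2, collapse = " "),
        CSN3 = paste(h$CSN3, collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  path
}

## independent day-by-day oracle for the 210-day standardization: build
## the piecewise-linear daily-yield curve (flat before the first and after
## the last control) and accumulate one day at a time with the midpoint
## rule, which integrates a piecewise-linear curve exactly when kinks sit
## on integer days
oracle_fleischmann <- function(dim_days, milk, horizon = 210) {
  keep <- dim_days <= horizon
  t <- dim_days[keep]; m <- milk[keep]
  interp <- function(x) {
    if (x <= t[1]) return(m[1])
    if (x >= t[length(t)]) return(m[length(m)])
    i <- max(which(t <= x))
    m[i] + (m[i + 1] - m[i]) * (x - t[i]) / (t[i + 1] - t[i])
  }
  total <- 0
  for (d in seq_len(horizon)) total <- total + interp(d - 0.5)
  total
}
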