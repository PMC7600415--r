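## Casein-complex haplotype data model, allele-frequency and linkage
## disequilibrium summaries, and grouping of animals by haplotype variant.
##
## The four casein loci on goat chromosome 6: CSN1S1 (alpha-s1), CSN2
## (beta), CSN1S2 (alpha-s2), CSN3 (kappa). Alleles are tokens: single bases
## "A"/"C"/"G"/"T", the deletion token ".-", or multi-base insertion tokens
## such as "AATC". Tokens are always delimiter-separated on input;
## concatenated display strings are ambiguous and not accepted.

CASEIN_LOCI <- c("CSN1S1", "CSN1S2", "CSN2", "CSN3")

#' Define a casein locus block
#'
#' @param name one of `CSN1S1`, `CSN1S2`, `CSN2`, `CSN3`.
#' @param n_positions number of SNP positions in the block.
#' @param snp_ids optional SNP identifiers (defaults to `name_1..name_n`).
#' @return list of class `"locus_block"`.
#' @export
locus_block <- function(name, n_positions, snp_ids = NULL) {
  stopifnot(name %in% CASEIN_LOCI)
  n_positions <- check_count(n_positions, "n_positions")
  if (is.null(snp_ids)) snp_ids <- paste0(name, "_", seq_len(n_positions))
  stopifnot(length(snp_ids) == n_positions, !anyDuplicated(snp_ids))
  structure(list(name = name, snp_ids = snp_ids, n_positions = n_positions),
            class = "locus_block")
}

#' Default casein-complex block layout (48 SNPs over four loci)
#'
#' The study's complex carries 48 SNPs; the default layout assigns 18 to
#' CSN1S1, 10 to CSN1S2, 9 to CSN2 and 11 to CSN3 (the alpha-s1 block is the
#' longest, matching its 18-token haplotype sequences).
#'
#' @return named list of [locus_block()]s.
#' @export
default_blocks <- function() {
  list(CSN1S1 = locus_block("CSN1S1", 18), CSN1S2 = locus_block("CSN1S2", 10),
       CSN2 = locus_block("CSN2", 9), CSN3 = locus_block("CSN3", 11))
}

#' Parse phased haplotype assignments
#'
#' Reads the haplotype CSV: columns `animal_id`, `phase` (1 or 2), and one
#' column per locus block containing space-delimited allele tokens (e.g.
#' `"T T C C .- AATC"`). Every animal must carry exactly two phases and each
#' block's token count must match the block definition.
#'
#' @param path CSV path.
#' @param blocks named list of [locus_block()]s; defaults to
#'   [default_blocks()].
#' @return data.frame of class `"haplotype_assignments"`: one row per
#'   (animal, phase), token sequences kept as list columns, plus a
#'   `haplotype` column with the full-complex token sequence collapsed by
#'   `"|"` (block boundaries marked `"/"`).
#' @export
parse_haplotypes <- function(path, blocks = default_blocks()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("animal_id", "phase", names(blocks))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_caprihap(paste0("haplotype file missing column(s): ",
                         paste(missing, collapse = ", ")), "caprihap_format_error")
  build_assignments(df, blocks)
}

build_assignments <- function(df, blocks = default_blocks()) {
  for (bl in names(blocks)) {
    toks <- strsplit(trimws(df[[bl]]), "[ \t]+")
    nt <- lengths(toks)
    bad <- which(nt != blocks[[bl]]$n_positions)
    if (length(bad))
      stop_caprihap(sprintf(
        "token count mismatch in block %s for animal(s) %s: got %s, expected %d",
        bl, paste(unique(df$animal_id[bad]), collapse = ", "),
        paste(unique(nt[bad]), collapse = "/"), blocks[[bl]]$n_positions),
        "caprihap_validation_error")
    df[[bl]] <- toks
  }
  tab <- table(df$animal_id)
  if (any(tab != 2))
    stop_caprihap(paste0("animals without exactly two phases: ",
                         paste(names(tab)[tab != 2], collapse = ", ")),
                  "caprihap_validation_error")
  df$haplotype <- vapply(seq_len(nrow(df)), function(i)
    paste(vapply(names(blocks), function(bl) paste(df[[bl]][[i]], collapse = "|"), ""),
          collapse = "/"), "")
  attr(df, "blocks") <- blocks
  class(df) <- c("haplotype_assignments", "data.frame")
  df
}

#' Write haplotype assignments to CSV
#' @param assignments a `"haplotype_assignments"` data.frame.
#' @param path output path.
#' @export
write_haplotypes <- function(assignments, path) {
  blocks <- attr(assignments, "blocks")
  out <- data.frame(animal_id = assignments$animal_id, phase = assignments$phase,
                    stringsAsFactors = FALSE)
  for (bl in names(blocks))
    out[[bl]] <- vapply(assignments[[bl]], paste, "", collapse = " ")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Phased allele matrix across the complex
#'
#' @param assignments a `"haplotype_assignments"` data.frame.
#' @return character matrix, one row per (animal, phase), one column per SNP
#'   (column names are the block SNP ids).
#' @export
snp_matrix <- function(assignments) {
  blocks <- attr(assignments, "blocks")
  cols <- unlist(lapply(blocks, `[[`, "snp_ids"), use.names = FALSE)
  m <- do.call(cbind, lapply(names(blocks), function(bl)
    do.call(rbind, assignments[[bl]])))
  colnames(m) <- cols
  rownames(m) <- paste0(assignments$animal_id, "_p", assignments$phase)
  m
}

#' Minor allele frequency of one SNP column
#'
#' @param calls vector of allele tokens (phased calls over all chromosomes).
#' @return list with `maf` (frequency of the rarer allele, in \[0, 0.5\]),
#'   `rare` (`TRUE` when `maf` is below `threshold`) and `monomorphic`.
#' @param threshold rare-variant cut-off (default 0.05).
#' @export
maf <- function(calls, threshold = 0.05) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) stop_caprihap("no allele calls", "caprihap_data_error")
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(tab) > 2)
    stop_caprihap(paste0("more than two alleles observed: ",
                         paste(names(tab), collapse = ", ")), "caprihap_data_error")
  if (length(tab) == 1)
    return(list(maf = 0, rare = TRUE, monomorphic = TRUE))
  f <- as.numeric(tab[2]) / sum(tab)
  list(maf = f, rare = f < threshold, monomorphic = FALSE)
}

#' Observed heterozygosity at one SNP
#'
#' Fraction of animals whose two phases carry different alleles at the SNP.
#'
#' @param assignments a `"haplotype_assignments"` data.frame.
#' @param snp SNP id (a column of [snp_matrix()]).
#' @return heterozygous fraction in \[0, 1\].
#' @export
heterozygosity <- function(assignments, snp) {
  m <- snp_matrix(assignments)
  if (!snp %in% colnames(m)) stop_caprihap("unknown SNP id", "caprihap_data_error")
  a <- m[assignments$phase == 1, snp]
  b <- m[assignments$phase == 2, snp]
  ids1 <- assignments$animal_id[assignments$phase == 1]
  ids2 <- assignments$animal_id[assignments$phase == 2]
  b <- b[match(ids1, ids2)]
  mean(a != b)
}

#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' With major/minor alleles A/a at the first SNP and B/b at the second,
#' \eqn{D = p_{AB} - p_A p_B};
#' \eqn{D' = |D| / D_{max}} where \eqn{D_{max} = \min(p_A p_b, p_a p_B)} when
#' \eqn{D > 0} and \eqn{\min(p_A p_B, p_a p_b)} otherwise; and
#' \eqn{r^2 = D^2 / (p_A p_a p_B p_b)}.
#'
#' @param hap_i,hap_j phased allele calls at the two SNPs (same chromosome
#'   order).
#' @return list with `d`, `d_prime`, `r2` (the latter two in \[0, 1\]).
#' @export
ld_pair <- function(hap_i, hap_j) {
  ok <- !is.na(hap_i) & !is.na(hap_j)
  hap_i <- hap_i[ok]; hap_j <- hap_j[ok]
  ai <- sort(unique(hap_i)); aj <- sort(unique(hap_j))
  if (length(ai) != 2 || length(aj) != 2)
    stop_caprihap("LD requires two biallelic SNPs with MAF > 0", "caprihap_domain_error")
  pA <- mean(hap_i == ai[1]); pa <- 1 - pA
  pB <- mean(hap_j == aj[1]); pb <- 1 - pB
  pAB <- mean(hap_i == ai[1] & hap_j == aj[1])
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  d_prime <- if (dmax == 0) 0 else abs(D) / dmax
  list(d = D, d_prime = min(d_prime, 1), r2 = D^2 / (pA * pa * pB * pb))
}

#' Pairwise LD table across all SNPs
#'
#' @param assignments a `"haplotype_assignments"` data.frame.
#' @return long-format data.frame `snp_i, snp_j, d_prime, r2` for every SNP
#'   pair where both SNPs are polymorphic and biallelic (others skipped).
#' @export
ld_table <- function(assignments) {
  m <- snp_matrix(assignments)
  snps <- colnames(m)
  rows <- list()
  for (i in seq_along(snps)[-length(snps)]) for (j in (i + 1):length(snps)) {
    ld <- tryCatch(ld_pair(m[, i], m[, j]), error = function(e) NULL)
    if (!is.null(ld))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_i = snps[i], snp_j = snps[j], d_prime = ld$d_prime, r2 = ld$r2,
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(snp_i = character(), snp_j = character(),
                                       d_prime = numeric(), r2 = numeric()))
  do.call(rbind, rows)
}

#' Group animals by carried haplotype variant
#'
#' Enumerates the distinct full-complex haplotype sequences and maps each
#' animal to the group(s) of its carried haplotypes. By default a
#' heterozygous animal contributes to both groups; with
#' `homozygous_only = TRUE` only animals whose two phases are identical are
#' grouped (one group membership each), which keeps group memberships
#' disjoint.
#'
#' @param assignments a `"haplotype_assignments"` data.frame.
#' @param homozygous_only restrict to homozygous carriers.
#' @return list with `groups` (named list: haplotype label -> animal ids),
#'   `haplotypes` (data.frame label/sequence/count), and `summary`
#'   (`n_animals`, `n_haplotypes`, `animals_per_haplotype`).
#' @export
group_by_haplotype <- function(assignments, homozygous_only = FALSE) {
  seqs <- assignments$haplotype
  ids <- assignments$animal_id
  uniq <- sort(unique(seqs))
  labels <- paste0("H", formatC(seq_along(uniq), width = 2, flag = "0"))
  names(labels) <- uniq
  if (homozygous_only) {
    byid <- split(seqs, ids)
    hom <- names(byid)[vapply(byid, function(s) s[1] == s[2], NA)]
    keep <- ids %in% hom & !duplicated(ids)
    groups <- split(ids[keep], labels[seqs[keep]])
  } else {
    ## one membership per carried haplotype; homozygotes counted once
    key <- !duplicated(paste(ids, seqs))
    groups <- split(ids[key], labels[seqs[key]])
  }
  haps <- data.frame(label = labels[uniq], sequence = uniq,
                     count = as.integer(table(seqs)[uniq]),
                     stringsAsFactors = FALSE)
  rownames(haps) <- NULL
  n_animals <- length(unique(ids))
  list(groups = groups, haplotypes = haps,
       summary = list(n_animals = n_animals, n_haplotypes = length(uniq),
                      animals_per_haplotype = n_animals / length(uniq)))
}
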