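test_that("token-delimited haplotype parsing validates block lengths", {
  blocks <- tiny_blocks()
  path <- withr::local_tempfile(fileext = ".csv")
  animals <- list(
    G1 = list(list(CSN1S1 = c("A", "G"), CSN1S2 = c("T", ".-"),
                   CSN2 = c("C", "C"), CSN3 = c("AATC", "G")),
              list(CSN1S1 = c("A", "A"), CSN1S2 = c("T", "T"),
                   CSN2 = c("C", "G"), CSN3 = c("AATC", "G"))))
  write_tiny_haplotypes(path, animals)
  asg <- parse_haplotypes(path, blocks)
  expect_s3_class(asg, "haplotype_assignments")
  expect_equal(nrow(asg), 2L)
  ## deletion and insertion tokens survive as single alleles
  expect_equal(asg$CSN1S2[[1]], c("T", ".-"))
  expect_equal(asg$CSN3[[1]], c("AATC", "G"))

  ## wrong token count names the animal and block
  animals$G1[[1]]$CSN1S1 <- c("A")
  write_tiny_haplotypes(path, animals)
  err <- tryCatch(parse_haplotypes(path, blocks), error = identity)
  expect_s3_class(err, "caprihap_validation_error")
  expect_match(conditionMessage(err), "CSN1S1")
  expect_match(conditionMessage(err), "G1")

  ## an 18-token block parses with the default layout
  full <- simulate_herd(sim_config(n_goats = 5, n_farms = 2, seed = 3))
  expect_equal(lengths(full$assignments$CSN1S1), rep(18L, 10L))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_haplotypes(full$assignments, path2)
  back <- parse_haplotypes(path2)
  expect_equal(back$haplotype, full$assignments$haplotype)
})

test_that("minor allele frequency counts the rarer allele and flags rare variants", {
  expect_equal(maf(rep("A", 20))$maf, 0)
  expect_true(maf(rep("A", 20))$monomorphic)

  m <- maf(c(rep("A", 30), rep("G", 10)))
  expect_equal(m$maf, 0.25)
  expect_false(m$rare)

  m2 <- maf(c(rep("A", 39), "G"))
  expect_equal(m2$maf, 0.025)
  expect_true(m2$rare)
  ## boundary: exactly 0.05 is not rare (threshold is strict)
  expect_false(maf(c(rep("A", 38), rep("G", 2)))$rare)

  ## label swaps leave the frequency unchanged
  calls <- c(rep("T", 12), rep("C", 28))
  swapped <- ifelse(calls == "T", "C", "T")
  expect_equal(maf(calls)$maf, maf(swapped)$maf)

  expect_error(maf(c("A", "C", "G")), class = "caprihap_data_error")
})

test_that("heterozygosity is the fraction of animals with differing phases", {
  blocks <- tiny_blocks()
  hom <- list(CSN1S1 = c("A", "A"), CSN1S2 = c("T", "T"),
              CSN2 = c("C", "C"), CSN3 = c("G", "G"))
  het <- list(CSN1S1 = c("G", "A"), CSN1S2 = c("T", "T"),
              CSN2 = c("C", "C"), CSN3 = c("G", "G"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_haplotypes(path, list(G1 = list(hom, hom), G2 = list(het, hom),
                                   G3 = list(hom, hom), G4 = list(het, hom)))
  asg <- parse_haplotypes(path, blocks)
  expect_equal(heterozygosity(asg, "CSN1S1_1"), 0.5)
  expect_equal(heterozygosity(asg, "CSN1S1_2"), 0)

  ## Hardy-Weinberg draw at p = 0.5 gives ~50% heterozygotes
  freqs <- c(H1 = 0.5, H2 = 0.5)
  dip <- assign_diplotypes(freqs, 4000, seed = 21)
  het_frac <- mean(dip[, 1] != dip[, 2])
  expect_equal(het_frac, 0.5, tolerance = 3 * sqrt(0.25 / 4000) / 0.5)
})

test_that("pairwise LD matches the brute-force 2x2 contingency oracle", {
  ## perfectly co-inherited SNPs
  h1 <- c(rep("A", 40), rep("G", 40))
  h2 <- c(rep("T", 40), rep("C", 40))
  ld <- ld_pair(h1, h2)
  expect_equal(ld$d_prime, 1)
  expect_equal(ld$r2, 1)

  ## the 4-haplotype toy table AB:40 Ab:10 aB:10 ab:40
  hi <- c(rep("A", 50), rep("a", 50))
  hj <- c(rep("B", 40), rep("b", 10), rep("B", 10), rep("b", 40))
  ld2 <- ld_pair(hi, hj)
  pA <- 0.5; pB <- 0.5; pAB <- 0.4
  D <- pAB - pA * pB
  expect_equal(ld2$d, D, tolerance = 1e-12)
  expect_equal(ld2$d_prime, D / min(pA * (1 - pB), (1 - pA) * pB))
  expect_equal(ld2$r2, D^2 / (pA * (1 - pA) * pB * (1 - pB)))

  ## independently shuffled phases decorrelate
  set.seed(31)
  hi2 <- sample(c("A", "a"), 5000, replace = TRUE)
  hj2 <- sample(c("B", "b"), 5000, replace = TRUE)
  ld3 <- ld_pair(hi2, hj2)
  expect_lt(ld3$r2, 0.005)
  expect_lt(ld3$d_prime, 0.2)

  expect_error(ld_pair(rep("A", 10), sample(c("B", "b"), 10, replace = TRUE)),
               class = "caprihap_domain_error")

  ## invariants across random tables: bounds and r2 = 1 => |D'| = 1
  for (i in 1:25) {
    counts <- rmultinom(1, 200, prob = runif(4, 0.05, 1))[, 1]
    hi3 <- rep(c("A", "A", "a", "a"), counts)
    hj3 <- rep(c("B", "b", "B", "b"), counts)
    ld4 <- tryCatch(ld_pair(hi3, hj3), error = function(e) NULL)
    if (is.null(ld4)) next
    expect_lte(ld4$r2, 1 + 1e-12)
    expect_lte(ld4$d_prime, 1)
    expect_gte(ld4$d_prime, 0)
    if (abs(ld4$r2 - 1) < 1e-12) expect_equal(ld4$d_prime, 1)
  }

  ## ld_table emits the long format over polymorphic pairs
  ds <- simulate_herd(sim_config(n_goats = 12, n_farms = 3, seed = 5))
  tab <- ld_table(ds$assignments)
  expect_true(all(c("snp_i", "snp_j", "d_prime", "r2") %in% names(tab)))
  if (nrow(tab)) {
    expect_true(all(tab$r2 <= 1 + 1e-12))
    expect_true(all(tab$d_prime <= 1 + 1e-12))
  }
})

test_that("haplotype grouping recovers the generated inventory and ratio", {
  cfg <- sim_config(n_goats = 50, n_farms = 8, seed = 13)
  ds <- simulate_herd(cfg)
  grp <- group_by_haplotype(ds$assignments)

  ## inventory: every generated label's token sequence appears
  truth_seqs <- sort(unique(vapply(ds$truth$token_map, function(toks)
    paste(vapply(names(toks), function(bl) paste(toks[[bl]], collapse = "|"), ""),
          collapse = "/"), "")))
  carried <- sort(unique(ds$assignments$haplotype))
  expect_in(carried, truth_seqs)
  expect_equal(grp$summary$n_haplotypes, length(carried))
  expect_equal(grp$summary$n_animals, 50L)
  expect_equal(grp$summary$animals_per_haplotype, 50 / length(carried))

  ## membership covers all animals, one entry per carried haplotype
  memb <- unlist(grp$groups, use.names = FALSE)
  expect_setequal(unique(memb), ds$records$animal_id)
  per_animal <- table(memb)
  expect_true(all(per_animal %in% 1:2))
  het <- ds$diplotypes$hap1 != ds$diplotypes$hap2
  ## heterozygous carriers of two distinct sequences appear twice
  expect_equal(sum(per_animal == 2), sum(het))

  ## homozygous-only switch gives disjoint single memberships
  grp_hom <- group_by_haplotype(ds$assignments, homozygous_only = TRUE)
  memb_hom <- unlist(grp_hom$groups, use.names = FALSE)
  expect_equal(anyDuplicated(memb_hom), 0L)
  expect_equal(sort(memb_hom), sort(ds$diplotypes$animal_id[!het]))

  ## all-identical homozygotes collapse to one group
  blocks <- tiny_blocks()
  hom <- list(CSN1S1 = c("A", "A"), CSN1S2 = c("T", "T"),
              CSN2 = c("C", "C"), CSN3 = c("G", "G"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_haplotypes(path, list(G1 = list(hom, hom), G2 = list(hom, hom)))
  one <- group_by_haplotype(parse_haplotypes(path, blocks))
  expect_equal(one$summary$n_haplotypes, 1L)
})
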