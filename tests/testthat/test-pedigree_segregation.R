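make_ped <- function(n_cases = 4, n_carriers = 1, n_controls = 1) {
  famvar:::sim_pedigree(sim_config(n_cases = n_cases, n_carriers = n_carriers,
                                   n_controls = n_controls))
}

test_that("quality filter applies quality, depth, strand and caller criteria", {
  df <- data.frame(chrom = "1", pos = 1:5, ref = "A",
                   alt = c("G", "G", "G", "AG", "AG"),
                   qual = c(30, 30, 10, 50, 50),
                   depth = c(10L, 10L, 10L, 30L, 30L),
                   fwd_reads = c(3L, 5L, 3L, 5L, 5L),
                   rev_reads = c(2L, 0L, 2L, 5L, 5L),
                   caller_filter = c("PASS", "PASS", "PASS", "badReads",
                                     "PASS"),
                   gt_s = "0/1", stringsAsFactors = FALSE)
  vt <- variant_table(df)
  ok <- quality_filter(vt)
  # SNV with both-strand support passes; one-strand SNV is strand-biased;
  # low quality fails; non-PASS indel fails; PASS indel passes
  expect_identical(as.vector(ok), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(attr(ok, "reason")[2], "strand_bias")
  expect_identical(attr(ok, "reason")[4], "caller_filter")

  # missing quality fails with its own reason
  df$qual[1] <- NA
  ok2 <- quality_filter(variant_table(df))
  expect_false(ok2[1])
  expect_identical(attr(ok2, "reason")[1], "missing_quality")
})

test_that("MAF filter is inclusive at the threshold and spans all populations", {
  df <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                   gt_s = "0/1",
                   af_p1 = c(8.43e-5, 0.001, 0.0011),
                   af_p2 = c(0, 0, 0), stringsAsFactors = FALSE)
  vt <- variant_table(df)
  expect_identical(maf_filter(vt), c(TRUE, TRUE, FALSE))
  expect_error(maf_filter(vt, max_af = 0), class = "famvar_config_error")
  expect_error(maf_filter(vt, max_af = 1), class = "famvar_config_error")
  # declared population without a column: treated as absent (AF 0)
  expect_warning(keep <- maf_filter(vt, populations = c("p1", "p9")),
                 "p9")
  expect_identical(keep, c(TRUE, TRUE, FALSE))
})

test_that("segregation filter keeps case-only carrier patterns", {
  ped <- make_ped()
  gt <- function(case, carrier, control) {
    df <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
    for (s in paste0("case", 1:4)) df[[paste0("gt_", s)]] <- case
    df$gt_carrier1 <- carrier
    df$gt_control1 <- control
    variant_table(df)
  }
  keep <- function(vt) nrow(segregation_filter(vt, ped)$kept) == 1L

  expect_true(keep(gt("het", "het", "hom_ref")))      # full segregation
  expect_false(keep(gt("het", "het", "het")))         # control carries
  expect_true(keep(gt("het", "hom_ref", "hom_ref")))  # carrier unconstrained
  expect_true(keep(gt("hom_alt", "het", "hom_ref")))  # hom-alt counts as present

  # missing case genotype: strict drops, permissive keeps
  df <- as.data.frame(gt("het", "het", "hom_ref"))
  df$gt_case2 <- "./."
  vt <- variant_table(df)
  res_strict <- segregation_filter(vt, ped)
  expect_equal(nrow(res_strict$kept), 0L)
  expect_identical(res_strict$reason, "missing_case_gt")
  res_perm <- segregation_filter(vt, ped,
                                 segregation_rule(missing_case = "permissive"))
  expect_equal(nrow(res_perm$kept), 1L)

  # a pedigree sample absent from the genotype map is an error naming it
  ped2 <- pedigree_roles(rbind(as.data.frame(ped),
                               data.frame(family_id = "FAM1",
                                          sample_id = "ghost",
                                          father_id = "0", mother_id = "0",
                                          sex = "1", phenotype = "0",
                                          role = "case")))
  expect_error(segregation_filter(gt("het", "het", "hom_ref"), ped2),
               "ghost", class = "famvar_config_error")
})

test_that("segregation filter equals the brute-force genotype predicate", {
  sim <- simulate_cohort(sim_config(seed = 91, n_variants = 400,
                                    planted = list()))
  res <- segregation_filter(sim$variants, sim$pedigree)
  oracle <- brute_force_segregation(sim$variants, sim$pedigree)
  expect_identical(res$kept$variant_id, sim$variants$variant_id[oracle])
})

test_that("pre-filters are subsetting and commute", {
  sim <- simulate_cohort(sim_config(seed = 12, n_variants = 300,
                                    planted = list()))
  v <- sim$variants
  q <- quality_filter(v); m <- maf_filter(v)
  expect_true(all(v$variant_id[q & m] %in% v$variant_id))
  # quality-then-maf equals maf-then-quality
  a <- maf_filter(v[q, , drop = FALSE])
  b <- quality_filter(v[m, , drop = FALSE])
  expect_identical(v$variant_id[q][a], v$variant_id[m][b])
})

test_that("relatedness matrix is the Jaccard index of carrier sets", {
  ped <- pedigree_roles(data.frame(
    sample_id = c("A", "B", "C"), role = c("case", "case", "control"),
    stringsAsFactors = FALSE))
  df <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                   gt_A = c("het", "het", "hom_ref"),
                   gt_B = c("hom_ref", "het", "het"),
                   gt_C = c("hom_ref", "hom_ref", "hom_ref"),
                   stringsAsFactors = FALSE)
  vt <- variant_table(df)
  expect_warning(m <- relatedness_matrix(vt, ped), "C")
  # A carries {v1,v2}, B carries {v2,v3}: Jaccard 1/3
  expect_equal(m["A", "B"], 1 / 3)
  expect_equal(m["A", "A"], 1)
  expect_equal(m["A", "C"], 0)
  expect_true(isSymmetric(m))

  # identical genotype vectors give 1, disjoint sets give 0
  df2 <- df; df2$gt_B <- df2$gt_A
  df2$gt_C <- c("hom_ref", "hom_ref", "het")
  m2 <- relatedness_matrix(variant_table(df2), ped)
  expect_equal(m2["A", "B"], 1)
  expect_equal(m2["A", "C"], 0)
})
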