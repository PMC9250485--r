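score_df <- function(...) {
  base <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                     gt_s = "0/1", region_class = "exonic",
                     exonic_effect = "missense", stringsAsFactors = FALSE)
  vals <- list(...)
  for (nm in names(vals)) base[[nm]] <- vals[[nm]]
  variant_table(base)
}

test_that("region split routes every region class to its arm", {
  df <- data.frame(chrom = "1", pos = 1:9, ref = "A", alt = "G",
                   gt_s = "0/1", region_class = famvar:::REGION_CLASSES,
                   stringsAsFactors = FALSE)
  parts <- split_by_region(variant_table(df))
  expect_setequal(parts$coding$region_class, c("exonic", "splicing"))
  expect_setequal(parts$near_gene$region_class,
                  c("UTR5", "UTR3", "upstream", "downstream"))
  expect_setequal(parts$discarded$region_class,
                  c("intronic", "intergenic", "ncRNA"))
  expect_equal(nrow(parts$coding) + nrow(parts$near_gene) +
                 nrow(parts$discarded), 9L)

  df$region_class[1] <- "weird"
  expect_error(split_by_region(variant_table(df)), "weird")
})

test_that("synonymous exclusion keeps damaging effect classes and splicing", {
  df <- data.frame(chrom = "1", pos = 1:6, ref = "A", alt = "G",
                   gt_s = "0/1",
                   region_class = c(rep("exonic", 5), "splicing"),
                   exonic_effect = c("synonymous", "missense", "stopgain",
                                     "frameshift", "unknown", NA),
                   stringsAsFactors = FALSE)
  kept <- exclude_synonymous(variant_table(df))
  expect_setequal(kept$pos, c(2L, 3L, 4L, 6L))
  expect_equal(nrow(exclude_synonymous(kept[0, , drop = FALSE])), 0L)
})

test_that("conservation vote counts GERP, PhastCons (strict) and PhyloP", {
  v <- conservation_vote(score_df(gerp = 5.49, phylop = 5.60,
                                  phastcons = 0.91))
  expect_equal(v$votes, 3L); expect_true(v$pass)

  # boundary semantics: >= for GERP/PhyloP, strict > for PhastCons
  v2 <- conservation_vote(score_df(gerp = 2.0, phastcons = 0.3,
                                   phylop = 3.0))
  expect_equal(v2$votes, 2L); expect_true(v2$pass)

  v3 <- conservation_vote(score_df())
  expect_equal(v3$votes, 0L); expect_false(v3$pass)
})

test_that("intolerance vote uses Z for missense and pLI for LoF", {
  # all four criteria met: fraction 1
  v <- intolerance_vote(score_df(intol_local = -1, intol_esp6500 = -1,
                                 intol_exac = -1, exac_z = 0.5))
  expect_equal(v$fraction, 1); expect_true(v$pass)

  # three of four: 0.75, passes the 60% rule
  v2 <- intolerance_vote(score_df(intol_local = -1, intol_esp6500 = -1,
                                  intol_exac = -1, exac_z = -0.5))
  expect_equal(v2$fraction, 0.75); expect_true(v2$pass)

  # two of four: 0.5, fails
  v3 <- intolerance_vote(score_df(intol_local = -1, intol_esp6500 = -1,
                                  intol_exac = 0.5, exac_z = -0.5))
  expect_equal(v3$fraction, 0.5); expect_false(v3$pass)

  # stopgain uses pLI >= 0.9, not Z
  v4 <- intolerance_vote(score_df(exonic_effect = "stopgain",
                                  intol_local = -1, intol_esp6500 = -1,
                                  intol_exac = -1, exac_z = -2,
                                  exac_pli = 0.95))
  expect_equal(v4$fraction, 1)
  v5 <- intolerance_vote(score_df(exonic_effect = "stopgain",
                                  intol_local = -1, intol_esp6500 = -1,
                                  intol_exac = -1, exac_pli = 0.85))
  expect_equal(v5$fraction, 0.75)
})

test_that("deleteriousness vote applies the ten per-tool predicates", {
  all_pass <- list(pred_SIFT = "D", pred_PP2_HumDiv = "D",
                   pred_PP2_HumVar = "P", pred_LRT = "D",
                   pred_MutationTaster = "A", pred_MutationAssessor = "M",
                   pred_FATHMM = "D", pred_ReliabilityIndex = 9,
                   pred_VEST3 = 0.5, pred_PROVEAN = "D")
  v <- deleteriousness_vote(do.call(score_df, all_pass))
  expect_equal(v$fraction, 1); expect_true(v$pass)   # VEST3 0.5 passes (>=)

  nine <- all_pass; nine$pred_FATHMM <- "T"
  expect_equal(deleteriousness_vote(do.call(score_df, nine))$fraction, 0.9)

  eight <- nine; eight$pred_ReliabilityIndex <- 4
  expect_equal(deleteriousness_vote(do.call(score_df, eight))$fraction, 0.8)

  # missing tools count as failed with the fixed denominator
  v0 <- deleteriousness_vote(score_df(pred_SIFT = "D"))
  expect_equal(v0$fraction, 0.1); expect_false(v0$pass)
  # but in "available" mode the denominator shrinks
  va <- deleteriousness_vote(score_df(pred_SIFT = "D"),
                             cascade_config(denominator = "available"))
  expect_equal(va$fraction, 1)

  # unrecognized tokens are failures, reported once
  expect_message(
    vb <- deleteriousness_vote(score_df(pred_SIFT = "Q")),
    "unrecognized")
  expect_equal(vb$fraction, 0)
})

test_that("60% of 4 means 3 and 60% of 10 means 6 (vote arithmetic)", {
  # intolerance: k/4 passes iff k >= 3
  intl <- function(k) {
    vals <- list(intol_local = 1, intol_esp6500 = 1, intol_exac = 1,
                 exac_z = -1)
    for (nm in head(c("intol_local", "intol_esp6500", "intol_exac"), k))
      vals[[nm]] <- -1
    if (k >= 4) vals$exac_z <- 1
    intolerance_vote(do.call(score_df, vals))$pass
  }
  expect_identical(vapply(0:4, intl, TRUE), c(F, F, F, T, T))

  # deleteriousness: k/10 passes iff k >= 6
  tools <- c("SIFT", "PP2_HumDiv", "PP2_HumVar", "LRT", "MutationTaster",
             "MutationAssessor", "FATHMM", "PROVEAN")
  del <- function(k) {
    vals <- list(pred_ReliabilityIndex = 0, pred_VEST3 = 0)
    ok <- c("D", "D", "D", "D", "D", "M", "D", "D")
    for (i in seq_len(min(k, 8)))
      vals[[paste0("pred_", tools[i])]] <- ok[i]
    if (k >= 9) vals$pred_ReliabilityIndex <- 5
    if (k >= 10) vals$pred_VEST3 <- 0.5
    deleteriousness_vote(do.call(score_df, vals))$pass
  }
  expect_identical(vapply(0:10, del, TRUE),
                   c(F, F, F, F, F, F, T, T, T, T, T))
})

test_that("the cascade records every elimination in the funnel", {
  sim <- simulate_cohort(sim_config(
    seed = 5, n_variants = 60,
    planted = list(planted_variant("pass_all"),
                   planted_variant("fail_cadd"),
                   planted_variant("fail_conservation"),
                   planted_variant("fail_intolerance"),
                   planted_variant("fail_deleteriousness"),
                   planted_variant("fail_synonymous"),
                   planted_variant("fail_region"))))
  res <- run_coding_cascade(sim$variants)
  surv <- res$funnel$stages
  names(surv) <- vapply(surv, `[[`, "", "name")
  truth <- sim$truth[sim$truth$planted, ]
  for (i in seq_len(nrow(truth))) {
    id <- truth$variant_id[i]; fate <- truth$expected_stage[i]
    if (fate == "survivor") {
      expect_true(id %in% res$survivors$variant_id)
    } else if (fate == "segregation") {
      next  # not part of the coding cascade
    } else {
      # present in the stage's input, absent from its survivors
      expect_false(id %in% surv[[fate]]$surviving_ids)
    }
  }
  # cadd=9.99 eliminated exactly at the CADD stage
  cadd_id <- truth$variant_id[truth$profile == "fail_cadd"]
  expect_true(cadd_id %in% surv[["nonsynonymous"]]$surviving_ids)
  expect_false(cadd_id %in% surv[["cadd"]]$surviving_ids)
})

test_that("funnel is monotone and equals per-variant predicate conjunction", {
  sim <- simulate_cohort(sim_config(seed = 19, n_variants = 500,
                                    planted = list()))
  cfg <- cascade_config()
  res <- run_coding_cascade(sim$variants, cfg)
  counts <- summary(res$funnel)
  expect_true(all(counts$n_out <= counts$n_in))
  ids <- lapply(res$funnel$stages, `[[`, "surviving_ids")
  for (k in seq_along(ids)[-1])
    expect_true(all(ids[[k]] %in% ids[[k - 1]]))

  # order-free oracle: conjunction of independent per-variant predicates
  v <- sim$variants
  pred <- v$region_class %in% c("exonic", "splicing") &
    ((!is.na(v$exonic_effect) &
        v$exonic_effect %in% c("missense", "stopgain", "stoploss",
                               "frameshift")) |
       v$region_class == "splicing") &
    !is.na(v$cadd_phred) & v$cadd_phred >= 10 &
    conservation_vote(v, cfg)$pass &
    intolerance_vote(v, cfg)$pass &
    deleteriousness_vote(v, cfg)$pass
  expect_setequal(res$survivors$variant_id, v$variant_id[pred])

  # raising the CADD threshold never adds survivors
  res20 <- run_coding_cascade(sim$variants, cascade_config(cadd_min = 20))
  expect_true(all(res20$survivors$variant_id %in% res$survivors$variant_id))

  # survivor ordering: CADD descending, ties by variant id
  s <- res$survivors
  if (nrow(s) > 1)
    expect_identical(order(-s$cadd_phred, s$variant_id), seq_len(nrow(s)))
})
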