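# length-3 motif, consensus ACG
toy3 <- pfm_record("MA0001.1", "TOY3",
                   matrix(c(8, 1, 0,   # A
                            1, 7, 1,   # C
                            0, 1, 8,   # G
                            1, 1, 1),  # T
                          nrow = 4, byrow = TRUE,
                          dimnames = list(c("A", "C", "G", "T"), NULL)))

test_that("PWM construction yields finite log-odds and a positive range", {
  pwm <- build_pwm(toy3)
  expect_true(all(is.finite(pwm$log_odds)))
  expect_lt(pwm$score_min, pwm$score_max)
  expect_equal(pwm$score_min, sum(pwm$col_min))
  # consensus scores exactly 1 at its offset
  hits <- pwm_scan(pwm_consensus(pwm), pwm, threshold = 0.8)
  expect_equal(hits$rel_score[hits$strand == "+"], 1)
  expect_error(build_pwm(toy3, pseudocount = 0),
               class = "famvar_config_error")
})

test_that("scanner matches exhaustive enumeration of all trinucleotides", {
  pwm <- build_pwm(toy3)
  bases <- c("A", "C", "G", "T")
  words <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (th in c(0.5, 0.8)) {
    for (w in words) {
      got <- pwm_scan(w, pwm, threshold = th)
      want <- oracle_pwm_hits(w, toy3, threshold = th)
      expect_equal(got$start, want$start, info = w)
      expect_equal(got$strand, want$strand, info = w)
      expect_equal(got$rel_score, want$rel_score, tolerance = 1e-12)
    }
  }
})

test_that("scanner agrees with the brute-force oracle on longer sequences", {
  set.seed(77)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T", "N"), 60,
                                    replace = TRUE,
                                    prob = c(.24, .24, .24, .24, .04)),
                             collapse = ""))
  for (s in seqs) {
    got <- pwm_scan(s, build_pwm(toy3), threshold = 0.7)
    want <- oracle_pwm_hits(s, toy3, threshold = 0.7)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$rel_score, want$rel_score, tolerance = 1e-12)
  }
})

test_that("scanning is strand-symmetric and monotone in the threshold", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  pwm <- build_pwm(toy3)
  h <- pwm_scan(s, pwm, threshold = 0.6)
  h_rc <- pwm_scan(famvar:::revcomp(s), pwm, threshold = 0.6)
  # reverse-complementing the sequence swaps strands and mirrors coords
  key <- function(df, n) {
    k <- paste(df$strand, df$start, round(df$rel_score, 9))
    sort(k)
  }
  mirrored <- data.frame(start = nchar(s) - h$end + 1L,
                         strand = ifelse(h$strand == "+", "-", "+"),
                         rel_score = h$rel_score)
  expect_identical(key(h_rc), key(mirrored))

  # lowering the threshold never removes a hit
  h85 <- pwm_scan(s, pwm, threshold = 0.85)
  h80 <- pwm_scan(s, pwm, threshold = 0.80)
  expect_true(all(paste(h85$start, h85$strand) %in%
                    paste(h80$start, h80$strand)))
  expect_true(all(h80$rel_score >= 0 & h80$rel_score <= 1))
  expect_error(pwm_scan(s, pwm, threshold = 1.2),
               class = "famvar_config_error")
})

test_that("mutant sequence construction guards the reference base", {
  v <- list(pos = 129308531L, ref = "C", alt = "T")
  wt <- "AACCTCGATT"
  mut <- build_mutant_sequence(wt, 129308528L, v)
  expect_equal(nchar(mut), nchar(wt))
  expect_equal(substr(mut, 4, 4), "T")
  v_bad <- list(pos = 129308529L, ref = "C", alt = "T")  # actually A
  expect_error(build_mutant_sequence(wt, 129308528L, v_bad),
               "expected C, observed A")
  expect_error(build_mutant_sequence(wt, 129309000L, v), "outside")
})

test_that("regulatory annotation intersects the promoter correctly", {
  promoter <- genomic_intervals("12", 129308486, 129308588,
                                "SLC15A4_promoter", "-")
  tracks <- list(promoters = promoter)
  v_in <- list(chrom = "12", pos = 129308531L, variant_id = "x")
  v_out <- list(chrom = "12", pos = 129308600L, variant_id = "y")
  ann_in <- annotate_regulatory(v_in, tracks)
  ann_out <- annotate_regulatory(v_out, tracks)
  expect_equal(nrow(ann_in$overlapping_elements), 1L)
  expect_equal(ann_in$overlapping_elements$name, "SLC15A4_promoter")
  expect_equal(nrow(ann_out$overlapping_elements), 0L)
  # boundary: 1-based start and end are covered, flanks are not
  hit_at <- function(p) nrow(annotate_regulatory(
    list(chrom = "12", pos = p, variant_id = "z"),
    tracks)$overlapping_elements)
  expect_equal(hit_at(129308487L), 1L)
  expect_equal(hit_at(129308486L), 0L)
  expect_equal(hit_at(129308588L), 1L)
  expect_equal(hit_at(129308589L), 0L)
  # chromosome mismatch warns and returns empty overlap
  expect_warning(ann_mis <- annotate_regulatory(
    list(chrom = "7", pos = 10L, variant_id = "w"), tracks), "absent")
  expect_equal(nrow(ann_mis$overlapping_elements), 0L)
})

test_that("interval intersection equals the quadratic oracle", {
  set.seed(41)
  n <- 1000
  start <- sample.int(5000, n, replace = TRUE)
  iv <- genomic_intervals("1", start, start + sample.int(50, n, TRUE))
  for (pos in sample.int(5100, 25)) {
    ann <- annotate_regulatory(list(chrom = "1", pos = pos,
                                    variant_id = "v"),
                               list(t = iv))
    want <- brute_force_overlap(pos, iv)
    expect_setequal(ann$overlapping_elements$name, iv$name[want])
  }
})

test_that("chromatin-state join copies and validates the annotation row", {
  st <- data.frame(variant_id = "12_129308531_C_T", chromhmm_state = "TssA",
                   chromhmm_score = 0.969, segway_label = "TSS",
                   tfbs_count = 52L, tfbs_peak_count = 115L,
                   stringsAsFactors = FALSE)
  ann <- annotate_regulatory(list(chrom = "12", pos = 129308531L,
                                  variant_id = "12_129308531_C_T"),
                             list(), st)
  expect_equal(ann$chromhmm_state, "TssA")
  expect_equal(ann$chromhmm_score, 0.969)
  expect_equal(ann$tfbs_peak_count, 115L)
  st$chromhmm_score <- 1.5
  expect_error(annotate_regulatory(list(chrom = "12", pos = 129308531L,
                                        variant_id = "12_129308531_C_T"),
                                   list(), st),
               class = "famvar_format_error")
})

test_that("differential TFBS calls group by transcription factor", {
  hits <- load_differential_hits()
  d <- differential_tfbs(hits[hits$targeting == "WT", ],
                         hits[hits$targeting == "MUT", ])
  expect_length(d$wt_only, 9L)
  expect_length(d$mut_only, 8L)
  expect_length(d$shared, 0L)
  # a TF with two matrices collapses to one entry
  expect_equal(sum(d$wt_only == "STAT1"), 1L)
  expect_equal(sum(d$mut_only == "SCRT1"), 1L)

  # identical hit lists: everything shared
  d2 <- differential_tfbs(hits, hits)
  expect_length(d2$wt_only, 0L)
  expect_length(d2$mut_only, 0L)
  expect_setequal(d2$shared, unique(hits$tf_name))

  # the three sets partition the TF universe
  all_tfs <- unique(c(d$wt_only, d$mut_only, d$shared))
  expect_setequal(all_tfs, unique(hits$tf_name))
  expect_length(intersect(d$wt_only, d$mut_only), 0L)
})

test_that("the noncoding arm flags CADD and reports the planted disruption", {
  pm <- simulate_promoter(promoter_config(seed = 9))
  rep <- run_noncoding(pm$variant, sequences = pm$sequences,
                       pfms = pm$pfms)
  res <- rep$variants[[pm$variant$variant_id]]
  expect_true(res$cadd_flag)
  expect_true(pm$truth$tf %in% res$differential$wt_only)
  expect_true(all(rep$table$targeting %in% c("WT", "MUT")))
  # a variant with no covering sequence is skipped with a warning
  v2 <- pm$variant; v2$pos <- v2$pos + 10000L
  v2$variant_id <- "far_away"
  expect_warning(run_noncoding(v2, sequences = pm$sequences,
                               pfms = pm$pfms), "covering")
})
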