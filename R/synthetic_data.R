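# Deterministic generator of pedigrees, annotated variant tables,
# promoter sequences and toy PFMs with the statistical structure the
# pipeline assumes.  Distributions are testability choices for synthetic
# data, not estimates from any real cohort; all randomness flows through
# the single seed in the configuration.

#' Specification of a planted variant
#'
#' A planted variant realizes a chosen fate in the cascade exactly, with
#' scores set just inside or outside each threshold, so recovery can be
#' asserted in tests.
#'
#' @param profile which fate to realize: `"pass_all"` (survives every
#'   stage) or `"fail_<stage>"` where stage is one of `segregation`,
#'   `region`, `synonymous`, `cadd`, `conservation`, `intolerance`,
#'   `deleteriousness` (fails exactly at that stage, passes all earlier
#'   ones).
#' @param genotype_pattern optional named character vector (sample ->
#'   genotype level) overriding the default pattern (cases and possible
#'   carriers het, controls hom-ref).
#' @return object of class `planted_variant`.
#' @export
planted_variant <- function(profile = c("pass_all", "fail_segregation",
                                        "fail_region", "fail_synonymous",
                                        "fail_cadd", "fail_conservation",
                                        "fail_intolerance",
                                        "fail_deleteriousness"),
                            genotype_pattern = NULL) {
  structure(list(profile = match.arg(profile),
                 genotype_pattern = genotype_pattern),
            class = "planted_variant")
}

#' Simulation configuration for a synthetic family cohort
#'
#' Defaults emulate the scale and structure of a three-generation
#' pedigree study: a 6-sample family (4 cases, 1 possible carrier,
#' 1 control) and a table of roughly 10^4 rare variants with
#' annotation-score columns.  Background allele frequencies are
#' log-uniform on 10^-6..10^-2; the PHRED-like CADD background is drawn
#' as -10 log10(U) so that 10% of variants reach the >= 10 threshold by
#' construction; per-sample background carrier probability is 0.25.
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param n_variants number of variants including planted ones.
#' @param n_cases,n_controls,n_carriers pedigree composition.
#' @param planted list of [planted_variant()] specifications.
#' @param carrier_prob per-sample probability that a background variant
#'   is carried (het or hom-alt).
#' @param het_fraction fraction of carried background genotypes that are
#'   het rather than hom-alt.
#' @param missing_rate per-genotype missingness probability.
#' @param damaging_prob marginal probability that a categorical predictor
#'   reports a damaging category for a background variant.
#' @param indel_fraction fraction of background variants that are
#'   deletions rather than SNVs.
#' @param af_log10_range log10 range of background allele frequencies.
#' @param populations allele-frequency populations to simulate.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_variants = 10000L, n_cases = 4L,
                       n_controls = 1L, n_carriers = 1L,
                       planted = list(planted_variant("pass_all")),
                       carrier_prob = 0.25, het_fraction = 0.95,
                       missing_rate = 0, damaging_prob = 0.3,
                       indel_fraction = 0.05,
                       af_log10_range = c(-6, -2),
                       populations = c("1000g_eur", "exac_nfe",
                                       "esp6500", "local")) {
  if (n_variants < length(planted))
    stop_famvar("n_variants (%d) smaller than number of planted variants (%d)",
                n_variants, length(planted), class = "famvar_config_error")
  if (!all(vapply(planted, inherits, TRUE, "planted_variant")))
    stop_famvar("'planted' must be a list of planted_variant objects",
                class = "famvar_config_error")
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_carriers = as.integer(n_carriers), planted = planted,
                 carrier_prob = carrier_prob, het_fraction = het_fraction,
                 missing_rate = missing_rate, damaging_prob = damaging_prob,
                 indel_fraction = indel_fraction,
                 af_log10_range = af_log10_range,
                 populations = populations),
            class = "sim_config")
}

sim_pedigree <- function(cfg) {
  ids <- c(sprintf("case%d", seq_len(cfg$n_cases)),
           if (cfg$n_carriers > 0) sprintf("carrier%d", seq_len(cfg$n_carriers)),
           if (cfg$n_controls > 0) sprintf("control%d", seq_len(cfg$n_controls)))
  roles <- c(rep("case", cfg$n_cases),
             rep("possible_carrier", cfg$n_carriers),
             rep("control", cfg$n_controls))
  pedigree_roles(data.frame(
    family_id = "FAM1", sample_id = ids, father_id = "0", mother_id = "0",
    sex = rep(c("1", "2"), length.out = length(ids)), phenotype = "0",
    role = roles, stringsAsFactors = FALSE))
}

# Deterministic annotation values for a planted variant realizing its
# profile: every threshold is passed comfortably except the targeted one,
# which is narrowly missed (e.g. CADD 9.99 against the 10 cutoff).
planted_row_values <- function(profile) {
  vals <- list(
    region_class = "exonic", exonic_effect = "missense",
    qual = 60, depth = 40L, fwd_reads = 20L, rev_reads = 20L,
    caller_filter = "PASS", af = 1e-5,
    cadd_phred = 25, gerp = 4, phastcons = 0.8, phylop = 4,
    intol_local = -1, intol_esp6500 = -1, intol_exac = -1,
    exac_z = 1, exac_pli = 0.99,
    preds = list(SIFT = "D", PP2_HumDiv = "D", PP2_HumVar = "P",
                 LRT = "D", MutationTaster = "D", MutationAssessor = "H",
                 FATHMM = "T", ReliabilityIndex = 7, VEST3 = 0.9,
                 PROVEAN = "D"),  # 9 of 10 favorable
    control_gt = "hom_ref")
  switch(profile,
         pass_all = vals,
         fail_segregation = { vals$control_gt <- "het"; vals },
         fail_region = { vals$region_class <- "intronic"
                         vals$exonic_effect <- NA_character_; vals },
         fail_synonymous = { vals$exonic_effect <- "synonymous"; vals },
         fail_cadd = { vals$cadd_phred <- 9.99; vals },
         fail_conservation = { vals$gerp <- 1.99; vals$phastcons <- 0.30
                               vals$phylop <- 3; vals },  # exactly 1 vote
         fail_intolerance = { vals$intol_exac <- 0.5; vals$exac_z <- -0.2
                              vals },                      # 2 of 4
         fail_deleteriousness = {
           vals$preds <- list(SIFT = "D", PP2_HumDiv = "D",
                              PP2_HumVar = "P", LRT = "D",
                              MutationTaster = "D", MutationAssessor = "L",
                              FATHMM = "T", ReliabilityIndex = 3,
                              VEST3 = 0.2, PROVEAN = "N")  # 5 of 10
           vals })
}

planted_expected_stage <- function(profile) {
  switch(profile,
         pass_all = "survivor",
         fail_segregation = "segregation",
         fail_region = "coding_region",
         fail_synonymous = "nonsynonymous",
         fail_cadd = "cadd",
         fail_conservation = "conservation",
         fail_intolerance = "intolerance",
         fail_deleteriousness = "deleteriousness")
}

#' Simulate a family cohort with planted variants
#'
#' Generates a pedigree, an annotated variant table and a truth table.
#' Planted variants realize their profiles exactly (verified at
#' generation time by running the corresponding filter predicates);
#' background variants are drawn i.i.d. from the configured
#' distributions.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedigree` ([pedigree_roles()]), `variants`
#'   ([variant_table()]) and `truth` (data frame with `variant_id`,
#'   `planted`, `profile`, `expected_stage`; `expected_stage` is NA for
#'   background variants, whose fate is random).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ped <- sim_pedigree(cfg)
  n <- cfg$n_variants
  k <- length(cfg$planted)
  samples <- ped$sample_id
  roles <- ped$role

  chrom <- as.character(sample.int(22L, n, replace = TRUE))
  pos <- sample.int(2^28, n, replace = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  is_indel <- runif(n) < cfg$indel_fraction
  ref[is_indel] <- paste0(ref[is_indel],
                          sample(bases, sum(is_indel), replace = TRUE))
  alt[is_indel] <- substr(ref[is_indel], 1L, 1L)

  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   gene = sprintf("GENE%04d", sample.int(500L, n, TRUE)),
                   stringsAsFactors = FALSE)
  df$region_class <- sample(REGION_CLASSES, n, replace = TRUE,
                            prob = c(0.20, 0.01, 0.03, 0.05, 0.04, 0.03,
                                     0.45, 0.14, 0.05))
  eff_pool <- c("synonymous", "missense", "stopgain", "stoploss",
                "nonframeshift", "frameshift", "unknown")
  df$exonic_effect <- ifelse(
    df$region_class == "exonic",
    sample(eff_pool, n, replace = TRUE,
           prob = c(0.40, 0.48, 0.03, 0.01, 0.03, 0.03, 0.02)),
    NA_character_)

  df$qual <- round(runif(n, 10, 90), 1)
  df$depth <- rpois(n, 30L)
  alt_reads <- pmax(1L, rbinom(n, pmax(df$depth, 1L), 0.5))
  df$fwd_reads <- rbinom(n, alt_reads, 0.5)
  df$rev_reads <- alt_reads - df$fwd_reads
  df$caller_filter <- sample(c("PASS", "badReads"), n, TRUE, c(0.97, 0.03))

  r <- cfg$af_log10_range
  for (p in cfg$populations)
    df[[paste0("af_", p)]] <- 10^runif(n, r[1], r[2])

  for (s in samples) {
    carried <- runif(n) < cfg$carrier_prob
    gt <- ifelse(carried,
                 ifelse(runif(n) < cfg$het_fraction, "het", "hom_alt"),
                 "hom_ref")
    if (cfg$missing_rate > 0)
      gt[runif(n) < cfg$missing_rate] <- "missing"
    df[[paste0("gt_", s)]] <- gt
  }

  df$cadd_phred <- round(pmin(-10 * log10(runif(n)), 60), 3)
  df$gerp <- round(rnorm(n, 0, 2), 3)
  df$phastcons <- round(rbeta(n, 0.5, 0.5), 3)
  df$phylop <- round(rnorm(n, 0.5, 1.5), 3)
  df$intol_local <- round(rnorm(n), 3)
  df$intol_esp6500 <- round(rnorm(n), 3)
  df$intol_exac <- round(rnorm(n), 3)
  df$exac_z <- round(rnorm(n, 0, 1.5), 3)
  df$exac_pli <- round(rbeta(n, 0.2, 0.2), 4)
  benign <- c(SIFT = "T", PP2_HumDiv = "B", PP2_HumVar = "B", LRT = "N",
              MutationTaster = "N", MutationAssessor = "L", FATHMM = "T",
              PROVEAN = "N")
  damaging <- c(SIFT = "D", PP2_HumDiv = "D", PP2_HumVar = "D", LRT = "D",
                MutationTaster = "D", MutationAssessor = "M", FATHMM = "D",
                PROVEAN = "D")
  for (tool in names(benign))
    df[[paste0("pred_", tool)]] <- ifelse(runif(n) < cfg$damaging_prob,
                                          damaging[[tool]], benign[[tool]])
  df$pred_ReliabilityIndex <- sample(0:10, n, replace = TRUE)
  df$pred_VEST3 <- round(runif(n), 3)

  # Overwrite the first k rows with the planted variants.
  for (i in seq_len(k)) {
    pv <- cfg$planted[[i]]
    v <- planted_row_values(pv$profile)
    df$chrom[i] <- "1"; df$pos[i] <- 1000L + i
    df$ref[i] <- "A"; df$alt[i] <- "G"
    df$gene[i] <- sprintf("PLANT%02d", i)
    df$region_class[i] <- v$region_class
    df$exonic_effect[i] <- v$exonic_effect
    df$qual[i] <- v$qual; df$depth[i] <- v$depth
    df$fwd_reads[i] <- v$fwd_reads; df$rev_reads[i] <- v$rev_reads
    df$caller_filter[i] <- v$caller_filter
    for (p in cfg$populations) df[[paste0("af_", p)]][i] <- v$af
    for (s in seq_along(samples)) {
      gt <- if (!is.null(pv$genotype_pattern) &&
                samples[s] %in% names(pv$genotype_pattern))
        pv$genotype_pattern[[samples[s]]]
      else if (roles[s] == "control") v$control_gt
      else "het"
      df[[paste0("gt_", samples[s])]][i] <- gt
    }
    df$cadd_phred[i] <- v$cadd_phred
    df$gerp[i] <- v$gerp; df$phastcons[i] <- v$phastcons
    df$phylop[i] <- v$phylop
    df$intol_local[i] <- v$intol_local
    df$intol_esp6500[i] <- v$intol_esp6500
    df$intol_exac[i] <- v$intol_exac
    df$exac_z[i] <- v$exac_z; df$exac_pli[i] <- v$exac_pli
    for (tool in names(v$preds))
      df[[paste0("pred_", tool)]][i] <- v$preds[[tool]]
  }

  variants <- variant_table(df, af_populations = cfg$populations)
  truth <- data.frame(
    variant_id = variants$variant_id,
    planted = seq_len(n) <= k,
    profile = c(vapply(cfg$planted, `[[`, "", "profile"),
                rep(NA_character_, n - k)),
    expected_stage = c(vapply(cfg$planted, function(p)
      planted_expected_stage(p$profile), ""),
      rep(NA_character_, n - k)),
    stringsAsFactors = FALSE)
  verify_planted(variants, ped, truth)
  list(pedigree = ped, variants = variants, truth = truth)
}

# Generation-time check that each planted variant realizes its profile;
# errors name the stage whose predicate disagrees.
verify_planted <- function(variants, pedigree, truth) {
  idx <- which(truth$planted)
  if (!length(idx)) return(invisible(TRUE))
  cfg <- cascade_config()
  for (i in idx) {
    v <- variants[i, , drop = FALSE]
    expected <- truth$expected_stage[i]
    if (!quality_filter(v)[1])
      stop_famvar("planted variant %s fails the quality filter", v$variant_id)
    if (!maf_filter(v)[1])
      stop_famvar("planted variant %s fails the MAF filter", v$variant_id)
    stage_ok <- c(
      segregation = nrow(segregation_filter(v, pedigree)$kept) == 1L,
      coding_region = v$region_class %in% CODING_REGIONS,
      nonsynonymous = nrow(exclude_synonymous(v)) == 1L,
      cadd = !is.na(v$cadd_phred) && v$cadd_phred >= cfg$cadd_min,
      conservation = conservation_vote(v, cfg)$pass,
      intolerance = intolerance_vote(v, cfg)$pass,
      deleteriousness = deleteriousness_vote(v, cfg)$pass)
    for (stage in names(stage_ok)) {
      if (expected == stage) {
        if (stage_ok[[stage]])
          stop_famvar("planted variant %s: profile '%s' unexpectedly passes stage '%s'",
                      v$variant_id, truth$profile[i], stage)
        break
      }
      if (!stage_ok[[stage]])
        stop_famvar("planted variant %s: profile '%s' unexpectedly fails stage '%s'",
                    v$variant_id, truth$profile[i], stage)
    }
  }
  invisible(TRUE)
}

sharpen_pfm <- function(pfm, power) {
  counts <- pfm$counts^power
  counts <- sweep(counts, 2, colSums(counts), "/") * 1000
  pfm_record(pfm$matrix_id, pfm$tf_name, counts)
}

#' Built-in toy position frequency matrices
#'
#' Each toy motif has moderately informative columns plus one
#' near-deterministic maximum-information column, so that a single
#' substitution at that column drops the relative score of the consensus
#' site below the standard 80% threshold.
#'
#' @param soft count vector for the moderate columns (consensus base
#'   first).
#' @param sharp_total count mass of the sharp column's consensus base.
#' @return list of [pfm_record()] objects.
#' @export
toy_pfms <- function(soft = c(55, 15, 15, 15), sharp_total = 1000) {
  make <- function(matrix_id, tf_name, consensus, sharp_pos) {
    bases <- c("A", "C", "G", "T")
    cons <- strsplit(consensus, "")[[1]]
    counts <- sapply(seq_along(cons), function(j) {
      col <- stats::setNames(rep(soft[2], 4), bases)
      col[cons[j]] <- soft[1]
      if (j == sharp_pos) {
        col[] <- 0
        col[cons[j]] <- sharp_total
      }
      col
    })
    pfm_record(matrix_id, tf_name, counts)
  }
  list(make("MA9001.1", "TOYA", "ACGTGACC", 4L),
       make("MA9002.1", "TOYB", "GGATCCGT", 5L),
       make("MA9003.1", "TOYC", "CACGTG", 3L))
}

#' Promoter-simulation configuration
#'
#' @param seed integer seed.
#' @param length promoter length in bp.
#' @param chrom,start genomic anchoring of the synthetic window (1-based
#'   start).
#' @param pfms candidate motifs; the planted one is
#'   `pfms[[plant_index]]`.
#' @param plant_index which motif to plant.
#' @param offset 1-based offset of the planted consensus within the
#'   promoter; default centers it.
#' @param strand strand on which the consensus is planted.
#' @param threshold relative-score threshold used for the generation-time
#'   verification (default 0.8).
#' @param max_retries how many sharpen-and-retry attempts before giving
#'   up.
#' @return object of class `promoter_config`.
#' @export
promoter_config <- function(seed = 1L, length = 200L, chrom = "12",
                            start = 1001L, pfms = toy_pfms(),
                            plant_index = 1L, offset = NULL,
                            strand = c("+", "-"), threshold = 0.8,
                            max_retries = 5L) {
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 chrom = chrom, start = as.integer(start), pfms = pfms,
                 plant_index = as.integer(plant_index), offset = offset,
                 strand = match.arg(strand), threshold = threshold,
                 max_retries = as.integer(max_retries)),
            class = "promoter_config")
}

#' Simulate a promoter with a planted, disruptable motif
#'
#' Generates a random promoter sequence containing the consensus site of
#' one motif, and a single-nucleotide variant at the motif's
#' maximum-information position chosen to drop the site's relative score
#' below the threshold.  The construction is verified at generation time
#' by scanning both sequences with every configured motif: the planted
#' transcription factor must appear in the wild-type-only set of the
#' differential call.  If verification fails the generator retries with
#' a sharper motif and a shifted sub-seed, then errors.
#'
#' @param cfg a [promoter_config()].
#' @return list with `wt_seq`, `mut_seq`, `variant` (one-row
#'   [variant_table()]), `pfms` (the motif set actually used), `sequences`
#'   (ready for [run_noncoding()]) and `truth` (planted TF, matrix id,
#'   motif offset, disrupted position, strand).
#' @export
simulate_promoter <- function(cfg = promoter_config()) {
  stopifnot(inherits(cfg, "promoter_config"))
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (attempt in seq_len(cfg$max_retries)) {
    set.seed(cfg$seed + (attempt - 1L) * 1000L)
    pfms <- cfg$pfms
    if (attempt > 1L)
      pfms[[cfg$plant_index]] <- sharpen_pfm(pfms[[cfg$plant_index]],
                                             1 + attempt / 2)
    pfm <- pfms[[cfg$plant_index]]
    pwm <- build_pwm(pfm)
    L <- ncol(pwm$log_odds)
    offset <- cfg$offset %||% (floor((cfg$length - L) / 2) + 1L)
    if (offset < 1L || offset + L - 1L > cfg$length)
      stop_famvar("motif offset outside promoter", class = "famvar_config_error")

    wt <- paste(sample(bases, cfg$length, replace = TRUE), collapse = "")
    consensus <- pwm_consensus(pwm)
    site <- if (cfg$strand == "+") consensus else revcomp(consensus)
    substr(wt, offset, offset + L - 1L) <- site

    info <- pwm$col_max - pwm$col_min
    j <- which.max(info)
    seq_pos <- if (cfg$strand == "+") offset + j - 1L else offset + (L - j)
    worst <- rownames(pwm$log_odds)[which.min(pwm$log_odds[, j])]
    ref_base <- substr(wt, seq_pos, seq_pos)
    alt_base <- if (cfg$strand == "+") worst else unname(comp[worst])
    if (alt_base == ref_base) next  # degenerate column; retry sharper

    mut <- wt
    substr(mut, seq_pos, seq_pos) <- alt_base

    pwms <- lapply(pfms, build_pwm)
    scan_all <- function(x) do.call(rbind, lapply(pwms, function(p)
      pwm_scan(x, p, threshold = cfg$threshold)))
    hw <- scan_all(wt); hm <- scan_all(mut)
    planted_hit <- any(hw$matrix_id == pfm$matrix_id & hw$start == offset &
                         hw$strand == cfg$strand)
    diffres <- differential_tfbs(hw, hm)
    if (planted_hit && pfm$tf_name %in% diffres$wt_only) {
      gpos <- cfg$start + seq_pos - 1L
      vdf <- data.frame(chrom = cfg$chrom, pos = gpos, ref = ref_base,
                        alt = alt_base, gene = "SIMGENE",
                        region_class = "upstream",
                        exonic_effect = NA_character_,
                        qual = 60, depth = 40L, fwd_reads = 20L,
                        rev_reads = 20L, caller_filter = "PASS",
                        af_local = 1e-5, cadd_phred = 12,
                        gt_case1 = "het", gt_case2 = "het",
                        gt_case3 = "het", gt_case4 = "het",
                        gt_carrier1 = "het", gt_control1 = "hom_ref",
                        stringsAsFactors = FALSE)
      variant <- variant_table(vdf, af_populations = "local")
      return(list(wt_seq = wt, mut_seq = mut, variant = variant,
                  pfms = pfms,
                  sequences = list(list(name = "sim_promoter", seq = wt,
                                        chrom = cfg$chrom,
                                        start = cfg$start)),
                  truth = list(tf = pfm$tf_name,
                               matrix_id = pfm$matrix_id,
                               motif_offset = offset,
                               disrupt_position = seq_pos,
                               strand = cfg$strand)))
    }
  }
  stop_famvar("planted mutation failed to cross the %.0f%% threshold after %d attempts",
              100 * cfg$threshold, cfg$max_retries)
}
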