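# The coding-variant cascade: region split, synonymous exclusion, CADD
# threshold, conservation vote, gene-intolerance vote, ensemble
# deleteriousness vote, with funnel accounting.

#' Cascade configuration
#'
#' Thresholds of the coding cascade.  Defaults encode the standard
#' criteria: PHRED-scaled CADD >= 10 (the most deleterious ~10% of
#' substitutions genome-wide), conservation support from at least 2 of
#' GERP (>= 2.0), PhastCons (> 0.3, strict) and PhyloP (>= 3.0), at least
#' 60% of four gene-intolerance criteria, and at least 60% of the ten
#' ensemble deleteriousness predictors.
#'
#' @param cadd_min minimum PHRED-scaled CADD score (default 10).
#' @param gerp_min minimum GERP score (default 2, inclusive).
#' @param phastcons_min_exclusive PhastCons threshold, strict `>`
#'   (default 0.3).
#' @param phylop_min minimum PhyloP score (default 3, inclusive).
#' @param conservation_votes_needed votes needed out of 3 (default 2).
#' @param intolerance_fraction fraction of the 4 intolerance criteria
#'   required (default 0.6, i.e. >= 3 of 4).
#' @param deleteriousness_fraction fraction of the 10 predictors required
#'   (default 0.6, i.e. >= 6 of 10).
#' @param denominator `"fixed"` (default): fractions use the full
#'   denominator (4 or 10) and missing values count as failed criteria;
#'   `"available"`: fractions use only criteria with observed values.
#' @return object of class `cascade_config`.
#' @export
cascade_config <- function(cadd_min = 10, gerp_min = 2,
                           phastcons_min_exclusive = 0.3, phylop_min = 3,
                           conservation_votes_needed = 2,
                           intolerance_fraction = 0.6,
                           deleteriousness_fraction = 0.6,
                           denominator = c("fixed", "available")) {
  for (nm in c("cadd_min", "gerp_min", "phastcons_min_exclusive",
               "phylop_min", "conservation_votes_needed",
               "intolerance_fraction", "deleteriousness_fraction"))
    assert_scalar_number(get(nm), nm)
  if (intolerance_fraction <= 0 || intolerance_fraction > 1 ||
      deleteriousness_fraction <= 0 || deleteriousness_fraction > 1)
    stop_famvar("vote fractions must lie in (0, 1]", class = "famvar_config_error")
  if (conservation_votes_needed < 0 || conservation_votes_needed > 3)
    stop_famvar("conservation_votes_needed must be between 0 and 3",
                class = "famvar_config_error")
  structure(list(cadd_min = cadd_min, gerp_min = gerp_min,
                 phastcons_min_exclusive = phastcons_min_exclusive,
                 phylop_min = phylop_min,
                 conservation_votes_needed = conservation_votes_needed,
                 intolerance_fraction = intolerance_fraction,
                 deleteriousness_fraction = deleteriousness_fraction,
                 denominator = match.arg(denominator)),
            class = "cascade_config")
}

#' Split variants by genomic region class
#'
#' @param variants a [variant_table()] with populated `region_class`.
#' @return list with elements `coding` (exonic, splicing), `near_gene`
#'   (5'/3' UTR, upstream, downstream) and `discarded` (intronic,
#'   intergenic, ncRNA), each a subset of `variants`.
#' @export
split_by_region <- function(variants) {
  rc <- variants$region_class
  if (is.null(rc))
    stop_famvar("variant table has no region_class column",
                class = "famvar_config_error")
  bad <- unique(rc[is.na(rc) | !rc %in% REGION_CLASSES])
  if (length(bad))
    stop_famvar("unknown region_class label(s): %s",
                paste(ifelse(is.na(bad), "NA", bad), collapse = ", "))
  list(coding = variants[rc %in% CODING_REGIONS, , drop = FALSE],
       near_gene = variants[rc %in% NEARGENE_REGIONS, , drop = FALSE],
       discarded = variants[rc %in% DISCARD_REGIONS, , drop = FALSE])
}

#' Exclude synonymous variants
#'
#' Keeps missense, stopgain, stoploss and frameshift variants, plus any
#' variant in the `splicing` region class (whose exonic effect may be
#' undefined).  Synonymous, non-frameshift and unknown-effect exonic
#' variants are dropped as presumed low-impact.
#'
#' @param coding a [variant_table()] subset (the coding arm).
#' @return the filtered subset.
#' @export
exclude_synonymous <- function(coding) {
  eff <- coding$exonic_effect %||% rep(NA_character_, nrow(coding))
  rc <- coding$region_class %||% rep(NA_character_, nrow(coding))
  keep <- (!is.na(eff) & eff %in% c("missense", "stopgain", "stoploss",
                                    "frameshift")) |
    (!is.na(rc) & rc == "splicing")
  coding[keep, , drop = FALSE]
}

#' Conservation vote
#'
#' One vote each for GERP >= `gerp_min`, PhastCons strictly greater than
#' `phastcons_min_exclusive`, and PhyloP >= `phylop_min`.  A missing score
#' is a failed vote.
#'
#' @param variants a [variant_table()] (uses columns `gerp`, `phastcons`,
#'   `phylop`).
#' @param cfg a [cascade_config()].
#' @return data frame with per-variant `votes` (0-3) and `pass`.
#' @export
conservation_vote <- function(variants, cfg = cascade_config()) {
  n <- nrow(variants)
  gerp <- variants$gerp %||% rep(NA_real_, n)
  pc <- variants$phastcons %||% rep(NA_real_, n)
  pp <- variants$phylop %||% rep(NA_real_, n)
  v <- (!is.na(gerp) & gerp >= cfg$gerp_min) +
    (!is.na(pc) & pc > cfg$phastcons_min_exclusive) +
    (!is.na(pp) & pp >= cfg$phylop_min)
  data.frame(votes = as.integer(v),
             pass = v >= cfg$conservation_votes_needed)
}

#' Gene-intolerance vote
#'
#' Four Boolean criteria per variant: the three gene intolerance scores
#' (local cohort, ESP6500-based, ExAC-based) each below 0, plus one
#' class-specific ExAC criterion -- missense variants use the missense
#' Z score (> 0), loss-of-function variants (stopgain, stoploss,
#' frameshift, splicing) use pLI (>= 0.9).  With the default fixed
#' denominator, missing scores are failed criteria and the fraction is
#' passed/4; the vote passes at `intolerance_fraction` (0.6 requires 3
#' of 4).
#'
#' @param variants a [variant_table()] (uses `intol_local`,
#'   `intol_esp6500`, `intol_exac`, `exac_z`, `exac_pli`,
#'   `exonic_effect`, `region_class`).
#' @param cfg a [cascade_config()].
#' @return data frame with per-variant `fraction` and `pass`.
#' @export
intolerance_vote <- function(variants, cfg = cascade_config()) {
  n <- nrow(variants)
  get_col <- function(nm) variants[[nm]] %||% rep(NA_real_, n)
  il <- get_col("intol_local"); ie <- get_col("intol_esp6500")
  ix <- get_col("intol_exac")
  z <- get_col("exac_z"); pli <- get_col("exac_pli")
  eff <- variants$exonic_effect %||% rep(NA_character_, n)
  rc <- variants$region_class %||% rep(NA_character_, n)
  is_missense <- !is.na(eff) & eff == "missense"
  is_lof <- (!is.na(eff) & eff %in% c("stopgain", "stoploss", "frameshift")) |
    (!is.na(rc) & rc == "splicing")

  crit <- cbind(!is.na(il) & il < 0,
                !is.na(ie) & ie < 0,
                !is.na(ix) & ix < 0,
                ifelse(is_missense, !is.na(z) & z > 0,
                       ifelse(is_lof, !is.na(pli) & pli >= 0.9, FALSE)))
  avail <- cbind(!is.na(il), !is.na(ie), !is.na(ix),
                 ifelse(is_missense, !is.na(z),
                        ifelse(is_lof, !is.na(pli), FALSE)))
  denom <- if (cfg$denominator == "fixed") rep(4, n) else pmax(rowSums(avail), 0)
  frac <- ifelse(denom > 0, rowSums(crit) / denom, 0)
  data.frame(fraction = frac, pass = denom > 0 & frac >= cfg$intolerance_fraction)
}

#' Per-tool pass predicates for the deleteriousness ensemble
#'
#' Categorical tools pass on their damaging categories (SIFT: D;
#' PolyPhen-2 HumDiv/HumVar: D or P; LRT: D; MutationTaster: D or A;
#' MutationAssessor: H or M; FATHMM: D; PROVEAN: D); Reliability Index
#' passes at >= 5 and VEST3 at >= 0.5.
#'
#' @return named list: for each tool either a character vector of passing
#'   categories or a numeric minimum (inclusive).
#' @export
default_tool_predicates <- function() {
  list(SIFT = "D",
       PP2_HumDiv = c("D", "P"),
       PP2_HumVar = c("D", "P"),
       LRT = "D",
       MutationTaster = c("D", "A"),
       MutationAssessor = c("H", "M"),
       FATHMM = "D",
       ReliabilityIndex = 5,
       VEST3 = 0.5,
       PROVEAN = "D")
}

#' Ensemble deleteriousness vote
#'
#' Applies the ten per-tool predicates of [default_tool_predicates()] to
#' the `pred_<tool>` columns.  With the default fixed denominator the
#' fraction is passed/10 and missing predictions are failed tools; the
#' vote passes at `deleteriousness_fraction` (0.6 requires 6 of 10).
#' MetaSVM/MetaLR columns are accepted in the table but excluded from the
#' vote so the 10-tool denominator is preserved.  Unrecognized categorical
#' tokens count as failed and are reported once per token.
#'
#' @param variants a [variant_table()].
#' @param cfg a [cascade_config()].
#' @param predicates per-tool predicate list, see
#'   [default_tool_predicates()].
#' @return data frame with per-variant `fraction` and `pass`.
#' @export
deleteriousness_vote <- function(variants, cfg = cascade_config(),
                                 predicates = default_tool_predicates()) {
  n <- nrow(variants)
  tools <- names(predicates)
  passed <- matrix(FALSE, n, length(tools), dimnames = list(NULL, tools))
  avail <- passed
  unknown_tokens <- character(0)
  for (tool in tools) {
    col <- variants[[paste0("pred_", tool)]]
    pred <- predicates[[tool]]
    if (is.null(col)) next
    if (is.numeric(pred)) {
      vals <- suppressWarnings(as.numeric(col))
      avail[, tool] <- !is.na(vals)
      passed[, tool] <- !is.na(vals) & vals >= pred
    } else {
      toks <- toupper(trimws(as.character(col)))
      toks[toks %in% c(".", "", "NA")] <- NA_character_
      known <- is.na(toks) | toks %in% c(pred, "T", "N", "B", "L", "U")
      if (any(!known))
        unknown_tokens <- c(unknown_tokens,
                            paste0(tool, ":", unique(toks[!known])))
      avail[, tool] <- !is.na(toks)
      passed[, tool] <- !is.na(toks) & toks %in% pred
    }
  }
  if (length(unknown_tokens))
    message(sprintf("deleteriousness_vote: unrecognized prediction token(s) counted as fail: %s",
                    paste(unique(unknown_tokens), collapse = ", ")))
  denom <- if (cfg$denominator == "fixed")
    rep(length(tools), n) else rowSums(avail)
  frac <- ifelse(denom > 0, rowSums(passed) / denom, 0)
  data.frame(fraction = frac,
             pass = denom > 0 & frac >= cfg$deleteriousness_fraction)
}

#' Run the full coding cascade
#'
#' Stage order: region split (keep coding) -> synonymous exclusion ->
#' CADD threshold -> conservation vote -> intolerance vote ->
#' deleteriousness vote.  Every stage is recorded in a funnel report.
#' Survivors are ordered by CADD descending, then variant id.
#'
#' @param variants a [variant_table()] (typically already quality-, MAF-
#'   and segregation-filtered).
#' @param cfg a [cascade_config()].
#' @param funnel an existing [funnel_report()] to append to, or `NULL`
#'   to start a fresh one.
#' @return list with `survivors` (ordered [variant_table()] subset with
#'   appended vote columns `conservation_votes`, `intolerance_fraction`,
#'   `deleteriousness_fraction`) and `funnel` (a [funnel_report()]).
#' @export
run_coding_cascade <- function(variants, cfg = cascade_config(),
                               funnel = NULL) {
  stopifnot(inherits(cfg, "cascade_config"))
  funnel <- funnel %||% funnel_report()
  ids <- function(v) v$variant_id

  parts <- split_by_region(variants)
  coding <- parts$coding
  funnel <- funnel_add_stage(funnel, "coding_region", ids(variants), ids(coding))

  nonsyn <- exclude_synonymous(coding)
  funnel <- funnel_add_stage(funnel, "nonsynonymous", ids(coding), ids(nonsyn))

  cadd <- nonsyn$cadd_phred %||% rep(NA_real_, nrow(nonsyn))
  cadd_keep <- nonsyn[!is.na(cadd) & cadd >= cfg$cadd_min, , drop = FALSE]
  funnel <- funnel_add_stage(funnel, "cadd", ids(nonsyn), ids(cadd_keep))

  cons <- conservation_vote(cadd_keep, cfg)
  cons_keep <- cadd_keep[cons$pass, , drop = FALSE]
  cons_keep$conservation_votes <- cons$votes[cons$pass]
  funnel <- funnel_add_stage(funnel, "conservation", ids(cadd_keep), ids(cons_keep))

  intol <- intolerance_vote(cons_keep, cfg)
  intol_keep <- cons_keep[intol$pass, , drop = FALSE]
  intol_keep$intolerance_fraction <- intol$fraction[intol$pass]
  funnel <- funnel_add_stage(funnel, "intolerance", ids(cons_keep), ids(intol_keep))

  del <- deleteriousness_vote(intol_keep, cfg)
  survivors <- intol_keep[del$pass, , drop = FALSE]
  survivors$deleteriousness_fraction <- del$fraction[del$pass]
  funnel <- funnel_add_stage(funnel, "deleteriousness", ids(intol_keep),
                             ids(survivors))

  cadd_s <- survivors$cadd_phred
  ord <- order(-cadd_s, survivors$variant_id)
  survivors <- survivors[ord, , drop = FALSE]
  rownames(survivors) <- NULL
  list(survivors = survivors, funnel = funnel)
}
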