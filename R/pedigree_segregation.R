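# Pre-filters (call quality, rarity) and the pedigree segregation filter.

#' Call-quality filter
#'
#' A variant passes when its call quality is at least `min_qual`, its
#' coverage at least `min_depth`, SNVs have read support from both strands
#' (at least one forward and one reverse read carrying the alternate
#' allele), and indels carry the caller's `PASS` flag.  Missing quality or
#' depth fails with reason `missing_quality`.
#'
#' @param variants a [variant_table()].
#' @param min_qual minimum PHRED call quality (default 20).
#' @param min_depth minimum coverage (default 5).
#' @return logical vector, one element per variant, with a `reason`
#'   attribute giving the first failure reason per variant (`""` = pass).
#' @export
quality_filter <- function(variants, min_qual = 20, min_depth = 5) {
  assert_scalar_number(min_qual, "min_qual")
  assert_scalar_number(min_depth, "min_depth")
  n <- nrow(variants)
  qual <- variants$qual %||% rep(NA_real_, n)
  depth <- variants$depth %||% rep(NA_real_, n)
  fwd <- variants$fwd_reads %||% rep(NA_integer_, n)
  rev <- variants$rev_reads %||% rep(NA_integer_, n)
  filt <- variants$caller_filter %||% rep(NA_character_, n)
  is_snv <- variants$variant_class == "SNV"

  reason <- character(n)
  reason[is.na(qual) | is.na(depth)] <- "missing_quality"
  low_q <- reason == "" & qual < min_qual
  reason[low_q] <- "low_qual"
  low_d <- reason == "" & depth < min_depth
  reason[low_d] <- "low_depth"
  sb <- reason == "" & is_snv &
    (is.na(fwd) | is.na(rev) | fwd < 1L | rev < 1L)
  reason[sb] <- "strand_bias"
  cf <- reason == "" & !is_snv & (is.na(filt) | filt != "PASS")
  reason[cf] <- "caller_filter"

  structure(reason == "", reason = reason)
}

#' Minor-allele-frequency filter
#'
#' A variant is retained when its allele frequency is at most `max_af`
#' (inclusive) in *every* declared filtering population.  Missing
#' frequencies are treated as 0 (unobserved); a declared population with
#' no `af_` column is treated as all-zero with a warning.
#'
#' @param variants a [variant_table()].
#' @param populations character vector of population names (without the
#'   `af_` prefix); defaults to the table's declared filtering populations.
#' @param max_af maximum allele frequency, default 0.001 (0.1%).
#' @return logical vector, one element per variant.
#' @export
maf_filter <- function(variants, populations = NULL, max_af = 0.001) {
  assert_scalar_number(max_af, "max_af")
  if (max_af <= 0 || max_af >= 1)
    stop_famvar("max_af must be inside (0, 1)", class = "famvar_config_error")
  populations <- populations %||% attr(variants, "af_populations")
  if (is.null(populations) || !length(populations))
    stop_famvar("no filtering populations declared", class = "famvar_config_error")
  keep <- rep(TRUE, nrow(variants))
  for (p in populations) {
    col <- paste0("af_", p)
    if (is.null(variants[[col]])) {
      warning(sprintf("population '%s' has no af_ column; treated as AF = 0", p))
      next
    }
    af <- variants[[col]]
    af[is.na(af)] <- 0
    keep <- keep & af <= max_af
  }
  keep
}

#' Segregation rule
#'
#' Encodes the dominant-model segregation constraint: the candidate allele
#' must be present (het or hom-alt) in affected members and absent
#' (hom-ref) in healthy controls; possible carriers are unconstrained.
#'
#' @param require_in_cases `"all"` (default) or `"any"`: how many cases
#'   must carry the allele.
#' @param forbid_in_controls require controls to be hom-ref (default TRUE).
#' @param min_carrier_genotype `"het"` (default; het or hom-alt counts as
#'   carrying) or `"hom_alt"` (only hom-alt counts).
#' @param missing_case `"strict"` (default; a missing case genotype drops
#'   the variant with reason `missing_case_gt`) or `"permissive"` (missing
#'   case genotypes are ignored).
#' @return object of class `segregation_rule`.
#' @export
segregation_rule <- function(require_in_cases = c("all", "any"),
                             forbid_in_controls = TRUE,
                             min_carrier_genotype = c("het", "hom_alt"),
                             missing_case = c("strict", "permissive")) {
  structure(list(require_in_cases = match.arg(require_in_cases),
                 forbid_in_controls = isTRUE(forbid_in_controls),
                 min_carrier_genotype = match.arg(min_carrier_genotype),
                 missing_case = match.arg(missing_case)),
            class = "segregation_rule")
}

gt_matrix <- function(variants, samples) {
  cols <- paste0("gt_", samples)
  miss <- samples[!cols %in% names(variants)]
  if (length(miss))
    stop_famvar("pedigree sample(s) absent from genotype columns: %s",
                paste(miss, collapse = ", "), class = "famvar_config_error")
  m <- as.matrix(as.data.frame(variants)[, cols, drop = FALSE])
  colnames(m) <- samples
  m
}

#' Pedigree segregation filter
#'
#' Keeps variants whose genotype pattern is compatible with dominant
#' segregation of the disease in the pedigree: every case carries the
#' allele, every control is hom-ref, possible carriers are unconstrained.
#'
#' @param variants a [variant_table()].
#' @param pedigree a [pedigree_roles()] data frame.
#' @param rule a [segregation_rule()].
#' @return list with elements `kept` (the surviving subset of `variants`),
#'   `stage` (a funnel-stage record: name, n_in, n_out, surviving_ids) and
#'   `reason` (per-variant drop reason, `""` for survivors).
#' @export
segregation_filter <- function(variants, pedigree, rule = segregation_rule()) {
  stopifnot(inherits(pedigree, "pedigree_roles"))
  cases <- pedigree$sample_id[pedigree$role == "case"]
  controls <- pedigree$sample_id[pedigree$role == "control"]
  if (!length(cases) || !length(controls))
    stop_famvar("segregation filtering needs at least one case and one control",
                class = "famvar_config_error")
  carrier_lv <- if (rule$min_carrier_genotype == "het")
    c("het", "hom_alt") else "hom_alt"

  gcase <- gt_matrix(variants, cases)
  gctrl <- gt_matrix(variants, controls)

  case_missing <- rowSums(gcase == "missing") > 0L
  case_carrier <- gcase %in% carrier_lv
  dim(case_carrier) <- dim(gcase)
  if (rule$missing_case == "permissive") {
    # ignore missing case genotypes; a variant with all cases missing fails
    eff <- case_carrier | gcase == "missing"
    dim(eff) <- dim(gcase)
    case_ok <- if (rule$require_in_cases == "all")
      rowSums(eff) == ncol(gcase) & rowSums(case_carrier) >= 1L
    else rowSums(case_carrier) >= 1L
  } else {
    case_ok <- if (rule$require_in_cases == "all")
      rowSums(case_carrier) == ncol(gcase)
    else rowSums(case_carrier) >= 1L
    case_ok <- case_ok & !case_missing
  }
  ctrl_ok <- if (rule$forbid_in_controls)
    rowSums(gctrl == "hom_ref") == ncol(gctrl) else TRUE

  keep <- case_ok & ctrl_ok
  reason <- character(nrow(variants))
  reason[!ctrl_ok] <- "control_carries"
  reason[!case_ok] <- "case_pattern"
  if (rule$missing_case == "strict")
    reason[case_missing & !keep & ctrl_ok] <- "missing_case_gt"

  kept <- variants[keep, , drop = FALSE]
  stage <- list(name = "segregation",
                n_in = nrow(variants), n_out = nrow(kept),
                surviving_ids = kept$variant_id)
  list(kept = kept, stage = stage, reason = reason)
}

#' Pairwise relatedness from shared rare variants
#'
#' A light-weight sample-swap / relatedness check: for every pair of
#' samples the Jaccard index of their carrier sets (variants carried het
#' or hom-alt) over the supplied rare-variant table.
#'
#' @param variants a [variant_table()] of rare variants.
#' @param pedigree a [pedigree_roles()] data frame (defines sample order).
#' @return symmetric numeric matrix; the diagonal is 1 for samples
#'   carrying at least one variant.  Samples carrying none get 0 rows with
#'   a warning.
#' @export
relatedness_matrix <- function(variants, pedigree) {
  samples <- pedigree$sample_id
  if (length(samples) < 2L)
    stop_famvar("relatedness needs at least two samples",
                class = "famvar_config_error")
  g <- gt_matrix(variants, samples)
  carrier <- g == "het" | g == "hom_alt"
  counts <- colSums(carrier)
  if (any(counts == 0L))
    warning(sprintf("sample(s) carry no rare variants: %s",
                    paste(samples[counts == 0L], collapse = ", ")))
  inter <- crossprod(carrier)               # |A n B|
  uni <- outer(counts, counts, "+") - inter # |A u B|
  m <- ifelse(uni > 0, inter / uni, 0)
  dimnames(m) <- list(samples, samples)
  m
}
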