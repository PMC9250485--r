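# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Enumerations used throughout the variant table.
REGION_CLASSES <- c("exonic", "splicing", "UTR5", "UTR3", "upstream",
                    "downstream", "intronic", "intergenic", "ncRNA")
CODING_REGIONS   <- c("exonic", "splicing")
NEARGENE_REGIONS <- c("UTR5", "UTR3", "upstream", "downstream")
DISCARD_REGIONS  <- c("intronic", "intergenic", "ncRNA")

EXONIC_EFFECTS <- c("synonymous", "missense", "stopgain", "stoploss",
                    "frameshift", "nonframeshift", "unknown")

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

# The ten ensemble deleteriousness predictors that enter the default vote.
TOOL_SET <- c("SIFT", "PP2_HumDiv", "PP2_HumVar", "LRT", "MutationTaster",
              "MutationAssessor", "FATHMM", "ReliabilityIndex", "VEST3",
              "PROVEAN")
# Recognized but excluded from the default 10-tool vote.
EXTRA_TOOLS <- c("MetaSVM", "MetaLR")

CHROMHMM_STATES <- c("TssA", "TssAFInk", "TxFlnk", "Tx", "TxWk", "EnhG",
                     "Enh", "ZNF/Rpts", "Het", "TssBiv", "BivFlnk",
                     "EnhBiv", "ReprPC", "ReprPCWk", "Quies")

stop_famvar <- function(fmt, ..., class = "famvar_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "famvar_error")))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_famvar("'%s' must be a single non-missing number", name,
                class = "famvar_config_error")
  invisible(x)
}

# Parse numeric annotation cells; "." / "" / "NA" are the missing-data
# conventions of upstream annotators.  Returns list(values, n_bad) where
# n_bad counts cells that were neither numeric nor a missing token.
parse_score_column <- function(x) {
  x <- as.character(x)
  miss <- is.na(x) | x %in% c(".", "", "NA", "na")
  vals <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(vals)
  list(values = ifelse(miss | bad, NA_real_, vals), n_bad = sum(bad))
}

# Reverse complement of a plain character DNA string (IUPAC ACGTN only).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
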