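# Readers and writers for every external format the pipeline touches.
# All coordinate conversions happen here: intervals are 0-based half-open
# internally (BED-native) and 1-based inclusive in user-facing output.

#' Normalize genotype call tokens
#'
#' Accepts VCF-style (`0/0`, `0/1`, `1/1`, `./.`, phased `|` variants) and
#' word aliases (`ref`, `het`, `hom`, `hom_alt`, `missing`) as produced by
#' different annotator dialects, and maps them to the canonical levels
#' `hom_ref`, `het`, `hom_alt`, `missing`.
#'
#' @param x character vector of genotype tokens.
#' @return character vector over the canonical genotype levels.
#'   Unrecognized tokens become `missing` with a warning.
#' @examples
#' normalize_genotype(c("0/1", "1|1", "ref", "./."))
#' @export
normalize_genotype <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  x0 <- gsub("|", "/", x0, fixed = TRUE)
  map <- c("0/0" = "hom_ref", "0" = "hom_ref", "ref" = "hom_ref",
           "hom_ref" = "hom_ref", "wt" = "hom_ref",
           "0/1" = "het", "1/0" = "het", "het" = "het",
           "1/1" = "hom_alt", "hom" = "hom_alt", "hom_alt" = "hom_alt",
           "alt" = "hom_alt", "1" = "hom_alt",
           "./." = "missing", "." = "missing",
           "na" = "missing", "missing" = "missing")
  out <- unname(map[x0])
  out[is.na(x0) | x0 == ""] <- "missing"
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sprintf("unrecognized genotype token(s) treated as missing: %s",
                    paste(unique(x0[unknown]), collapse = ", ")))
    out[unknown] <- "missing"
  }
  out
}

classify_variant <- function(ref, alt) {
  ifelse(nchar(alt) > nchar(ref), "insertion",
         ifelse(nchar(alt) < nchar(ref), "deletion", "SNV"))
}

#' Construct a validated annotated variant table
#'
#' The central container of the pipeline: a data frame with one row per
#' variant.  Core columns are `chrom`, `pos` (1-based), `ref`, `alt`;
#' per-sample genotypes live in `gt_<sample>` columns, per-population
#' allele frequencies in `af_<population>` columns, and per-tool
#' deleteriousness predictions in `pred_<tool>` columns.  Recognized score
#' columns: `cadd_phred`, `gerp`, `phastcons`, `phylop`, `intol_local`,
#' `intol_esp6500`, `intol_exac`, `exac_z`, `exac_pli`, `snap2_effect`,
#' `snap2_accuracy`.  A `variant_id` of the form `chrom_pos_ref_alt` and a
#' `variant_class` (SNV/insertion/deletion) are derived when absent.
#'
#' @param df data frame holding at least `chrom`, `pos`, `ref`, `alt` and
#'   one `gt_` column.
#' @param af_populations character vector naming the populations (without
#'   the `af_` prefix) used for allele-frequency *filtering*.  Defaults to
#'   every `af_` column except gnomAD-derived ones, which are treated as
#'   report-only context.
#' @return the validated data frame with class `variant_table` and
#'   attributes `samples` and `af_populations`.
#' @seealso [read_variant_table()] to build one from a TSV file.
#' @export
variant_table <- function(df, af_populations = NULL) {
  required <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_famvar("variant table is missing required column(s): %s",
                paste(miss, collapse = ", "), class = "famvar_format_error")
  gt_cols <- grep("^gt_", names(df), value = TRUE)
  if (!length(gt_cols))
    stop_famvar("variant table needs at least one genotype column (gt_<sample>)",
                class = "famvar_format_error")

  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (anyNA(df$pos) || any(df$pos < 1L))
    stop_famvar("column 'pos' must be a positive 1-based integer",
                class = "famvar_format_error")
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  if (any(df$ref == df$alt))
    stop_famvar("ref and alt alleles must differ (rows: %s)",
                paste(which(df$ref == df$alt), collapse = ", "),
                class = "famvar_format_error")

  if (is.null(df$variant_id))
    df$variant_id <- paste(df$chrom, df$pos, df$ref, df$alt, sep = "_")
  dup <- unique(df$variant_id[duplicated(df$variant_id)])
  if (length(dup))
    stop_famvar("duplicate variant_id(s): %s", paste(dup, collapse = ", "),
                class = "famvar_format_error")
  df$variant_class <- classify_variant(df$ref, df$alt)

  for (g in gt_cols) df[[g]] <- normalize_genotype(df[[g]])

  af_cols <- grep("^af_", names(df), value = TRUE)
  for (a in af_cols) {
    df[[a]] <- parse_score_column(df[[a]])$values
    bad <- !is.na(df[[a]]) & (df[[a]] < 0 | df[[a]] > 1)
    if (any(bad))
      stop_famvar("allele frequencies in '%s' outside [0,1] (rows: %s)",
                  a, paste(which(bad), collapse = ", "),
                  class = "famvar_format_error")
  }
  if (is.null(af_populations)) {
    af_populations <- setdiff(sub("^af_", "", af_cols),
                              grep("gnomad", sub("^af_", "", af_cols),
                                   value = TRUE))
  }

  rownames(df) <- NULL
  structure(df,
            samples = sub("^gt_", "", gt_cols),
            af_populations = af_populations,
            class = c("variant_table", "data.frame"))
}

#' Read an annotated variant table from TSV
#'
#' Parses the tab-separated variant table produced upstream by
#' ANNOVAR/dbNSFP-style annotators.  Unparseable score cells become
#' missing values; their count is reported via a message.  Row order is
#' preserved.
#'
#' @inheritParams variant_table
#' @param path path to a tab-separated file with a header line.
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path, af_populations = NULL) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  score_cols <- intersect(
    c("qual", "depth", "fwd_reads", "rev_reads",
      "cadd_phred", "gerp", "phastcons", "phylop",
      "intol_local", "intol_esp6500", "intol_exac", "exac_z", "exac_pli",
      "snap2_effect", "snap2_accuracy",
      "pred_ReliabilityIndex", "pred_VEST3"),
    names(raw))
  n_bad <- 0L
  for (sc in score_cols) {
    parsed <- parse_score_column(raw[[sc]])
    raw[[sc]] <- parsed$values
    n_bad <- n_bad + parsed$n_bad
  }
  if (n_bad > 0L)
    message(sprintf("read_variant_table: %d unparseable score cell(s) set to missing",
                    n_bad))
  # "." is the missing token for categorical annotation columns too
  cat_cols <- c("gene", "region_class", "exonic_effect", "caller_filter",
                grep("^pred_", names(raw), value = TRUE))
  for (cc in intersect(cat_cols, names(raw))) {
    if (!is.character(raw[[cc]])) next
    raw[[cc]][raw[[cc]] %in% c(".", "")] <- NA_character_
  }
  for (int_col in intersect(c("depth", "fwd_reads", "rev_reads"), names(raw)))
    raw[[int_col]] <- as.integer(raw[[int_col]])
  for (chr_col in intersect(c("pred_SIFT", "pred_PP2_HumDiv"), character(0)))
    raw[[chr_col]] <- as.character(raw[[chr_col]])  # already character
  variant_table(raw, af_populations = af_populations)
}

#' Write a variant table to TSV
#'
#' Inverse of [read_variant_table()]: genotypes are serialized as VCF-style
#' tokens (`0/0`, `0/1`, `1/1`, `./.`) and missing values as `.`, so a
#' write/read round trip reproduces the in-memory object.
#'
#' @param x a [variant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  out <- as.data.frame(x)
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  for (g in grep("^gt_", names(out), value = TRUE))
    out[[g]] <- unname(gt_map[out[[g]]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

default_role_aliases <- function() {
  list(case = c("case", "affected", "cancer"),
       control = c("control", "unaffected", "healthy"),
       possible_carrier = c("possible_carrier", "possible-carrier",
                            "carrier", "polyps"),
       unknown = c("unknown", "0", "."))
}

#' Read a pedigree/roles file
#'
#' PED-like whitespace-separated table with seven columns: family id,
#' sample id, father id, mother id, sex, phenotype, and a role column.
#' Roles drive the segregation filter: `case` samples must carry the
#' candidate allele, `control` samples must not, `possible_carrier`
#' samples (e.g. a young descendant with pre-malignant findings) are
#' unconstrained.
#'
#' @param path path to the pedigree file (lines starting with `#` are
#'   skipped; an optional header line is detected).
#' @param role_aliases named list mapping each canonical role to the
#'   tokens that should be read as that role.
#' @return a data frame of class `pedigree_roles`.
#' @export
read_pedigree <- function(path, role_aliases = default_role_aliases()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) && grepl("sample_id", lines[1], fixed = TRUE))
    lines <- lines[-1]
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncol_seen <- unique(lengths(fields))
  if (length(lines) == 0L || !identical(ncol_seen, 7L))
    stop_famvar("pedigree file must have exactly 7 whitespace-separated columns (family, sample, father, mother, sex, phenotype, role)",
                class = "famvar_format_error")
  m <- do.call(rbind, fields)
  df <- data.frame(family_id = m[, 1], sample_id = m[, 2],
                   father_id = m[, 3], mother_id = m[, 4],
                   sex = m[, 5], phenotype = m[, 6],
                   role = tolower(m[, 7]), stringsAsFactors = FALSE)
  pedigree_roles(df, role_aliases = role_aliases)
}

#' @rdname read_pedigree
#' @param df data frame with at least `sample_id` and `role` columns.
#' @export
pedigree_roles <- function(df, role_aliases = default_role_aliases()) {
  stopifnot(all(c("sample_id", "role") %in% names(df)))
  if (anyDuplicated(df$sample_id))
    stop_famvar("duplicate sample_id(s) in pedigree: %s",
                paste(unique(df$sample_id[duplicated(df$sample_id)]),
                      collapse = ", "),
                class = "famvar_format_error")
  alias2role <- unlist(lapply(names(role_aliases), function(r)
    stats::setNames(rep(r, length(role_aliases[[r]])), role_aliases[[r]])))
  role <- unname(alias2role[tolower(df$role)])
  unk <- is.na(role)
  if (any(unk)) {
    warning(sprintf("unknown role token(s) mapped to 'unknown': %s",
                    paste(unique(df$role[unk]), collapse = ", ")))
    role[unk] <- "unknown"
  }
  df$role <- role
  if (!any(role == "case") || !any(role == "control"))
    stop_famvar("pedigree must contain at least one case and one control (segregation undefined otherwise)",
                class = "famvar_config_error")
  rownames(df) <- NULL
  structure(df, class = c("pedigree_roles", "data.frame"))
}

#' Write a pedigree/roles file
#' @param ped a `pedigree_roles` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  cols <- c("family_id", "sample_id", "father_id", "mother_id",
            "sex", "phenotype", "role")
  for (cl in setdiff(cols, names(ped))) ped[[cl]] <- "0"
  utils::write.table(ped[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a set of genomic intervals (0-based half-open)
#'
#' Internal interval representation is BED-native: `start` is 0-based,
#' `end` is exclusive, so an interval covers 1-based positions
#' `start+1 .. end`.
#'
#' @param chrom,start,end,name,strand interval fields; `strand` is one of
#'   `+`, `-`, `.`.
#' @return data frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end,
                              name = paste0(chrom, ":", start, "-", end),
                              strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  strand <- rep(strand, length.out = length(start))
  name <- rep(as.character(name), length.out = length(start))
  bad <- which(!(start >= 0L & start < end))
  if (length(bad))
    stop_famvar("invalid interval(s) (need 0 <= start < end) at row(s): %s",
                paste(bad, collapse = ", "), class = "famvar_format_error")
  if (!all(strand %in% c("+", "-", ".")))
    stop_famvar("strand must be one of +, -, .", class = "famvar_format_error")
  structure(data.frame(chrom = as.character(chrom), start = start,
                       end = end, name = as.character(name),
                       strand = strand, stringsAsFactors = FALSE),
            class = c("genomic_intervals", "data.frame"))
}

#' Read a BED file of regulatory elements
#'
#' Coordinates are kept 0-based half-open internally; use
#' [intervals_1based()] for display.
#'
#' @param path path to a BED file (3+ columns; `track`/`browser`/comment
#'   lines are skipped).
#' @return a [genomic_intervals()] data frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(genomic_intervals(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L))
    stop_famvar("BED line %d has fewer than 3 fields",
                lineno[which(lengths(fields) < 3L)[1]],
                class = "famvar_format_error")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0L)
  if (length(bad))
    stop_famvar("BED line %d: invalid interval (need 0 <= start < end)",
                lineno[bad[1]], class = "famvar_format_error")
  name <- vapply(seq_along(fields), function(i)
    if (length(fields[[i]]) >= 4L) fields[[i]][[4L]] else
      paste0(chrom[i], ":", start[i], "-", end[i]), "")
  strand <- vapply(seq_along(fields), function(i)
    if (length(fields[[i]]) >= 6L) fields[[i]][[6L]] else ".", "")
  strand[!strand %in% c("+", "-")] <- "."
  genomic_intervals(chrom, start, end, name, strand)
}

#' Convert internal intervals to 1-based inclusive coordinates
#' @param x a [genomic_intervals()] data frame.
#' @return data frame with `start1` and `end1` columns (1-based inclusive).
#' @export
intervals_1based <- function(x) {
  data.frame(chrom = x$chrom, start1 = x$start + 1L, end1 = x$end,
             name = x$name, strand = x$strand, stringsAsFactors = FALSE)
}

#' Read sequences from a FASTA file
#'
#' @param path path to a (DNA or protein) FASTA file.
#' @return named character vector of uppercased sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0L))
    stop_famvar("FASTA record(s) of length 0: %s",
                paste(names(set)[Biostrings::width(set) == 0L], collapse = ", "),
                class = "famvar_format_error")
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  out <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts the JASPAR 2020 text dialect: a `>MA0137.2 STAT1` header
#' followed by four count rows, either bracketed (`A [ 0 3 79 ... ]`) or
#' bare whitespace-separated numbers in A, C, G, T order.
#'
#' @param path path to a JASPAR text file containing one or more matrices.
#' @return list of `pfm_record` objects, each with `matrix_id`,
#'   `tf_name` and a 4 x L `counts` matrix with rows A, C, G, T.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr))
    stop_famvar("no JASPAR headers ('>') found in %s", path,
                class = "famvar_format_error")
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    header <- sub("^>\\s*", "", lines[hdr[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    matrix_id <- toks[1]
    tf_name <- if (length(toks) > 1L) paste(toks[-1], collapse = " ") else toks[1]
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    if (length(body) != 4L)
      stop_famvar("matrix %s: expected 4 count rows, found %d",
                  matrix_id, length(body), class = "famvar_format_error")
    rows <- lapply(body, function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals))
        stop_famvar("matrix %s: non-numeric count row", matrix_id,
                    class = "famvar_format_error")
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      stop_famvar("matrix %s: ragged count rows (lengths %s)",
                  matrix_id, paste(lengths(rows), collapse = ", "),
                  class = "famvar_format_error")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[i]] <- pfm_record(matrix_id, tf_name, counts)
  }
  out
}

#' Construct a position frequency matrix record
#' @param matrix_id matrix accession, e.g. `MA0137.2`.
#' @param tf_name transcription factor name, e.g. `STAT1`.
#' @param counts 4 x L non-negative count matrix with rows A, C, G, T.
#' @return object of class `pfm_record`.
#' @export
pfm_record <- function(matrix_id, tf_name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    stop_famvar("PFM counts must be a 4 x L matrix with L >= 1",
                class = "famvar_format_error")
  if (any(counts < 0))
    stop_famvar("PFM counts must be non-negative", class = "famvar_format_error")
  if (any(colSums(counts) == 0))
    stop_famvar("PFM %s has an all-zero column", matrix_id,
                class = "famvar_format_error")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(matrix_id = matrix_id, tf_name = tf_name, counts = counts),
            class = "pfm_record")
}

#' Write PFM records in JASPAR text format
#' @param pfms list of `pfm_record` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pfms) {
    cat(sprintf(">%s %s\n", p$matrix_id, p$tf_name), file = con)
    for (b in c("A", "C", "G", "T"))
      cat(sprintf("%s [ %s ]\n", b,
                  paste(format(p$counts[b, ], trim = TRUE), collapse = " ")),
          file = con)
  }
  invisible(path)
}

#' Read a TFBS hit table
#'
#' Tab-separated hit list with columns `tf_name`, `targeting` (WT/MUT/BOTH),
#' `matrix_id`, `rel_score`, `start`, `end`, `strand`, `site_seq`.
#'
#' @param path path to the TSV file.
#' @return data frame of hits.
#' @export
read_tfbs_hits <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  required <- c("tf_name", "matrix_id", "rel_score", "start", "end", "strand")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_famvar("TFBS hit table missing column(s): %s",
                paste(miss, collapse = ", "), class = "famvar_format_error")
  df
}
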