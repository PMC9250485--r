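# The non-coding arm: regulatory-element intersection, chromatin-state
# annotation join, PWM scanning of wild-type vs mutant sequence, and
# differential TFBS calling.

#' Build a position weight matrix from a PFM
#'
#' Counts are converted to probabilities with a pseudocount distributed
#' by the background composition (`p = (count + pc * bg) / (N + pc)`,
#' the JASPAR convention), then to base-2 log-odds against the
#' background.  Per-column minima/maxima give the score range used for
#' min-max relative scoring.
#'
#' @param pfm a [pfm_record()].
#' @param pseudocount total pseudocount per column (default 0.8).
#' @param background length-4 base composition for A, C, G, T (default
#'   uniform 0.25).
#' @return object of class `pwm` with fields `log_odds` (4 x L),
#'   `col_min`, `col_max`, `score_min`, `score_max`.
#' @export
build_pwm <- function(pfm, pseudocount = 0.8,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(pfm, "pfm_record"))
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop_famvar("background must be 4 positive frequencies summing to 1",
                class = "famvar_config_error")
  if (pseudocount <= 0)
    stop_famvar("pseudocount must be positive", class = "famvar_config_error")
  counts <- pfm$counts
  N <- colSums(counts)
  probs <- sweep(counts + pseudocount * background, 2, N + pseudocount, "/")
  log_odds <- log2(probs / background)
  col_min <- apply(log_odds, 2, min)
  col_max <- apply(log_odds, 2, max)
  if (!all(is.finite(log_odds)) || sum(col_min) >= sum(col_max))
    stop_famvar("degenerate PWM: log-odds not finite or zero score range")
  structure(list(matrix_id = pfm$matrix_id, tf_name = pfm$tf_name,
                 counts = counts, log_odds = log_odds,
                 col_min = col_min, col_max = col_max,
                 score_min = sum(col_min), score_max = sum(col_max),
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' Consensus (maximum-likelihood) sequence of a PWM
#' @param pwm a [build_pwm()] object.
#' @return character string over A, C, G, T.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$log_odds)[apply(pwm$log_odds, 2, which.max)],
        collapse = "")
}

empty_hits <- function() {
  data.frame(matrix_id = character(0), tf_name = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             rel_score = numeric(0), site_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Every window of motif length on both strands is scored as the sum of
#' per-position log-odds; the relative score is the min-max normalization
#' `(S - score_min) / (score_max - score_min)` over the motif's possible
#' score range.  A hit is emitted when the relative score reaches the
#' threshold (default 80%, the standard JASPAR profile threshold).
#' Windows containing non-ACGT letters are skipped.  Minus-strand windows
#' are scored on the reverse complement and reported in plus-strand
#' window coordinates, with `site_seq` giving the matched (minus-strand)
#' sequence.
#'
#' @param seq character DNA sequence.
#' @param pwm a [build_pwm()] object.
#' @param threshold relative-score threshold in (0, 1], default 0.8.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data frame of hits with 1-based inclusive `start`/`end`
#'   within `seq`, `strand`, `rel_score` and `site_seq`.
#' @export
pwm_scan <- function(seq, pwm, threshold = 0.8, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1)
    stop_famvar("threshold must lie in (0, 1]", class = "famvar_config_error")
  seq <- toupper(seq)
  L <- ncol(pwm$log_odds)
  n <- nchar(seq)
  if (n < L) return(empty_hits())
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  rng <- pwm$score_max - pwm$score_min

  hits <- empty_hits()
  for (o in seq_len(n - L + 1L)) {
    w <- idx[o:(o + L - 1L)]
    if (anyNA(w)) next
    s_plus <- sum(pwm$log_odds[cbind(w, seq_len(L))])
    rel_plus <- (s_plus - pwm$score_min) / rng
    if (rel_plus >= threshold) {
      hits <- rbind(hits, data.frame(
        matrix_id = pwm$matrix_id, tf_name = pwm$tf_name,
        start = o, end = o + L - 1L, strand = "+",
        rel_score = rel_plus,
        site_seq = substr(seq, o, o + L - 1L), stringsAsFactors = FALSE))
    }
    if (both_strands) {
      w_rc <- rev(5L - w)
      s_minus <- sum(pwm$log_odds[cbind(w_rc, seq_len(L))])
      rel_minus <- (s_minus - pwm$score_min) / rng
      if (rel_minus >= threshold) {
        hits <- rbind(hits, data.frame(
          matrix_id = pwm$matrix_id, tf_name = pwm$tf_name,
          start = o, end = o + L - 1L, strand = "-",
          rel_score = rel_minus,
          site_seq = revcomp(substr(seq, o, o + L - 1L)),
          stringsAsFactors = FALSE))
      }
    }
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Substitute a variant allele into a wild-type window
#'
#' @param wt wild-type sequence of the window.
#' @param window_start 1-based genomic position of the first base of `wt`.
#' @param variant single-row [variant_table()] (or list) with `pos`,
#'   `ref`, `alt`; must be an SNV inside the window.
#' @return the mutant sequence (same length as `wt`).  Errors when the
#'   window base at the variant offset does not equal `ref`, guarding
#'   against build or strand mix-ups.
#' @export
build_mutant_sequence <- function(wt, window_start, variant) {
  pos <- as.integer(variant$pos); ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop_famvar("only SNVs can be substituted into a window")
  off <- pos - as.integer(window_start) + 1L
  if (off < 1L || off > nchar(wt))
    stop_famvar("variant position %d outside window [%d, %d]",
                pos, window_start, window_start + nchar(wt) - 1L)
  observed <- substr(wt, off, off)
  if (observed != ref)
    stop_famvar("reference mismatch at window offset %d: expected %s, observed %s",
                off, ref, observed)
  substr(wt, off, off) <- alt
  wt
}

#' Annotate a variant with regulatory-element overlaps and chromatin state
#'
#' Intersects the variant position with the supplied interval tracks
#' (promoters, enhancers, super-enhancers, ...) and joins the precomputed
#' chromatin-state annotation row (ChromHMM state and score, Segway
#' label, TFBS counts) for the variant if present in `state_table`.
#'
#' @param variant single-row [variant_table()] (or list with `chrom`,
#'   `pos`, `variant_id`).
#' @param tracks named list of [genomic_intervals()] tracks.
#' @param state_table optional data frame keyed by `variant_id` with
#'   columns among `chromhmm_state`, `chromhmm_score`, `segway_label`,
#'   `tfbs_count`, `tfbs_peak_count`.
#' @return list of class `regulatory_annotation`: chromatin fields plus
#'   `overlapping_elements` (a [genomic_intervals()] data frame with a
#'   `track` column).
#' @export
annotate_regulatory <- function(variant, tracks = list(), state_table = NULL) {
  chrom <- as.character(variant$chrom); pos <- as.integer(variant$pos)
  vr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  track_chroms <- unique(unlist(lapply(tracks, function(t) t$chrom)))
  if (length(tracks) && length(track_chroms) && !chrom %in% track_chroms)
    warning(sprintf("variant chromosome '%s' absent from all tracks (tracks use: %s)",
                    chrom, paste(track_chroms, collapse = ", ")))
  ov_list <- lapply(names(tracks), function(tn) {
    t <- tracks[[tn]]
    t <- t[t$chrom == chrom, , drop = FALSE]
    if (!nrow(t)) return(NULL)
    gr <- GenomicRanges::GRanges(t$chrom,
                                 IRanges::IRanges(t$start + 1L, t$end))
    hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, vr))
    if (!length(hit)) return(NULL)
    cbind(t[hit, , drop = FALSE], track = tn, stringsAsFactors = FALSE)
  })
  ov <- do.call(rbind, ov_list)
  if (is.null(ov))
    ov <- cbind(genomic_intervals(character(0), integer(0), integer(0)),
                track = character(0))

  ann <- list(chromhmm_state = NA_character_, chromhmm_score = NA_real_,
              segway_label = NA_character_, tfbs_count = NA_integer_,
              tfbs_peak_count = NA_integer_)
  if (!is.null(state_table) && !is.null(variant$variant_id)) {
    row <- state_table[state_table$variant_id == variant$variant_id, , drop = FALSE]
    if (nrow(row) == 1L) {
      for (f in names(ann))
        if (!is.null(row[[f]])) ann[[f]] <- row[[f]][1]
      if (!is.na(ann$chromhmm_score) &&
          (ann$chromhmm_score < 0 || ann$chromhmm_score > 1))
        stop_famvar("chromhmm_score must lie in [0, 1]",
                    class = "famvar_format_error")
      if (!is.na(ann$chromhmm_state) &&
          !ann$chromhmm_state %in% CHROMHMM_STATES)
        stop_famvar("unknown ChromHMM state '%s'", ann$chromhmm_state,
                    class = "famvar_format_error")
    }
  }
  ann$overlapping_elements <- ov
  structure(ann, class = "regulatory_annotation")
}

#' Differential TFBS call between wild-type and mutant hit lists
#'
#' Groups hits by transcription factor name (a TF whose matrices hit both
#' sequences is shared, even through different matrices) and partitions
#' the TF universe into wild-type-only (binding disrupted by the
#' variant), mutant-only (binding created) and shared.
#'
#' @param hits_wt,hits_mut hit data frames from [pwm_scan()] (or any data
#'   frame with a `tf_name` column), both obtained from the same window
#'   and threshold.
#' @return object of class `differential_tfbs` with sorted character
#'   vectors `wt_only`, `mut_only`, `shared` plus the input hit lists.
#' @export
differential_tfbs <- function(hits_wt, hits_mut) {
  wt_tfs <- unique(as.character(hits_wt$tf_name))
  mut_tfs <- unique(as.character(hits_mut$tf_name))
  structure(list(wt_only = sort(setdiff(wt_tfs, mut_tfs)),
                 mut_only = sort(setdiff(mut_tfs, wt_tfs)),
                 shared = sort(intersect(wt_tfs, mut_tfs)),
                 hits_wt = hits_wt, hits_mut = hits_mut),
            class = "differential_tfbs")
}

#' @export
print.differential_tfbs <- function(x, ...) {
  cat(sprintf("Differential TFBS: %d WT-only, %d MUT-only, %d shared\n",
              length(x$wt_only), length(x$mut_only), length(x$shared)))
  if (length(x$wt_only))
    cat("  disrupted (WT-only):", paste(x$wt_only, collapse = ", "), "\n")
  if (length(x$mut_only))
    cat("  created  (MUT-only):", paste(x$mut_only, collapse = ", "), "\n")
  invisible(x)
}

#' Non-coding arm configuration
#'
#' @param threshold PWM relative-score threshold (default 0.8).
#' @param cadd_min CADD flag threshold (default 10).
#' @param window_flank half-width of the scanned window around the
#'   variant, in bp (default 60).
#' @param overlap_variant_only when TRUE, only hits whose window covers
#'   the variant position enter the differential comparison.
#' @param pseudocount,background passed to [build_pwm()].
#' @return object of class `noncoding_config`.
#' @export
noncoding_config <- function(threshold = 0.8, cadd_min = 10,
                             window_flank = 60,
                             overlap_variant_only = FALSE,
                             pseudocount = 0.8,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1)
    stop_famvar("threshold must lie in (0, 1]", class = "famvar_config_error")
  structure(list(threshold = threshold, cadd_min = cadd_min,
                 window_flank = as.integer(window_flank),
                 overlap_variant_only = isTRUE(overlap_variant_only),
                 pseudocount = pseudocount, background = background),
            class = "noncoding_config")
}

#' Run the non-coding (regulatory) arm
#'
#' For every near-gene variant: regulatory-element intersection and
#' chromatin-state join, a CADD >= `cadd_min` flag, and -- when a
#' covering sequence window is available -- wild-type vs mutant PWM
#' scanning with a differential TFBS call.
#'
#' @param near_gene a [variant_table()] subset (the near-gene arm from
#'   [split_by_region()]).
#' @param tracks named list of [genomic_intervals()] regulatory tracks.
#' @param state_table optional chromatin-state annotation table, see
#'   [annotate_regulatory()].
#' @param sequences list of sequence windows, each a list with `name`,
#'   `seq`, `chrom` and `start` (1-based genomic position of the first
#'   base).
#' @param pfms list of [pfm_record()] objects to scan with.
#' @param cfg a [noncoding_config()].
#' @return object of class `noncoding_report`: per-variant results
#'   (`variants`, a list with annotation, `cadd_flag` and
#'   `differential`) and a combined exclusive-hit table (`table`) with
#'   columns tf_name, targeting, matrix_id, rel_score, start, end,
#'   strand, site_seq, genomic_start, genomic_end.
#' @export
run_noncoding <- function(near_gene, tracks = list(), state_table = NULL,
                          sequences = list(), pfms = list(),
                          cfg = noncoding_config()) {
  stopifnot(inherits(cfg, "noncoding_config"))
  pwms <- lapply(pfms, build_pwm, pseudocount = cfg$pseudocount,
                 background = cfg$background)
  results <- list()
  tab_rows <- list()
  for (i in seq_len(nrow(near_gene))) {
    v <- near_gene[i, , drop = FALSE]
    ann <- annotate_regulatory(v, tracks, state_table)
    cadd <- v$cadd_phred %||% NA_real_
    res <- list(variant_id = v$variant_id,
                annotation = ann,
                cadd_flag = !is.na(cadd) && cadd >= cfg$cadd_min,
                differential = NULL)
    covering <- Filter(function(s) {
      s$chrom == v$chrom && v$pos >= s$start &&
        v$pos <= s$start + nchar(s$seq) - 1L
    }, sequences)
    if (length(pwms) && length(covering)) {
      s <- covering[[1]]
      w0 <- max(s$start, v$pos - cfg$window_flank)
      w1 <- min(s$start + nchar(s$seq) - 1L, v$pos + cfg$window_flank)
      wt <- substr(s$seq, w0 - s$start + 1L, w1 - s$start + 1L)
      mut <- build_mutant_sequence(wt, w0, v)
      scan_all <- function(x) {
        do.call(rbind, c(list(empty_hits()),
                         lapply(pwms, function(p)
                           pwm_scan(x, p, threshold = cfg$threshold))))
      }
      hw <- scan_all(wt); hm <- scan_all(mut)
      if (cfg$overlap_variant_only) {
        voff <- v$pos - w0 + 1L
        hw <- hw[hw$start <= voff & hw$end >= voff, , drop = FALSE]
        hm <- hm[hm$start <= voff & hm$end >= voff, , drop = FALSE]
      }
      diffres <- differential_tfbs(hw, hm)
      res$differential <- diffres
      res$window_start <- w0
      tag <- function(df, label) {
        if (is.null(df) || !nrow(df)) return(NULL)
        cbind(df, targeting = label, stringsAsFactors = FALSE)
      }
      excl <- rbind(tag(hw[hw$tf_name %in% diffres$wt_only, , drop = FALSE], "WT"),
                    tag(hm[hm$tf_name %in% diffres$mut_only, , drop = FALSE], "MUT"))
      if (!is.null(excl) && nrow(excl)) {
        excl$genomic_start <- w0 + excl$start - 1L
        excl$genomic_end <- w0 + excl$end - 1L
        excl$variant_id <- v$variant_id
        tab_rows[[length(tab_rows) + 1L]] <- excl
      }
    } else if (length(pwms)) {
      warning(sprintf("variant %s has no covering sequence window; TFBS comparison skipped",
                      v$variant_id))
    }
    results[[v$variant_id]] <- res
  }
  tab <- if (length(tab_rows)) do.call(rbind, tab_rows) else
    cbind(empty_hits(), targeting = character(0),
          genomic_start = integer(0), genomic_end = integer(0),
          variant_id = character(0))
  cols <- c("variant_id", "tf_name", "targeting", "matrix_id", "rel_score",
            "start", "end", "strand", "site_seq", "genomic_start",
            "genomic_end")
  tab <- tab[, cols, drop = FALSE]
  rownames(tab) <- NULL
  structure(list(variants = results, table = tab), class = "noncoding_report")
}
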