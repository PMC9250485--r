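# In-code fixtures and independent brute-force oracles used across the
# suite.  Oracles are deliberately naive (loops, enumeration) and do not
# share code paths with the implementation they check.

# Minimal in-memory variant table with two samples.
tiny_variant_df <- function() {
  data.frame(chrom = c("12", "9"), pos = c(129285482L, 132501952L),
             ref = c("T", "C"), alt = c("C", "T"),
             region_class = c("exonic", "exonic"),
             exonic_effect = c("missense", "missense"),
             qual = c(60, 60), depth = c(40L, 40L),
             fwd_reads = c(20L, 20L), rev_reads = c(20L, 20L),
             caller_filter = "PASS",
             gt_a = c("0/1", "0/1"), gt_b = c("0/0", "0/1"),
             af_eur = c(0, 1e-4),
             cadd_phred = c(23.7, 34),
             stringsAsFactors = FALSE)
}

# Brute-force dominant-segregation predicate: explicit per-variant,
# per-sample loops over the genotype columns.
brute_force_segregation <- function(variants, pedigree) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    ok <- TRUE
    for (j in seq_len(nrow(pedigree))) {
      gt <- variants[[paste0("gt_", pedigree$sample_id[j])]][i]
      role <- pedigree$role[j]
      if (role == "case" && !(gt %in% c("het", "hom_alt"))) ok <- FALSE
      if (role == "control" && gt != "hom_ref") ok <- FALSE
    }
    keep[i] <- ok
  }
  keep
}

# Independent PWM hit enumeration: recomputes the log-odds matrix from
# counts and scores every window on both strands with explicit loops.
oracle_pwm_hits <- function(seq, pfm, threshold, pseudocount = 0.8) {
  bases <- c("A", "C", "G", "T")
  counts <- pfm$counts
  L <- ncol(counts)
  lo <- matrix(0, 4, L, dimnames = list(bases, NULL))
  for (j in seq_len(L)) {
    N <- sum(counts[, j])
    for (b in seq_len(4))
      lo[b, j] <- log2(((counts[b, j] + pseudocount * 0.25) /
                          (N + pseudocount)) / 0.25)
  }
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_word <- function(word) {
    s <- 0
    for (j in seq_len(L)) {
      b <- substr(word, j, j)
      if (!b %in% bases) return(NA_real_)
      s <- s + lo[b, j]
    }
    (s - smin) / (smax - smin)
  }
  out <- data.frame(start = integer(0), strand = character(0),
                    rel_score = numeric(0))
  for (o in seq_len(nchar(seq) - L + 1L)) {
    w <- substr(seq, o, o + L - 1L)
    rc <- paste(rev(unname(comp[strsplit(w, "")[[1]]])), collapse = "")
    rp <- score_word(w)
    if (!is.na(rp) && rp >= threshold)
      out <- rbind(out, data.frame(start = o, strand = "+", rel_score = rp))
    rm_ <- score_word(rc)
    if (!is.na(rm_) && rm_ >= threshold)
      out <- rbind(out, data.frame(start = o, strand = "-", rel_score = rm_))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# Quadratic interval-containment oracle: a 1-based position pos overlaps a
# 0-based half-open interval iff start < pos <= end.
brute_force_overlap <- function(pos, intervals) {
  hits <- integer(0)
  for (i in seq_len(nrow(intervals)))
    if (intervals$start[i] < pos && pos <= intervals$end[i])
      hits <- c(hits, i)
  hits
}

# Published-style differential-hit fixture loaded once for reuse.
load_differential_hits <- function() {
  read_tfbs_hits(system.file("extdata", "differential_tfbs_hits.tsv",
                             package = "famvar"))
}
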