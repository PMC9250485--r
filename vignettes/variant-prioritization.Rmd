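---
title: "Family-based variant prioritization: methods and design notes"
author: "famvar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The problem and the model

In a cancer pedigree with several affected relatives, a plausible
monogenic hypothesis is that a single rare, dominant, high-penetrance
germline allele segregates with the disease.  `famvar` implements the
staged prioritization that this hypothesis dictates for exome data that
has already been called and annotated upstream (BWA/Platypus/ANNOVAR-style
tooling; running those tools is out of scope here):

1. **Call quality.** Keep variants with PHRED quality >= 20 and coverage
   >= 5x; SNVs additionally need at least one supporting read on each
   strand, and indels must carry the caller's `PASS` flag.
2. **Rarity.** Keep variants with MAF <= 0.1% in *every* declared
   reference population (e.g. 1000 Genomes EUR, non-TCGA ExAC NFE,
   ESP6500, a local cohort).  A high-penetrance allele shared by several
   affected relatives cannot be common.
3. **Segregation.** Under the dominant model, every affected member must
   carry the allele (het or hom-alt), every healthy control must be
   hom-ref, and designated *possible carriers* — relatives with
   suggestive but not diagnostic phenotypes, such as a young descendant
   with polyps — are deliberately unconstrained.
4. **Coding cascade.** Coding candidates (exonic, splicing) that are not
   synonymous are passed through a threshold-and-voting sequence over
   precomputed annotation scores:
   - PHRED-scaled CADD >= 10 (by construction of the PHRED scaling, the
     most deleterious ~10% of substitutions genome-wide);
   - a conservation vote: at least 2 of GERP >= 2.0, PhastCons > 0.3,
     PhyloP >= 3.0;
   - a gene-intolerance vote: at least 60% of four criteria — three
     intolerance scores < 0 plus the class-specific ExAC criterion
     (missense Z > 0 for missense variants, pLI >= 0.9 for
     loss-of-function variants);
   - an ensemble deleteriousness vote: at least 60% of ten predictors
     (SIFT, PolyPhen-2 HumDiv and HumVar, LRT, MutationTaster,
     MutationAssessor, FATHMM, Reliability Index, VEST3, PROVEAN) with
     their conventional damaging categories or cutoffs
     (`default_tool_predicates()`).
5. **Regulatory arm.** Near-gene non-coding candidates (UTRs, upstream,
   downstream) are intersected with regulatory-element tracks
   (promoters, enhancers), joined to chromatin-state annotations
   (ChromHMM state and score, Segway label), flagged at CADD >= 10, and
   — where promoter sequence is available — scanned with position weight
   matrices on both the wild-type and the mutant sequence to call
   transcription-factor binding sites that the variant disrupts
   (wild-type-only) or creates (mutant-only).

Every stage appends to a *funnel report* (counts in/out plus surviving
ids), so the whole prioritization is auditable and serializable.

## PWM scanning

A JASPAR-style position frequency matrix is converted to probabilities
with a pseudocount distributed by the background composition,
`p = (count + 0.8 * 0.25) / (N + 0.8)`, and then to base-2 log-odds
against that background.  These are the JASPAR-convention defaults; both
the pseudocount (0.8) and the background (uniform) are configuration
keys.  A window's score is min–max normalized over the motif's possible
score range:

    rel_score = (S - score_min) / (score_max - score_min)

which is 1 exactly for a per-column-maximal sequence, and a hit is
called at `rel_score >= 0.8`, the standard relative profile score
threshold.  Both strands are scanned; minus-strand windows are scored on
the reverse complement and reported in plus-strand window coordinates.
Windows containing `N` are skipped rather than penalized.

Differential binding is grouped at the *transcription factor* level: a
factor with any matrix hitting both sequences is shared, and a factor
counts as affected if any of its hits differ — hits are not required to
overlap the variant position, because disruption of a site's flank can
be as consequential as of its core (an `overlap_variant_only` mode is
available).  The scan window defaults to the variant ± 60 bp, wide
enough to contain any JASPAR-scale motif that touches the variant.

## Conservation summaries around a mutation site

For a protein alignment of orthologs (computed elsewhere and read as
aligned FASTA), `column_of_residue()` maps an ungapped reference
position (e.g. the 444 of p.Y444C) to its alignment column,
`is_position_conserved()` asks whether all non-gap residues in the
column agree, and `window_identity()` reports mean percent identity in
a window of ± 5 residues.  Identity is computed reference-vs-each-
ortholog and averaged (the `all_pairs` scheme is available); a gap on
either side of a comparison counts as a mismatch.  These summaries
depend on the ortholog set supplied, so published identity percentages
are only reproducible with the exact same alignment.

## The synthetic cohort generator

Real familial sequencing data is protected and typically cannot be
redistributed, so the package ships a deterministic generator that
emulates the *structure* the pipeline assumes:

- a configurable pedigree, by default 4 cases, 1 possible carrier and
  1 control;
- ~10^4 variants with background annotation columns: allele frequencies
  log-uniform on 10^-6..10^-2, CADD drawn as `-10 log10(U)` so that 10%
  of variants reach PHRED 10 by construction, conservation and
  intolerance scores from simple unimodal distributions, categorical
  predictor calls with a 30% damaging marginal, and per-sample carrier
  probability 0.25 (high for rare variants, but chosen so that
  segregation-filter false survivors are frequent enough to test the
  closed-form expectation `n * p^cases * (1 - p)` at small n);
- *planted* variants whose scores are set just inside or outside each
  threshold so that they realize a chosen fate exactly (`pass_all`,
  `fail_cadd` with CADD 9.99, `fail_conservation` with exactly one
  vote, ...); the generator re-runs the actual filter predicates at
  generation time and refuses to emit an unrealized profile;
- synthetic promoters with a planted motif consensus and an SNV at the
  motif's maximum-information column chosen to drop the site below the
  80% threshold, verified at generation time by scanning both sequences
  (with sharpen-and-retry, then an error).

The generator does **not** emulate linkage disequilibrium, realistic
site-frequency spectra, mutation-rate heterogeneity, Mendelian
transmission within the pedigree, or correlated annotation scores.
Passing tests on synthetic data therefore demonstrate the correctness of
the *filtering logic*, not the power of the thresholds on real exomes.

## Numerical and design choices

- **Zygosity.** Het and hom-alt both count as "present" (dominant
  model).  The segregation rule can be tightened to hom-alt only.
- **Missing data.** A missing score is a failed vote and the vote
  denominators stay fixed at 4 and 10, which keeps reported percentages
  interpretable (75% always means 3 of 4).  An `available`-denominator
  mode exists but is not the default.  A missing case genotype drops the
  variant (strict mode) for reproducibility; `permissive` mode ignores
  it.  Missing allele frequencies count as 0 (unobserved is treated as
  absent), and gnomAD-style columns are report-only context rather than
  filtering populations, so a variant common in gnomAD but absent from
  the declared filtering populations is retained by design.
- **Vote arithmetic.** With 60% thresholds the effective integer cutoffs
  are 3 of 4 and 6 of 10; fractions are compared with `>=` so exact
  boundary values pass, except PhastCons, whose documented comparison is
  strict (`> 0.3`).
- **MetaSVM/MetaLR** are parsed when present but excluded from the
  default vote so the denominator remains the ten predictors above.
- **Splicing variants** are retained through the synonymous-exclusion
  step (their exonic effect is often undefined) and use pLI as their
  class-specific intolerance criterion.
- **Relatedness** is summarized as the Jaccard index of carrier sets
  over rare variants — a deliberately simple sample-swap check, not a
  kinship estimator.
- **Coordinates** are 0-based half-open internally (BED-native) and
  1-based inclusive in all user-facing output; conversions happen only
  in the I/O layer.
- **Survivor ordering** is CADD descending with variant-id tie-break, so
  output order is total and reproducible.
- **Configuration** is a flat TOML-style file; unknown keys are errors,
  not warnings, to catch threshold typos before they silently change
  results.

## Problem sizes used by the test suite

The suite exercises the brute-force oracles at sizes where exhaustive
checking is exact and fast: segregation against a per-variant loop on
1,000 simulated variants; the PWM scanner against independent
enumeration for motif lengths 3–4 over all trinucleotides and random
50–120 bp sequences; interval intersection against a quadratic
all-pairs oracle on 1,000 random intervals; and planted-variant recovery
over 100 seeds at 600 background variants per seed, with the
segregation false-survivor count checked against its binomial
expectation within 3 standard deviations.

## Known limitations

- The pipeline consumes annotation scores; it cannot detect upstream
  annotation errors beyond simple format validation.
- The regulatory arm's window-relative coordinates depend on the chosen
  window anchoring; published binding-site tables produced with a
  different (unstated) window are comparable at the level of TF sets and
  counts, not raw coordinates.
- Percent-identity values depend on the ortholog set and identity
  scheme; they are reported, not asserted against external values.
- With a single control, the segregation filter's specificity is limited
  — the funnel records, rather than hides, how many variants that step
  removes.
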