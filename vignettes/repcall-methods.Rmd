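---
title: "Calling somatic SNVs in repetitive regions by copy collapse"
author: "repcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic SNVs in repetitive regions by copy collapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repcall)
```

## The problem

Short-read somatic variant callers are close to blind in repetitive regions.
A read carrying a mutation in one copy of a multi-copy locus aligns equally
well to every copy; aligners assign it (often arbitrarily, with mapping
quality 0) to one of them, so the mutant evidence is *diluted* across loci.
At any individual copy the variant allele frequency (VAF) stays below the
caller's threshold, and most callers additionally discard mapq-0 reads
outright. Mutation density measured across the genome drops sharply as
average mapping quality falls, even though mutation accumulation is
essentially stochastic — the deficit is technical, not biological. Many
non-protein-coding genes (snRNAs, tRNAs, rRNAs, snoRNAs) live in exactly
this kind of territory.

repcall inverts the dilution: if several loci are near-identical, their
reads can all be realigned onto a *single* reference copy. Reads from a
mutated copy then stack up at one collapsed position and the mutant count
becomes callable, at the cost of no longer knowing *which* copy mutated —
calls are therefore reported in reference-copy coordinates with the copy
multiplicity attached.

## Pipeline

1. **RROI definition** (`build_rroi_set`). Each BED region's sequence is
   aligned against the whole genome (both strands) with a word-seeded
   affine-gap aligner in query-global mode, so identity reflects
   full-length divergence. A hit is accepted with at most 1 gap opening,
   identity above 90% and length difference below 15% (all configurable).
   A region with at least two accepted hits — its self-hit plus one or
   more copies — is a repetitive region of interest (RROI). The seed locus
   becomes the reference copy, extended by a 100 bp flank on each side
   (truncated and recorded at contig ends) so borderline reads are not
   lost during realignment.
2. **Collapse** (`collapse_sample`). All non-duplicate reads overlapping
   any copy are extracted — including mapq-0 multimappers, which are the
   point of the exercise — and realigned to the flanked reference copy
   with local affine-gap Smith-Waterman (match +1, mismatch −4, gap open
   −6, gap extend −1). These scores prefer soft-clipping divergent read
   ends over forcing them into the alignment; clipped bases never enter a
   pileup. Reads clipping more than 50% of their bases are dropped and
   counted. Realignment is single-ended; mate identity is kept as
   metadata.
3. **Candidate detection** (`detect_candidates`). From tumour and matched
   normal pileups (base quality ≥ Phred 13), any position/alternative base
   with **≥ 4 mutant reads in the tumour and ≤ 3 in the control** becomes
   a candidate. Each alternative base at a multi-allelic position is
   evaluated independently.
4. **Genome re-check** (`recheck_mutant_reads`). Mutant reads with a
   perfect full-length genome hit (an exact substring match on either
   strand) likely belong to an unconsidered locus and are removed; the
   ≥ 4 threshold is re-applied.
5. **In-cis analysis** (`analyze_cis_context`). A true mutation arises on
   one copy, so all mutant reads must share that copy's private variants
   (the in-cis set), and the same variants must be visible in the normal,
   which carries the unmutated copy. Mutant reads partitioning into
   incompatible cis haplotypes indicate collapsed sequencing errors from
   different copies and the candidate is discarded. The *context-
   supportive coverage* `n` — the second shape parameter of the Beta
   posterior below — is then the number of reference-base reads at the
   candidate position consistent with the cis haplotype (reads covering no
   cis position count as consistent).
6. **Review filters** (`apply_review_filters`). Mean mutant base quality
   ≥ Phred 20; no strand bias (two-sided Fisher exact test of mutant
   versus non-mutant strand counts at p < 0.01 *and* more than 90% of
   mutant reads on one strand); no position bias (all mutant bases inside
   a window of 10% of the read length).
7. **Germline posterior** (`prob_tumor_exceeds_control`). With a uniform
   prior, the MAF posterior given `y` mutant and `n` context-supportive
   reads is `Beta(y + 1, n + 1)`. Drawing `M` paired samples from the
   tumour and control posteriors, the probability that the tumour MAF
   exceeds the control MAF is estimated as the fraction of pairs where the
   tumour draw is larger. Candidates with probability < 0.95 are
   discarded as potentially germline; exactly 0.95 passes.
8. **Panel of normals** (`apply_panel_of_normals`). Sites carried by more
   than `max_carriers` (default 0) unrelated normals are removed — the
   backstop for germline variants under-covered in the matched normal. A
   fixed copy-level difference present in controls is removed here or
   already by the ≤ 3-control bound.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `min_identity` / `max_gaps` / `max_len_diff` | 0.90 / 1 / 0.15 | repetitiveness thresholds; looser values recruit more diverged copies at the price of soft-clipping around their private variants |
| `flank` | 100 bp | retains borderline reads at copy boundaries |
| `min_tumor_reads` / `max_control_reads` | 4 / 3 | the candidate definition; absolute counts, not fractions of coverage |
| `min_base_quality` / `bq_min` | Phred 13 / 20 | pileup floor and mean-mutant-quality review cutoff; common caller defaults, exposed as flags since only "high quality" is prescribed by the method |
| `concordance_min` | 0.9 | cis concordance; literally "all mutant reads" would make a single sequencing error in 10+ mutant reads fatal, 0.9 tolerates one |
| `min_normal_cis_reads` | 2 | evidence required for the cis haplotype in the normal |
| `M` | 10,000 | Monte-Carlo sample count: standard error ≤ 0.005 at the 0.95 boundary |
| `posterior_threshold` | 0.95 | classification rule; ties pass |

Strand/position bias rules are stated qualitatively by the method; the
concrete tests (Fisher p < 0.01 plus > 90% one-strand; 10%-of-read-length
window) are this package's operationalization and are configurable.

## The Monte-Carlo posterior and its oracle

`exact_prob_oracle` computes `Pr(X > Y)` for two Beta variates by
deterministic integration of `f_X(x) F_Y(x)` (absolute error < 1e−8) and is
used in the test suite to bound the Monte-Carlo error at `4·sqrt(0.25/M)`
over a grid of counts, verify `prob(t,c) + prob(c,t) = 1`, symmetry at 0.5
and monotonicity in the counts. Floating-point ties between paired draws
count as non-exceedance (conservative). Each candidate's draws use a seed
derived reproducibly from the run-level seed, so identical configurations
give byte-identical outputs.

The classifier-stability benchmark (`simulate_classifier_cohort`) draws
1,000 somatic configurations (tumour VAF uniform in 0.2–0.5 at ~30
context-supportive coverage, zero control mutant reads at ~30 coverage) and
1,000 germline configurations (the same expected mutant count in both
samples). Configurations carry the *expected* read counts at the drawn
VAF: the cohort is meant to measure the stability of the Monte-Carlo
decision itself across seeds, and injecting binomial noise into the counts
would instead measure cohort sampling noise. The weakest somatic
configuration (VAF 0.2, y=6 of 30) has exact posterior probability 0.9947,
about 9 Monte-Carlo standard errors above the 0.95 threshold at M = 10⁴,
so classification is stable by construction *of the method*, not of the
test.

## The synthetic benchmark

`synth_genome` builds repeat families descending from random ancestors:
copies diverge by independent substitutions calibrated so that expected
pairwise identity hits the target (two copies at per-base divergence `d`
agree with probability `(1−d)² + d²/3`), separated by unique spacers so
boundary-spanning reads anchor uniquely. `simulate_reads` samples paired
150 bp reads (insert 300 ± 30 bp) uniformly, with substitution-only errors
and flat Phred-37 qualities; reads fully contained in a copy are annotated
mapq 0 to mimic multi-mappers. `spike_mutations` flips covering reads to
the alternative base up to a target count (or a binomial draw at a target
VAF), skips positions under 10× depth, marks truths achieving fewer than 3
mutant reads non-evaluable, and refuses two spikes on one read — clustered
spikes would distort the carrier reads' alignments. `evaluate_calls`
matches calls to truths exactly on (RROI, collapsed position, alternative
base); sensitivity is computed over evaluable truths and precision over
all calls.

What the generator deliberately does *not* emulate: indel errors and indel
variants (the caller is SNV-only), PCR/GC bias, quality-score decay along
the read, chimeric fragments, and copy-number differences between tumour
and normal. Passing tests therefore demonstrate the collapse/filter/
posterior machinery under clean read models, not robustness to every
real-data artefact.

### Problem sizes used in the test suite

The shipped tests run, on one CPU, fixtures of 1–17 repeat families × 2–3
copies of 150–400 bp at 30× (and 10× for the coverage contrast), chosen so
each end-to-end scenario completes in minutes while leaving collapsed
depths (~90×) representative. The acceptance benchmark fixture holds 50
spikes of 5–6 mutant reads at conserved mid-copy positions on a 17-family
genome — positions are conserved across copies so the spiked base cannot
perfectly match a sister copy, and carrier reads must hold the spike at
least 15 bp (10% of the read length) from either read end
(`mid_read_margin`), since a substitution within ~4 bp of a read end is
clipped by any local aligner under the default scores; together these
exclude the soft-clipping false-negative mode by construction. A companion property intentionally reproduces that
pathology: spikes adjacent to clustered copy-divergence are missed at a
higher rate, which is the caller's known false-negative mode.

## Numerical and design choices

* **Aligner**: the package ships its own affine-gap Smith-Waterman
  (local and query-global modes) in C++, returning CIGARs directly; its
  scores are checked against `Biostrings::pairwiseAlignment` in the test
  suite. The homology search seeds candidate windows with exact 16-mers
  before running the full dynamic program, and deduplicates overlapping
  hits keeping the best identity. Identity is matches over aligned columns
  (gaps count as columns); the gap count is the number of gap openings;
  length difference is `|hit − seed| / seed`.
* **"At least two hits"** includes the self-hit: a region whose only hit
  is itself is unique.
* **Reference copy**: the seed locus itself — reproducible, and the BED
  names the locus of interest. Minimum seed length for the search is
  40 bp (configurable); hits on any contig of the supplied FASTA count
  toward the two-hit rule, decoys included.
* **Coordinates**: 0-based half-open everywhere internally; 1-based only
  in VCF output.
* **Overlapping RROIs** are allowed with a warning; duplicated calls are
  removed at reporting by genomic position of the reference copy.
* **Tie-breaks**: the DP traceback prefers diagonal over gap states, so
  alignments are deterministic; boundary deletions arising from score
  ties are trimmed.
* **Degenerate inputs**: empty BED gives an empty manifest and a warning;
  positions absent from the control pileup are treated as zero coverage
  and flagged rather than dropped; an empty call set yields sensitivity 0
  and precision NA.
* **Unmapped mates** of copy-overlapping reads are not rescued (a
  divergence from aligner-based workflows that re-pair mates); reads are
  realigned as single ends.

## Limitations

Calls cannot be attributed to a physical copy — only to the collapsed
reference coordinate. Sensitivity drops near copy-divergence clusters
(soft-clipping) and below ~20× per-copy coverage. Absolute thresholds
(4 tumour / 3 control reads) do not scale with extreme coverages. The
panel-of-normals step is only as good as the panel supplied; none is
shipped. Copies absent from the reference genome are invisible to the
RROI search by construction.
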