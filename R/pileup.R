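#' Build a pileup over an RROI reference sequence
#'
#' Walks every collapsed alignment's CIGAR and emits one entry per aligned
#' (non-clipped) base at or above the base-quality floor. Soft-clipped bases
#' and insertions never enter a column; deletions consume reference without
#' emitting entries.
#'
#' @param collapsed a `collapsed_set`.
#' @param rroi the `rroi` the alignments refer to.
#' @param min_base_quality Phred floor for pileup entries (default 13).
#' @return a `data.table` with one row per pileup entry: `rroi_id`,
#'   `ref_pos` (0-based on the reference sequence), `ref_base`, `base`,
#'   `qual` (integer Phred), `strand` (sequencing strand), `cycle` (0-based
#'   offset within the read as sequenced), `read_name`.
#' @export
build_pileup <- function(collapsed, rroi, min_base_quality = 13) {
  a <- collapsed$alignments[collapsed$alignments$rroi_id == rroi$rroi_id, ]
  refseq <- rroi$reference_sequence
  if (nrow(a) == 0L) return(empty_pileup())
  entries <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    ops <- parse_cigar(a$cigar[i])
    qpos <- 1L            # 1-based offset in oriented read
    rpos <- a$ref_start[i]  # 0-based ref position of next aligned base
    n_aln <- sum(ops$len[ops$op %in% c("M", "=", "X")])
    ref_pos <- integer(n_aln); q_off <- integer(n_aln); k <- 0L
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        idx <- seq_len(len)
        ref_pos[k + idx] <- rpos + idx - 1L
        q_off[k + idx] <- qpos + idx - 1L
        k <- k + len; rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        qpos <- qpos + len
      } else if (op == "D") {
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }
    }
    entries[[i]] <- data.table::data.table(
      ref_pos = ref_pos,
      base = substring(a$seq[i], q_off, q_off),
      qual = phred_to_int(a$qual[i])[q_off],
      strand = if (a$cycle_step[i] == 1L) "+" else "-",
      cycle = a$cycle0[i] + a$cycle_step[i] * (q_off - 1L),
      read_name = a$read_name[i])
  }
  pu <- data.table::rbindlist(entries)
  pu <- pu[pu$qual >= min_base_quality, ]
  pu[, "rroi_id" := rroi$rroi_id]
  pu[, "ref_base" := substring(refseq, pu$ref_pos + 1L, pu$ref_pos + 1L)]
  data.table::setcolorder(pu, c("rroi_id", "ref_pos", "ref_base", "base",
                                "qual", "strand", "cycle", "read_name"))
  data.table::setkey(pu, ref_pos)
  pu
}

#' @noRd
empty_pileup <- function() {
  data.table::data.table(
    rroi_id = character(), ref_pos = integer(), ref_base = character(),
    base = character(), qual = integer(), strand = character(),
    cycle = integer(), read_name = character(), key = "ref_pos")
}

#' Build pileups for every RROI of a set
#' @inheritParams build_pileup
#' @param rroi_set an `rroi_set`.
#' @return single `data.table` keyed by (rroi_id, ref_pos).
#' @export
build_pileup_set <- function(collapsed, rroi_set, min_base_quality = 13) {
  pu <- data.table::rbindlist(
    lapply(rroi_set$rrois, function(r)
      build_pileup(collapsed, r, min_base_quality)))
  if (nrow(pu)) data.table::setkey(pu, rroi_id, ref_pos)
  pu
}

#' Detect candidate SNVs from tumour and control pileups
#'
#' A candidate is a (position, alternative base) with at least
#' `min_tumor_reads` supporting reads in the tumour and no more than
#' `max_control_reads` in the control. Positions absent from the control
#' pileup count as zero control coverage and are flagged
#' `low-control-coverage`. Each alternative base at a multi-allelic position
#' is an independent candidate. The provisional `n_t`/`n_c` are the
#' reference-base depths; they are refined to context-supportive coverage
#' during cis analysis.
#'
#' @param tumor,control pileup tables from [build_pileup_set()].
#' @param min_tumor_reads minimum tumour mutant reads (default 4).
#' @param max_control_reads maximum control mutant reads (default 3).
#' @return `data.table` of candidates: rroi_id, ref_pos, ref_base, alt,
#'   y_t, n_t, y_c, n_c, mutant_read_names (list), status, filter_reasons
#'   (list), flags.
#' @export
detect_candidates <- function(tumor, control, min_tumor_reads = 4,
                              max_control_reads = 3) {
  if (nrow(tumor) == 0L) return(empty_candidates())
  talt <- tumor[tumor$base != tumor$ref_base & tumor$base %in% DNA_BASES, ]
  if (nrow(talt) == 0L) return(empty_candidates())
  cnt <- talt[, list(y_t = .N, mutant_read_names = list(read_name)),
              by = c("rroi_id", "ref_pos", "ref_base", "base")]
  data.table::setnames(cnt, "base", "alt")
  cnt <- cnt[cnt$y_t >= min_tumor_reads, ]
  if (nrow(cnt) == 0L) return(empty_candidates())

  ctrl_alt <- control[, list(y_c = .N), by = c("rroi_id", "ref_pos", "base")]
  data.table::setnames(ctrl_alt, "base", "alt")
  cnt <- merge(cnt, ctrl_alt, by = c("rroi_id", "ref_pos", "alt"),
               all.x = TRUE, sort = FALSE)
  cnt$y_c[is.na(cnt$y_c)] <- 0L

  tref <- tumor[tumor$base == tumor$ref_base,
                list(n_t = .N), by = c("rroi_id", "ref_pos")]
  cref <- control[control$base == control$ref_base,
                  list(n_c = .N), by = c("rroi_id", "ref_pos")]
  cdepth <- control[, list(control_depth = .N), by = c("rroi_id", "ref_pos")]
  cnt <- Reduce(function(x, y) merge(x, y, by = c("rroi_id", "ref_pos"),
                                     all.x = TRUE, sort = FALSE),
                list(cnt, tref, cref, cdepth))
  for (cc in c("n_t", "n_c", "control_depth"))
    cnt[[cc]][is.na(cnt[[cc]])] <- 0L

  cnt <- cnt[cnt$y_c <= max_control_reads, ]
  if (nrow(cnt) == 0L) return(empty_candidates())
  cnt$status <- "candidate"
  cnt$filter_reasons <- replicate(nrow(cnt), character(0), simplify = FALSE)
  cnt$flags <- ifelse(cnt$control_depth == 0L, "low-control-coverage", "")
  cnt$control_depth <- NULL
  data.table::setcolorder(cnt, c("rroi_id", "ref_pos", "ref_base", "alt",
                                 "y_t", "n_t", "y_c", "n_c"))
  data.table::setorder(cnt, rroi_id, ref_pos, alt)
  cnt
}

#' @noRd
empty_candidates <- function() {
  data.table::data.table(
    rroi_id = character(), ref_pos = integer(), ref_base = character(),
    alt = character(), y_t = integer(), n_t = integer(), y_c = integer(),
    n_c = integer(), mutant_read_names = list(), status = character(),
    filter_reasons = list(), flags = character())
}

#' @noRd
fail_candidate <- function(cand, reason) {
  cand$status <- "filtered"
  cand$filter_reasons <- list(c(cand$filter_reasons[[1]], reason))
  cand
}

#' Re-check mutant reads against the reference genome
#'
#' A mutant read with a perfect full-length hit anywhere in the genome
#' (either strand, zero mismatches, zero gaps — i.e. an exact substring
#' match) most likely originates from an unconsidered locus and is removed
#' from the mutant set. If fewer than `min_tumor_reads` remain, the
#' candidate is filtered with reason `perfect-hit`.
#'
#' @param cand one-row candidate table.
#' @param collapsed tumour `collapsed_set` (to resolve read sequences).
#' @param genome genome object or FASTA path.
#' @param min_tumor_reads threshold re-applied after removal (default 4).
#' @return the updated one-row candidate.
#' @export
recheck_mutant_reads <- function(cand, collapsed, genome,
                                 min_tumor_reads = 4) {
  genome <- load_genome(genome)
  a <- collapsed$alignments
  nm <- cand$mutant_read_names[[1]]
  seqs <- a$seq[match(nm, a$read_name)]
  perfect <- vapply(seqs, function(s) has_perfect_genome_hit(s, genome),
                    logical(1), USE.NAMES = FALSE)
  if (any(perfect)) {
    cand$mutant_read_names <- list(nm[!perfect])
    cand$y_t <- sum(!perfect)
    if (cand$y_t < min_tumor_reads)
      cand <- fail_candidate(cand, "perfect-hit")
  }
  cand
}

#' @noRd
has_perfect_genome_hit <- function(seq, genome) {
  pats <- c(seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))))
  for (ctg in seq_along(genome)) {
    for (p in pats) {
      if (length(Biostrings::matchPattern(p, genome[[ctg]],
                                          max.mismatch = 0)) > 0L)
        return(TRUE)
    }
  }
  FALSE
}

#' In-cis haplotype analysis of a candidate
#'
#' Mutant reads arising from a true mutation on one repeat copy must share
#' that copy's private variants (the in-cis set) — and the same in-cis
#' variants must be visible in the matched normal, which carries the
#' unmutated copy. Mutant reads that partition into incompatible cis
#' haplotypes instead originate from different copies and the candidate is
#' an artefact of collapsed sequencing errors.
#'
#' The cis haplotype is the majority base of the mutant reads at every
#' position they cover where that majority base differs from the reference.
#' Concordance is the fraction of mutant reads consistent with the full cis
#' set over the positions they cover. On success the context-supportive
#' coverages `n_t`/`n_c` are recomputed as the reference-base reads
#' consistent with the cis haplotype (reads covering no cis position count
#' as consistent).
#'
#' @param cand one-row candidate table.
#' @param tumor,control pileup tables.
#' @param concordance_min minimum concordance (default 0.9, tolerating one
#'   sequencing error among >= 10 mutant reads).
#' @param min_normal_cis_reads minimum control reads supporting each cis
#'   variant (default 2).
#' @return list(cand = updated candidate, cis = list(cis_variants,
#'   concordance, observed_in_normal)).
#' @export
analyze_cis_context <- function(cand, tumor, control, concordance_min = 0.9,
                                min_normal_cis_reads = 2) {
  tpu <- tumor[tumor$rroi_id == cand$rroi_id, ]
  cpu <- control[control$rroi_id == cand$rroi_id, ]
  nm <- cand$mutant_read_names[[1]]
  mut <- tpu[tpu$read_name %in% nm & tpu$ref_pos != cand$ref_pos, ]

  cis <- list(cis_variants = data.frame(ref_pos = integer(),
                                        base = character()),
              concordance = 1.0, observed_in_normal = TRUE)
  if (nrow(mut) > 0L) {
    tab <- mut[, list(count = .N), by = c("ref_pos", "ref_base", "base")]
    tot <- mut[, list(total = .N), by = "ref_pos"]
    tab <- merge(tab, tot, by = "ref_pos")
    maj <- tab[order(tab$ref_pos, -tab$count, tab$base), ]
    maj <- maj[!duplicated(maj$ref_pos), ]
    cisv <- maj[maj$base != maj$ref_base, c("ref_pos", "base")]
    cis$cis_variants <- as.data.frame(cisv)

    # read-level consistency against the haplotype (cis variants + reference
    # elsewhere): a read is consistent if every covered position carries the
    # haplotype base
    hap <- stats::setNames(maj$base, maj$ref_pos)
    cons <- mut[, list(ok = all(base == hap[as.character(ref_pos)])),
                by = "read_name"]
    uncovered <- setdiff(nm, cons$read_name)
    cis$concordance <- (sum(cons$ok) + length(uncovered)) / length(nm)
  }

  if (cis$concordance < concordance_min) {
    return(list(cand = fail_candidate(cand, "cis-discordant"), cis = cis))
  }

  if (nrow(cis$cis_variants) > 0L) {
    seen <- vapply(seq_len(nrow(cis$cis_variants)), function(i) {
      v <- cis$cis_variants[i, ]
      sum(cpu$ref_pos == v$ref_pos & cpu$base == v$base) >= min_normal_cis_reads
    }, logical(1))
    cis$observed_in_normal <- all(seen)
    if (!cis$observed_in_normal)
      return(list(cand = fail_candidate(cand, "cis-absent-in-normal"),
                  cis = cis))
  }

  cand$n_t <- context_supportive_n(cand, tpu, cis$cis_variants)
  cand$n_c <- context_supportive_n(cand, cpu, cis$cis_variants)
  list(cand = cand, cis = cis)
}

#' Reference-base reads at the candidate position consistent with the cis
#' haplotype over whatever cis positions they cover
#' @noRd
context_supportive_n <- function(cand, pu, cis_variants) {
  at <- pu[pu$ref_pos == cand$ref_pos & pu$base == cand$ref_base, ]
  if (nrow(at) == 0L) return(0L)
  if (nrow(cis_variants) == 0L) return(nrow(at))
  sub <- pu[pu$read_name %in% at$read_name &
            pu$ref_pos %in% cis_variants$ref_pos, ]
  if (nrow(sub) == 0L) return(nrow(at))
  exp_base <- stats::setNames(cis_variants$base,
                              as.character(cis_variants$ref_pos))
  bad <- unique(sub$read_name[sub$base !=
                              exp_base[as.character(sub$ref_pos)]])
  nrow(at) - sum(at$read_name %in% bad)
}

#' Review filters: base quality, strand bias, position bias
#'
#' Encodes the manual-review criteria as computable rules: (ii) the mean
#' Phred quality of the mutant bases must reach `bq_min`; (v) no strand
#' bias — fail when a two-sided exact test (mutant fwd/rev vs non-mutant
#' fwd/rev) gives p < `strand_p` AND more than `strand_frac` of mutant reads
#' sit on one strand — and no position bias — fail when every mutant base
#' falls within a window of `pos_window_frac` of the read length.
#'
#' @param cand one-row candidate table.
#' @param tumor tumour pileup table.
#' @param bq_min mean mutant base-quality cutoff (Phred, default 20).
#' @param strand_p exact-test p-value cutoff (default 0.01).
#' @param strand_frac one-strand fraction for the strand-bias rule
#'   (default 0.9).
#' @param pos_window_frac read-length fraction for the position-bias rule
#'   (default 0.1).
#' @return list(cand = updated candidate, decision = list(
#'   mean_mutant_base_quality, strand_counts, position_dispersion, passes,
#'   reasons)).
#' @export
apply_review_filters <- function(cand, tumor, bq_min = 20, strand_p = 0.01,
                                 strand_frac = 0.9, pos_window_frac = 0.1) {
  tpu <- tumor[tumor$rroi_id == cand$rroi_id, ]
  at <- tpu[tpu$ref_pos == cand$ref_pos, ]
  nm <- cand$mutant_read_names[[1]]
  mut <- at[at$read_name %in% nm & at$base == cand$alt, ]
  non <- at[!at$read_name %in% nm, ]
  reasons <- character(0)

  mbq <- mean(mut$qual)
  if (is.nan(mbq) || mbq < bq_min) reasons <- c(reasons, "low-base-quality")

  sc <- c(fwd = sum(mut$strand == "+"), rev = sum(mut$strand == "-"))
  one_strand <- max(sc) / max(1L, sum(sc))
  p_strand <- stats::fisher.test(matrix(c(sc["fwd"], sc["rev"],
                                          sum(non$strand == "+"),
                                          sum(non$strand == "-")),
                                        nrow = 2))$p.value
  if (p_strand < strand_p && one_strand > strand_frac)
    reasons <- c(reasons, "strand-bias")

  rl <- max(mut$cycle, tpu$cycle, 0L) + 1L  # read length from observed cycles
  disp <- if (nrow(mut)) diff(range(mut$cycle)) else NA_integer_
  if (nrow(mut) && disp < pos_window_frac * rl)
    reasons <- c(reasons, "position-bias")

  if (length(reasons)) cand <- fail_candidate(cand, reasons[1])
  list(cand = cand,
       decision = list(mean_mutant_base_quality = mbq, strand_counts = sc,
                       position_dispersion = disp,
                       passes = length(reasons) == 0L, reasons = reasons))
}
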