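#' Extract all reads mapped to any copy of an RROI
#'
#' Returns the union of non-duplicate reads whose alignment overlaps any
#' copy interval of the RROI. A read overlapping two copies (e.g. a tandem
#' pair) is reported once; mapq-0 multimappers are deliberately retained —
#' they are the very reads conventional callers discard.
#'
#' @param alignments input for [read_alignments()].
#' @param rroi an `rroi` object.
#' @return a `data.table` of read records (one row per read segment).
#' @export
extract_reads <- function(alignments, rroi) {
  reads <- read_alignments(alignments)
  bad <- setdiff(unique(rroi$copies$chrom), unique(c(reads$chrom, rroi$seed$chrom)))
  reads <- reads[!reads$is_duplicate, ]
  if (nrow(reads) == 0L) return(reads)
  rg <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$pos + 1L, reads$end))
  cg <- GenomicRanges::GRanges(rroi$copies$chrom,
                               IRanges::IRanges(rroi$copies$start + 1L,
                                                rroi$copies$end))
  ov <- GenomicRanges::findOverlaps(rg, cg)
  hit <- unique(S4Vectors::queryHits(ov))
  out <- reads[hit, ]
  # one record per read segment even if it overlaps several copies
  out <- out[!duplicated(paste(out$qname, out$is_read1)), ]
  out
}

#' Realign extracted reads onto the RROI's flanked reference copy
#'
#' Each read is locally aligned (affine-gap Smith-Waterman via the aligner
#' contract) against the reference sequence; if the forward orientation
#' aligns poorly, the reverse complement is tried and the better alignment
#' kept, so copies on either strand collapse correctly. Reads whose best
#' alignment soft-clips more than `max_softclip` of their bases are dropped
#' and counted: soft-clipped bases never contribute to pileups.
#'
#' @param reads read records from [extract_reads()].
#' @param rroi an `rroi` object.
#' @param scoring [aligner_scoring()] (defaults favour clipping over forcing
#'   divergent ends).
#' @param max_softclip drop threshold on the soft-clipped fraction
#'   (default 0.5).
#' @return list with class `collapsed_set`: `sample_label` (unset),
#'   `alignments` (a `data.table`: read_name, rroi_id, ref_start 0-based on
#'   the reference sequence, cigar, score, softclip_frac, orient, seq, qual,
#'   cycle0, cycle_step, mapq_orig), and `dropped` counters.
#' @export
realign_to_reference_copy <- function(reads, rroi,
                                      scoring = aligner_scoring(),
                                      max_softclip = 0.5) {
  if (nrow(reads) == 0L) {
    return(new_collapsed_set(empty_collapsed_table(),
                             c(unaligned = 0L, excess_softclip = 0L)))
  }
  fwd <- pairwise_align(reads$seq, rroi$reference_sequence, type = "local",
                        scoring = scoring)
  # retry poorly aligned reads in the opposite orientation
  poor <- which(fwd$softclip_frac > max_softclip |
                fwd$score < 0.4 * fwd$q_len)
  orient <- rep("+", nrow(reads))
  best <- fwd
  if (length(poor)) {
    rcseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$seq[poor])))
    rev <- pairwise_align(rcseq, rroi$reference_sequence, type = "local",
                          scoring = scoring)
    better <- rev$score > fwd$score[poor]
    idx <- poor[better]
    if (length(idx)) {
      cols <- names(best)
      for (cc in cols) data.table::set(best, i = idx, j = cc,
                                       value = rev[[cc]][better])
      orient[idx] <- "-"
    }
  }
  keep <- best$softclip_frac <= max_softclip & best$n_match > 0
  dropped <- c(unaligned = sum(best$n_match == 0),
               excess_softclip = sum(best$n_match > 0 & !keep))
  seqs <- reads$seq
  quals <- reads$qual
  flip <- orient == "-"
  if (any(flip)) {
    seqs[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[flip])))
    quals[flip] <- vapply(quals[flip],
                          function(q) intToUtf8(rev(utf8ToInt(q))),
                          character(1), USE.NAMES = FALSE)
  }
  # cycle bookkeeping: sequencing cycle of query offset i (1-based, oriented
  # to the reference) is cycle0 + cycle_step * (i - 1)
  cycle0 <- ifelse(xor(flip, reads$strand == "-"), nchar(seqs) - 1L, 0L)
  cycle_step <- ifelse(xor(flip, reads$strand == "-"), -1L, 1L)
  aln <- data.table::data.table(
    read_name = paste0(reads$qname, ifelse(reads$is_read1, "/1", "/2")),
    rroi_id = rroi$rroi_id,
    ref_start = best$s_start - 1L,
    cigar = best$cigar,
    score = best$score,
    softclip_frac = best$softclip_frac,
    orient = orient,
    seq = seqs, qual = quals,
    cycle0 = cycle0, cycle_step = cycle_step,
    mapq_orig = reads$mapq)[keep, ]
  new_collapsed_set(aln, dropped)
}

#' @noRd
new_collapsed_set <- function(alignments, dropped, sample_label = NA_character_) {
  structure(list(sample_label = sample_label, alignments = alignments,
                 dropped = dropped, merged = FALSE),
            class = "collapsed_set")
}

#' @noRd
empty_collapsed_table <- function() {
  data.table::data.table(
    read_name = character(), rroi_id = character(), ref_start = integer(),
    cigar = character(), score = numeric(), softclip_frac = numeric(),
    orient = character(), seq = character(), qual = character(),
    cycle0 = integer(), cycle_step = integer(), mapq_orig = integer())
}

#' Collapse one sample over a whole RROI set
#'
#' Convenience wrapper: extract + realign per RROI, then merge.
#' @param alignments input for [read_alignments()].
#' @param rroi_set an `rroi_set`.
#' @param sample_label `"tumor"` or `"normal"`.
#' @inheritParams realign_to_reference_copy
#' @return a merged `collapsed_set`.
#' @export
collapse_sample <- function(alignments, rroi_set, sample_label,
                            scoring = aligner_scoring(),
                            max_softclip = 0.5) {
  reads <- read_alignments(alignments)
  sets <- lapply(rroi_set$rrois, function(r) {
    cs <- realign_to_reference_copy(extract_reads(reads, r), r,
                                    scoring = scoring,
                                    max_softclip = max_softclip)
    cs$sample_label <- sample_label
    cs
  })
  merge_collapsed(sets)
}

#' Merge per-RROI collapsed sets of one sample
#'
#' @param per_rroi_sets list of `collapsed_set` objects sharing a sample
#'   label. Read counts are conserved; the per-RROI partitioning is kept via
#'   the `rroi_id` column (a read landing in two overlapping RROIs stays in
#'   both partitions and downstream calls are deduplicated by genomic
#'   position).
#' @return one merged `collapsed_set`.
#' @export
merge_collapsed <- function(per_rroi_sets) {
  if (!length(per_rroi_sets))
    return(new_collapsed_set(empty_collapsed_table(),
                             c(unaligned = 0L, excess_softclip = 0L)))
  labels <- unique(vapply(per_rroi_sets, function(s) s$sample_label,
                          character(1)))
  labels <- labels[!is.na(labels)]
  if (length(labels) > 1L)
    stopf("cannot merge collapsed sets with mixed sample labels: %s",
          paste(labels, collapse = ", "))
  merged <- new_collapsed_set(
    data.table::rbindlist(lapply(per_rroi_sets, `[[`, "alignments")),
    Reduce(`+`, lapply(per_rroi_sets, `[[`, "dropped")),
    sample_label = if (length(labels)) labels else NA_character_)
  merged$merged <- TRUE
  merged
}

#' @export
print.collapsed_set <- function(x, ...) {
  cat(sprintf("<collapsed_set> sample: %s  alignments: %d over %d RROI(s)  dropped: %s\n",
              x$sample_label, nrow(x$alignments),
              length(unique(x$alignments$rroi_id)),
              paste(names(x$dropped), x$dropped, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a collapsed set as SAM whose contigs are the RROI reference copies
#'
#' @param collapsed a `collapsed_set`.
#' @param rroi_set the `rroi_set` it was aligned to (for contig lengths).
#' @param path output SAM path.
#' @export
write_collapsed_sam <- function(collapsed, rroi_set, path) {
  contigs <- vapply(rroi_set$rrois, function(r) nchar(r$reference_sequence),
                    integer(1))
  a <- collapsed$alignments
  reads <- data.table::data.table(
    qname = a$read_name, is_read1 = TRUE, chrom = a$rroi_id,
    pos = a$ref_start, end = a$ref_start + cigar_ref_span(a$cigar),
    strand = a$orient, mapq = 60L,
    cigar = gsub("[=X]", "M", collapse_cigar_mx(a$cigar)),
    seq = a$seq, qual = a$qual, is_duplicate = FALSE)
  write_sam(reads, contigs, path, paired = FALSE)
}

#' Merge adjacent =/X runs so the emitted CIGAR uses plain M ops
#' @noRd
collapse_cigar_mx <- function(cigars) {
  vapply(cigars, function(cg) {
    ops <- parse_cigar(cg)
    ops$op[ops$op %in% c("=", "X")] <- "M"
    r <- rle(ops$op)
    grp <- rep(seq_along(r$lengths), r$lengths)
    len <- vapply(split(ops$len, grp), sum, integer(1))
    paste0(len, r$values, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
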