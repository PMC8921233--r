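#' Synthesize a genome of repetitive gene families
#'
#' Builds a single contig holding `n_families` families of
#' `copies_per_family` near-identical copies. Each family descends from a
#' random ancestor; copies diverge by independent random substitutions
#' calibrated so that the expected pairwise identity between two copies
#' equals `inter_copy_identity` (two copies each at per-base divergence `d`
#' agree with probability `(1-d)^2 + d^2/3`). Copies are separated by
#' unique random spacers, so reads spanning a copy boundary anchor uniquely.
#' A BED marks the first copy of each family as its seed region.
#'
#' @param n_families number of repeat families.
#' @param copies_per_family copies per family (single value or one per
#'   family).
#' @param copy_length copy length in bp.
#' @param inter_copy_identity target pairwise identity in (0.5, 1].
#' @param spacer_length unique spacer length between copies (default 400).
#' @param seed RNG seed.
#' @return object of class `synthetic_genome`: `genome` (DNAStringSet with
#'   contig `sim1`), `bed` (seed regions, 0-based), `copies` (data.table:
#'   family, copy, start, end), and the generator parameters.
#' @export
synth_genome <- function(n_families, copies_per_family, copy_length,
                         inter_copy_identity = 0.97, spacer_length = 400,
                         seed = 1) {
  if (inter_copy_identity <= 0.5 || inter_copy_identity > 1)
    stopf("inter_copy_identity must be in (0.5, 1]")
  if (copy_length <= 0 || spacer_length <= 0)
    stopf("copy_length and spacer_length must be positive")
  ncp <- rep_len(copies_per_family, max(1L, n_families))
  d <- divergence_for_identity(inter_copy_identity)
  if (n_families > 0 && d > 0 && round(d * copy_length) < 1 &&
      inter_copy_identity < 1)
    stopf("identity target %.3f unreachable at copy length %d",
          inter_copy_identity, copy_length)
  with_seed(seed, {
    parts <- character(0)
    copies <- list()
    bed <- list()
    cursor <- 0L
    add <- function(s) { parts[[length(parts) + 1L]] <<- s
                         cursor <<- cursor + nchar(s) }
    add(random_dna(spacer_length))
    for (f in seq_len(n_families)) {
      anc <- random_dna(copy_length)
      for (k in seq_len(ncp[f])) {
        cp <- mutate_sequence(anc, d)
        start <- cursor
        add(cp)
        copies[[length(copies) + 1L]] <- data.table::data.table(
          family = f, copy = k, start = start, end = start + copy_length)
        if (k == 1L)
          bed[[length(bed) + 1L]] <- data.frame(
            chrom = "sim1", start = start, end = start + copy_length,
            name = sprintf("fam%02d", f), stringsAsFactors = FALSE)
        add(random_dna(spacer_length))
      }
    }
    genome <- Biostrings::DNAStringSet(paste(parts, collapse = ""))
    names(genome) <- "sim1"
    structure(list(
      genome = genome,
      bed = if (length(bed)) do.call(rbind, bed) else
        data.frame(chrom = character(), start = integer(),
                   end = integer(), name = character()),
      copies = data.table::rbindlist(copies),
      n_families = n_families, copies_per_family = ncp,
      copy_length = copy_length,
      inter_copy_identity = inter_copy_identity,
      spacer_length = spacer_length, seed = seed),
      class = "synthetic_genome")
  })
}

#' Per-copy divergence giving a target expected pairwise identity
#' @noRd
divergence_for_identity <- function(identity) {
  if (identity >= 1) return(0)
  stats::uniroot(function(d) (1 - d)^2 + d^2 / 3 - identity,
                 c(0, 0.5), tol = 1e-9)$root
}

#' @noRd
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- vapply(chars[pos], function(b) sample(other_bases(b), 1),
                       character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d bp, %d families x %s copies of %d bp at %.0f%% identity (seed %d)\n",
              length(x$genome[[1]]), x$n_families,
              paste(unique(x$copies_per_family), collapse = "/"),
              x$copy_length, 100 * x$inter_copy_identity, x$seed))
  invisible(x)
}

#' Simulate paired-end reads from a genome
#'
#' Uniform fragment sampling with Gaussian insert sizes, substitution-only
#' sequencing errors and flat Phred-37 base qualities. Reads are emitted
#' with alignments at their true source loci; a read fully contained in a
#' repeat copy is ambiguous by construction and gets mapping quality 0,
#' mimicking a multi-mapper, while uniquely anchored reads get mapq 60.
#'
#' @param sg a `synthetic_genome` (or a plain genome; then no mapq-0
#'   ambiguity is annotated).
#' @param coverage mean fold coverage.
#' @param read_length read length in bp (default 150).
#' @param error_rate per-base substitution error rate (default 0).
#' @param insert_mean,insert_sd fragment-length model (defaults 300, 30).
#' @param seed RNG seed.
#' @return a read-alignment `data.table` (see [read_alignments()]) with
#'   truth columns `frag_start`, `frag_end`.
#' @export
simulate_reads <- function(sg, coverage, read_length = 150, error_rate = 0,
                           insert_mean = 300, insert_sd = 30, seed = 1) {
  if (coverage <= 0) stopf("coverage must be positive")
  genome <- if (methods::is(sg, "synthetic_genome")) sg$genome else
    load_genome(sg)
  gl <- length(genome[[1]])
  gseq <- as.character(genome[[1]])
  if (read_length > gl) stopf("read_length exceeds the genome length")
  n_frag <- max(1L, as.integer(round(gl * coverage / (2 * read_length))))
  with_seed(seed, {
    insert <- pmax(read_length,
                   as.integer(round(stats::rnorm(n_frag, insert_mean,
                                                 insert_sd))))
    insert <- pmin(insert, gl)
    fstart <- vapply(insert, function(ins)
      sample.int(gl - ins + 1L, 1L) - 1L, integer(1))
    fend <- fstart + insert
    r1_seq <- substring(gseq, fstart + 1L, fstart + read_length)
    r2_src <- substring(gseq, fend - read_length + 1L, fend)
    r1_seq <- add_errors(r1_seq, error_rate)
    r2_src <- add_errors(r2_src, error_rate)
    qual <- strrep(int_to_phred(37L), read_length)
    reads <- data.table::rbindlist(list(
      data.table::data.table(
        qname = sprintf("frag%06d", seq_len(n_frag)), is_read1 = TRUE,
        chrom = names(genome)[1], pos = fstart,
        end = fstart + read_length, strand = "+",
        seq = r1_seq, frag_start = fstart, frag_end = fend),
      data.table::data.table(
        qname = sprintf("frag%06d", seq_len(n_frag)), is_read1 = FALSE,
        chrom = names(genome)[1], pos = fend - read_length,
        end = fend, strand = "-",
        seq = r2_src, frag_start = fstart, frag_end = fend)))
    reads$qual <- qual
    reads$cigar <- paste0(read_length, "M")
    reads$is_duplicate <- FALSE
    reads$mapq <- 60L
    if (methods::is(sg, "synthetic_genome") && nrow(sg$copies)) {
      rg <- IRanges::IRanges(reads$pos + 1L, reads$end)
      cg <- IRanges::IRanges(sg$copies$start + 1L, sg$copies$end)
      ov <- IRanges::findOverlaps(rg, cg, type = "within")
      reads$mapq[unique(S4Vectors::queryHits(ov))] <- 0L
    }
    data.table::setorder(reads, pos)
    reads
  })
}

#' @noRd
add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    chars <- strsplit(s, "")[[1]]
    chars[pos] <- vapply(chars[pos], function(b) sample(other_bases(b), 1),
                         character(1), USE.NAMES = FALSE)
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Spike mutations into simulated tumour reads
#'
#' For each spike specification the reads covering the target position on
#' the chosen copy are flipped to the alternative base until the target
#' mutant-read count is met (or, when `target_vaf` is given, a binomial
#' draw of the covering reads). Positions under `min_depth` coverage are
#' skipped; truths achieving fewer than `min_mut_reads` mutant reads are
#' kept but marked non-evaluable — mirroring how spike-in benchmarks
#' exclude under-supported positions from the sensitivity denominator. Two
#' specifications touching the same read are an error: clustered spikes
#' distort alignment of the carrier reads.
#'
#' @param reads tumour read table from [simulate_reads()].
#' @param sg the `synthetic_genome` the reads were drawn from.
#' @param specs data.frame with columns family, copy, offset (0-based
#'   within the copy), alt, and either target_reads or target_vaf.
#' @param min_mut_reads evaluability threshold (default 3).
#' @param min_depth minimum covering reads to attempt a spike (default 10).
#' @param mid_read_margin restrict carrier reads to those holding the
#'   target at least this many bp from both read ends (default 0 = any
#'   covering read). A substitution within a few bases of a read end is
#'   clipped by any local aligner, so benchmarks that want to exclude the
#'   soft-clipping false-negative mode by construction set a margin of
#'   about 10% of the read length.
#' @param seed RNG seed.
#' @return list: `reads` (mutated table), `truth` (data.table: family,
#'   copy, offset, genome_pos 0-based, ref, alt, depth, achieved,
#'   evaluable, exclusion_reason).
#' @export
spike_mutations <- function(reads, sg, specs, min_mut_reads = 3,
                            min_depth = 10, mid_read_margin = 0, seed = 1) {
  gseq <- as.character(sg$genome[[1]])
  reads <- data.table::copy(data.table::as.data.table(reads))
  touched <- rep(FALSE, nrow(reads))
  truth <- vector("list", nrow(specs))
  with_seed(seed, {
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      cp <- sg$copies[sg$copies$family == sp$family &
                      sg$copies$copy == sp$copy, ]
      if (nrow(cp) != 1L) stopf("spike %d targets unknown copy", i)
      gpos <- cp$start + sp$offset            # 0-based genome position
      ref <- substring(gseq, gpos + 1L, gpos + 1L)
      if (ref == sp$alt)
        stopf("spike %d: alt base equals the reference base at the target", i)
      cover <- which(reads$pos <= gpos & reads$end > gpos)
      depth <- length(cover)
      if (depth < min_depth) {
        truth[[i]] <- truth_row(sp, gpos, ref, depth, 0L, FALSE,
                                "below-min-depth")
        next
      }
      eligible <- cover[reads$pos[cover] + mid_read_margin <= gpos &
                        reads$end[cover] - mid_read_margin > gpos]
      target <- if (!is.null(sp$target_reads) && !is.na(sp$target_reads))
        sp$target_reads else stats::rbinom(1, depth, sp$target_vaf)
      pick <- eligible[sample.int(length(eligible),
                                  min(length(eligible), target))]
      if (any(touched[pick]))
        stopf(paste0("spike %d would mutate a read already carrying ",
                     "another spike; space specifications further apart"), i)
      touched[pick] <- TRUE
      off <- gpos - reads$pos[pick] + 1L
      reads$seq[pick] <- mapply(function(s, o) {
        substr(s, o, o) <- sp$alt; s
      }, reads$seq[pick], off, USE.NAMES = FALSE)
      achieved <- length(pick)
      truth[[i]] <- truth_row(sp, gpos, ref, depth, achieved,
                              achieved >= min_mut_reads,
                              if (achieved >= min_mut_reads) "" else
                                "under-min-mut-reads")
    }
  })
  list(reads = reads, truth = data.table::rbindlist(truth))
}

#' @noRd
truth_row <- function(sp, gpos, ref, depth, achieved, evaluable, reason) {
  data.table::data.table(
    family = sp$family, copy = sp$copy, offset = sp$offset,
    genome_pos = gpos, ref = ref, alt = sp$alt, depth = depth,
    achieved = achieved, evaluable = evaluable, exclusion_reason = reason)
}

#' Lift spike truths onto collapsed RROI coordinates
#'
#' Copies diverge by substitutions only, so offset `k` of any copy maps to
#' offset `k` of the family's reference copy; the collapsed coordinate adds
#' the left flank of the RROI.
#'
#' @param truth truth table from [spike_mutations()].
#' @param sg the `synthetic_genome`.
#' @param rroi_set the `rroi_set` built from `sg`'s BED.
#' @return truth with columns `rroi_id`, `ref_pos` added.
#' @export
lift_truth <- function(truth, sg, rroi_set) {
  truth <- data.table::copy(truth)
  truth$rroi_id <- NA_character_
  truth$ref_pos <- NA_integer_
  for (r in rroi_set$rrois) {
    seeds <- sg$bed[sg$bed$name == r$rroi_id, ]
    if (nrow(seeds) != 1L) next
    fam <- sg$copies[sg$copies$start == seeds$start, ]$family[1]
    sel <- which(truth$family == fam)
    truth$rroi_id[sel] <- r$rroi_id
    truth$ref_pos[sel] <- r$flank_left + truth$offset[sel]
  }
  truth
}

#' Score somatic calls against a spike-in truth table
#'
#' Matching is exact on (rroi_id, collapsed position, alt). True positives
#' are calls matching an evaluable truth; false negatives are evaluable
#' truths with no matching call; false positives are calls matching no
#' truth (evaluable or not). Non-evaluable truths are excluded from the
#' sensitivity denominator and do not count as false positives when called.
#'
#' @param calls data.frame of calls with rroi_id, ref_pos, alt.
#' @param truth lifted truth table ([lift_truth()]).
#' @return object of class `benchmark_result` with TP, FP, FN,
#'   sensitivity, precision.
#' @export
evaluate_calls <- function(calls, truth) {
  calls <- data.table::as.data.table(calls)
  key <- function(d) paste(d$rroi_id, d$ref_pos, d$alt)
  if (nrow(calls) && anyDuplicated(key(calls)))
    stopf("duplicate call records")
  ev <- truth[truth$evaluable & !is.na(truth$rroi_id), ]
  tp <- if (nrow(calls)) sum(key(calls) %in% key(ev)) else 0L
  fp <- if (nrow(calls)) sum(!key(calls) %in% key(truth)) else 0L
  fn <- nrow(ev) - tp
  benchmark_result(tp, fp, fn)
}

#' @rdname evaluate_calls
#' @param TP,FP,FN counts (for assembling a result directly).
#' @export
benchmark_result <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  structure(list(
    TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN),
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<benchmark_result> TP %d  FP %d  FN %d  sensitivity %s  precision %s\n",
              x$TP, x$FP, x$FN, fmt(x$sensitivity), fmt(x$precision)))
  invisible(x)
}

#' Write simulated reads as FASTQ (one file per mate)
#'
#' @param reads read table from [simulate_reads()].
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`. Mate-2 sequences are reverse-complemented back to
#'   sequencing orientation.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    sel <- reads[reads$is_read1 == (m == 1L), ]
    seqs <- sel$seq
    if (m == 2L)
      seqs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
    writeLines(paste0("@", sel$qname, "/", m, "\n", seqs, "\n+\n", sel$qual),
               paths[m])
  }
  invisible(paths)
}
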