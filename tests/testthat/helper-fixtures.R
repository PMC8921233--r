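# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# offsets within a family's copies where every copy carries the same base
conserved_offsets <- function(sg, fam) {
  gseq <- as.character(sg$genome[[1]])
  cps <- sg$copies[sg$copies$family == fam, ]
  mat <- sapply(seq_len(nrow(cps)), function(i)
    strsplit(substr(gseq, cps$start[i] + 1L, cps$end[i]), "")[[1]])
  which(apply(mat, 1, function(r) length(unique(r)) == 1L)) - 1L
}

# spike specs at conserved mid-copy offsets, one per (family, copy) pair,
# alternating target mutant-read counts
make_clean_specs <- function(sg, families, copies, targets = c(5L, 6L),
                             offset_range = NULL) {
  gseq <- as.character(sg$genome[[1]])
  L <- sg$copy_length
  if (is.null(offset_range)) offset_range <- c(round(L * 0.35), round(L * 0.65))
  out <- list()
  k <- 0L
  for (f in families) {
    off_ok <- conserved_offsets(sg, f)
    off_ok <- off_ok[off_ok >= offset_range[1] & off_ok <= offset_range[2]]
    for (cp in copies) {
      k <- k + 1L
      off <- off_ok[1L + ((k * 7L) %% max(1L, length(off_ok) - 1L))]
      cstart <- sg$copies[sg$copies$family == f & sg$copies$copy == cp, ]$start
      ref <- substr(gseq, cstart + off + 1L, cstart + off + 1L)
      out[[k]] <- data.frame(
        family = f, copy = cp, offset = off,
        alt = setdiff(c("A", "C", "G", "T"), ref)[1L],
        target_reads = targets[1L + (k %% length(targets))])
    }
  }
  do.call(rbind, out)
}

# small 3-family benchmark genome shared across pipeline tests
small_bench <- function() fixture("small_bench", function() {
  sg <- synth_genome(n_families = 3, copies_per_family = 3,
                     copy_length = 400, inter_copy_identity = 0.97,
                     seed = 11)
  rs <- suppressWarnings(build_rroi_set(sg$bed, sg$genome))
  list(sg = sg, rs = rs,
       tumor = simulate_reads(sg, coverage = 30, seed = 21),
       normal = simulate_reads(sg, coverage = 30, seed = 22))
})

# hand-built collapsed set: ungapped full-length alignments from a layout
# data.frame(read_name, ref_start, seq, qual_int, strand)
manual_collapsed <- function(layout, rroi_id = "rr1", sample = "tumor") {
  aln <- data.table::data.table(
    read_name = layout$read_name,
    rroi_id = rroi_id,
    ref_start = layout$ref_start,
    cigar = if (is.null(layout$cigar)) paste0(nchar(layout$seq), "=") else
      layout$cigar,
    score = nchar(layout$seq),
    softclip_frac = 0,
    orient = "+",
    seq = layout$seq,
    qual = vapply(seq_len(nrow(layout)), function(i)
      strrep(rawToChar(as.raw(layout$qual_int[i] + 33L)),
             nchar(layout$seq[i])), character(1)),
    cycle0 = ifelse(layout$strand == "-", nchar(layout$seq) - 1L, 0L),
    cycle_step = ifelse(layout$strand == "-", -1L, 1L),
    mapq_orig = 0L)
  structure(list(sample_label = sample, alignments = aln,
                 dropped = c(unaligned = 0L, excess_softclip = 0L),
                 merged = TRUE),
            class = "collapsed_set")
}

# minimal rroi object around an explicit reference sequence
manual_rroi <- function(refseq, rroi_id = "rr1", flank_left = 0L) {
  copies <- data.frame(chrom = "c1", start = 0L, end = nchar(refseq),
                       strand = "+", identity = c(1, 0.97),
                       gap_count = 0L, length_diff_frac = 0,
                       is_seed_self_hit = c(TRUE, FALSE))
  structure(list(rroi_id = rroi_id,
                 seed = genomic_interval("c1", 0L, nchar(refseq)),
                 copies = copies,
                 reference_copy = genomic_interval("c1", 0L, nchar(refseq)),
                 flank_bp = 0L, flank_left = flank_left, flank_right = 0L,
                 truncated = FALSE, reference_sequence = refseq),
            class = "rroi")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
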