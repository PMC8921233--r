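make_read_row <- function(qname, pos, len = 50, chrom = "c1", mapq = 60L,
                          dup = FALSE, seq = NULL, is_read1 = TRUE) {
  data.frame(qname = qname, is_read1 = is_read1, chrom = chrom, pos = pos,
             end = pos + len, strand = "+", mapq = mapq,
             cigar = paste0(len, "M"),
             seq = seq %||% strrep("A", len), qual = strrep("F", len),
             is_duplicate = dup, stringsAsFactors = FALSE)
}
`%||%` <- repcall:::`%||%`

test_that("extraction unions reads over copies, drops duplicates, keeps mapq 0", {
  refseq <- random_seq(200, 1)
  r <- manual_rroi(refseq)
  r$copies <- data.frame(chrom = "c1", start = c(0L, 1000L),
                         end = c(200L, 1200L), strand = "+",
                         identity = c(1, 0.97), gap_count = 0L,
                         length_diff_frac = 0,
                         is_seed_self_hit = c(TRUE, FALSE))
  reads <- do.call(rbind, c(
    lapply(1:10, function(i) make_read_row(sprintf("a%02d", i), 50 + i)),
    lapply(1:8, function(i) make_read_row(sprintf("b%02d", i), 1050 + i,
                                          mapq = 0L)),
    lapply(1:2, function(i) make_read_row(sprintf("d%02d", i), 60, dup = TRUE)),
    list(make_read_row("far", 5000))))
  got <- extract_reads(reads, r)
  expect_identical(nrow(got), 18L)          # 10 + 8, duplicates and 'far' out
  expect_true(all(got$mapq[startsWith(got$qname, "b")] == 0L))
})

test_that("a read overlapping both copies of a tandem pair is reported once", {
  refseq <- random_seq(100, 2)
  r <- manual_rroi(refseq)
  r$copies <- data.frame(chrom = "c1", start = c(0L, 100L),
                         end = c(100L, 200L), strand = "+",
                         identity = c(1, 0.99), gap_count = 0L,
                         length_diff_frac = 0,
                         is_seed_self_hit = c(TRUE, FALSE))
  got <- extract_reads(make_read_row("straddle", 80, len = 50), r)
  expect_identical(nrow(got), 1L)
})

test_that("realignment reproduces the identity case and records divergence", {
  refseq <- random_seq(400, 3)
  r <- manual_rroi(refseq)
  exact <- make_read_row("exact", 0, len = 100,
                         seq = substr(refseq, 101, 200))
  cs <- realign_to_reference_copy(read_alignments(exact), r)
  a <- cs$alignments
  expect_identical(nrow(a), 1L)
  expect_identical(a$ref_start, 100L)
  expect_identical(a$cigar, "100=")
  expect_identical(a$softclip_frac, 0)

  div <- substr(refseq, 101, 200)
  for (p in c(15, 45, 85)) {
    substr(div, p, p) <- setdiff(c("A", "C", "G", "T"), substr(div, p, p))[1]
  }
  cs2 <- realign_to_reference_copy(
    read_alignments(make_read_row("div", 0, len = 100, seq = div)), r)
  ops <- repcall:::parse_cigar(cs2$alignments$cigar)
  expect_identical(sum(ops$len[ops$op == "X"]), 3L)
})

test_that("reads from the reverse strand of a copy still collapse", {
  refseq <- random_seq(400, 4)
  r <- manual_rroi(refseq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(refseq, 151, 250))))
  cs <- realign_to_reference_copy(
    read_alignments(make_read_row("rc", 0, len = 100, seq = rc)), r)
  expect_identical(nrow(cs$alignments), 1L)
  expect_identical(cs$alignments$ref_start, 150L)
  expect_identical(cs$alignments$orient, "-")
  expect_identical(cs$alignments$seq, substr(refseq, 151, 250))
})

test_that("mostly-unalignable reads are dropped and accounted for", {
  refseq <- random_seq(300, 5)
  r <- manual_rroi(refseq)
  junk <- make_read_row("junk", 0, len = 100, seq = random_seq(100, 987))
  ok <- make_read_row("ok", 0, len = 100, seq = substr(refseq, 1, 100))
  cs <- realign_to_reference_copy(read_alignments(rbind(junk, ok)), r)
  expect_identical(nrow(cs$alignments), 1L)
  expect_identical(sum(cs$dropped), 1L)
  expect_identical(nrow(cs$alignments) + sum(cs$dropped), 2L)
})

test_that("clustered variants near a read end are soft-clipped and invisible downstream", {
  refseq <- random_seq(400, 6)
  r <- manual_rroi(refseq)
  read <- substr(refseq, 101, 200)
  for (p in 92:99) {  # 8 clustered mismatches near the 3' end
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), substr(read, p, p))[1]
  }
  cs <- realign_to_reference_copy(
    read_alignments(make_read_row("clip", 0, len = 100, seq = read)), r)
  expect_gt(cs$alignments$softclip_frac, 0)
  expect_match(cs$alignments$cigar, "S$")
  pu <- build_pileup(cs, r, min_base_quality = 0)
  clipped_ref_pos <- 100L + 92:99 - 1L
  expect_false(any(pu$ref_pos %in% clipped_ref_pos & pu$base != pu$ref_base))
})

test_that("merging conserves alignments and refuses mixed samples", {
  refseq <- random_seq(300, 7)
  r1 <- manual_rroi(refseq, rroi_id = "rrA")
  r2 <- manual_rroi(refseq, rroi_id = "rrB")
  mk <- function(r, n, label) {
    reads <- do.call(rbind, lapply(seq_len(n), function(i)
      make_read_row(sprintf("%s%02d", r$rroi_id, i), 0, len = 80,
                    seq = substr(refseq, 21, 100))))
    cs <- realign_to_reference_copy(read_alignments(reads), r)
    cs$sample_label <- label
    cs
  }
  m <- merge_collapsed(list(mk(r1, 16, "tumor"), mk(r2, 20, "tumor")))
  expect_identical(nrow(m$alignments), 36L)
  expect_identical(sort(unique(m$alignments$rroi_id)), c("rrA", "rrB"))
  expect_error(merge_collapsed(list(mk(r1, 2, "tumor"), mk(r2, 2, "normal"))),
               "mixed sample labels")
  empty <- merge_collapsed(list())
  expect_identical(nrow(empty$alignments), 0L)
})

test_that("collapse reverses the dilution of mutant reads across copies", {
  # mutation on one of 3 *identical* copies: per-locus VAF is diluted to
  # ~v/3, but the collapsed pileup recovers every spiked read
  sg <- synth_genome(1, 3, 400, inter_copy_identity = 1.0, seed = 61)
  rs <- build_rroi_set(sg$bed, sg$genome)
  reads <- simulate_reads(sg, coverage = 30, seed = 62)
  gseq <- as.character(sg$genome[[1]])
  cstart <- sg$copies[sg$copies$family == 1 & sg$copies$copy == 2, ]$start
  ref <- substr(gseq, cstart + 201, cstart + 201)
  specs <- data.frame(family = 1, copy = 2, offset = 200L,
                      alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                      target_reads = 12L)
  sp <- spike_mutations(reads, sg, specs, mid_read_margin = 10, seed = 33)
  expect_identical(sp$truth$achieved, 12L)
  tc <- collapse_sample(sp$reads, rs, "tumor")
  pu <- build_pileup(tc, rs$rrois[[1]])
  truth <- lift_truth(sp$truth, sg, rs)
  col <- pu[pu$ref_pos == truth$ref_pos, ]
  mut <- sum(col$base == truth$alt)
  expect_identical(mut, 12L)                 # every mutant read recovered
  vaf_collapsed <- mut / nrow(col)
  vaf_locus <- truth$achieved / truth$depth  # VAF within the mutated copy
  expect_lt(abs(vaf_collapsed - vaf_locus / 3), 0.06)
})

test_that("collapsed output is deterministic and SAM serialization is stable", {
  b <- small_bench()
  tc1 <- collapse_sample(b$tumor, b$rs, "tumor")
  tc2 <- collapse_sample(b$tumor, b$rs, "tumor")
  expect_identical(tc1$alignments, tc2$alignments)
  f1 <- tempfile(fileext = ".sam")
  f2 <- tempfile(fileext = ".sam")
  write_collapsed_sam(tc1, b$rs, f1)
  write_collapsed_sam(tc2, b$rs, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round-trip through the SAM reader preserves the alignment content
  back <- read_alignments(f1)
  expect_identical(nrow(back), nrow(tc1$alignments))
  expect_setequal(back$qname, tc1$alignments$read_name)
})

test_that("spikes beside clustered copy divergence are clipped away more often than mid-copy spikes", {
  refseq <- random_seq(400, 88)
  div <- refseq
  for (p in 196:199)  # a 4-substitution divergence cluster on the copy
    substr(div, p, p) <- setdiff(c("A", "C", "G", "T"), substr(div, p, p))[1]
  r <- manual_rroi(refseq)
  recovered <- function(spike_pos1) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(div, spike_pos1, spike_pos1))[1]
    starts <- seq(spike_pos1 - 145, spike_pos1 - 5, by = 5)
    starts <- starts[starts >= 1 & starts + 149 <= nchar(div)]
    reads <- do.call(rbind, lapply(seq_along(starts), function(i) {
      s <- substr(div, starts[i], starts[i] + 149)
      substr(s, spike_pos1 - starts[i] + 1, spike_pos1 - starts[i] + 1) <- alt
      data.frame(qname = sprintf("s%03d", i), is_read1 = TRUE, chrom = "c1",
                 pos = starts[i] - 1L, end = starts[i] + 149L, strand = "+",
                 mapq = 0L, cigar = "150M", seq = s, qual = strrep("F", 150),
                 is_duplicate = FALSE)
    }))
    cs <- realign_to_reference_copy(read_alignments(reads), r)
    pu <- build_pileup(cs, r)
    sum(pu$ref_pos == spike_pos1 - 1L & pu$base == alt) / length(starts)
  }
  near_cluster <- recovered(205)   # 6 bp downstream of the cluster
  mid_copy <- recovered(100)       # far from any divergence
  expect_lt(near_cluster, mid_copy)
})
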