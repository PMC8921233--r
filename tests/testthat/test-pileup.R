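# hand-built alignment layouts on an explicit 100 bp reference
REF <- random_seq(100, 811)

base_at <- function(s, pos0) substr(s, pos0 + 1, pos0 + 1)
set_base <- function(s, pos0, b) { substr(s, pos0 + 1, pos0 + 1) <- b; s }
alt_for <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

full_span_layout <- function(names, seqs, qual = 37L, strand = NULL) {
  data.frame(read_name = names, ref_start = 0L, seq = seqs,
             qual_int = qual,
             strand = strand %||% rep_len(c("+", "-"), length(names)),
             stringsAsFactors = FALSE)
}
`%||%` <- repcall:::`%||%`

# tumour with y_t mutant reads at pos 30 (plus optional cis variant at 37),
# control with y_c mutant reads; everything else matches REF
mk_pair <- function(y_t, y_c, n_t = 10L, n_c = 10L, cis_at = integer(0),
                    cis_in_normal = TRUE) {
  alt <- alt_for(base_at(REF, 30))
  t_seqs <- rep(REF, n_t + y_t)
  t_names <- sprintf("t%02d", seq_along(t_seqs))
  for (i in seq_len(y_t)) {
    t_seqs[i] <- set_base(t_seqs[i], 30, alt)
    for (p in cis_at) t_seqs[i] <- set_base(t_seqs[i], p, alt_for(base_at(REF, p)))
  }
  c_seqs <- rep(REF, n_c + y_c)
  c_names <- sprintf("c%02d", seq_along(c_seqs))
  for (i in seq_len(y_c)) c_seqs[i] <- set_base(c_seqs[i], 30, alt)
  if (cis_in_normal && length(cis_at) && n_c >= 2) {
    for (i in (y_c + 1):(y_c + 2)) {
      for (p in cis_at) c_seqs[i] <- set_base(c_seqs[i], p, alt_for(base_at(REF, p)))
    }
  }
  r <- manual_rroi(REF)
  tpu <- build_pileup(manual_collapsed(full_span_layout(t_names, t_seqs)), r)
  cpu <- if (length(c_seqs) == 0L) repcall:::empty_pileup() else
    build_pileup(manual_collapsed(full_span_layout(c_names, c_seqs),
                                  sample = "normal"), r)
  list(rroi = r, tumor = tpu, control = cpu, alt = alt)
}

test_that("pileups respect depth, the quality floor and soft clips", {
  r <- manual_rroi(REF)
  lay <- full_span_layout(sprintf("r%02d", 1:10), rep(REF, 10))
  pu <- build_pileup(manual_collapsed(lay), r)
  expect_identical(sum(pu$ref_pos == 50), 10L)
  expect_identical(sum(pu$base != pu$ref_base), 0L)

  lay$qual_int <- c(10L, rep(37L, 9))      # one read below the Phred-13 floor
  pu2 <- build_pileup(manual_collapsed(lay), r)
  expect_identical(sum(pu2$ref_pos == 50), 9L)

  # a position covered only by soft-clipped bases yields no column
  clip <- data.frame(read_name = "sc1", ref_start = 30L,
                     seq = paste0(strrep("A", 10), substr(REF, 31, 60)),
                     qual_int = 37L, strand = "+", cigar = "10S30=",
                     stringsAsFactors = FALSE)
  pu3 <- build_pileup(manual_collapsed(clip), r)
  expect_identical(sort(unique(pu3$ref_pos)), 30:59)
})

test_that("candidate thresholds are >= 4 tumour and <= 3 control mutant reads", {
  for (case in list(list(y_t = 4L, y_c = 3L, emitted = TRUE),
                    list(y_t = 3L, y_c = 0L, emitted = FALSE),
                    list(y_t = 10L, y_c = 4L, emitted = FALSE),
                    list(y_t = 5L, y_c = 0L, emitted = TRUE))) {
    p <- mk_pair(case$y_t, case$y_c)
    cands <- detect_candidates(p$tumor, p$control)
    expect_identical(nrow(cands), as.integer(case$emitted),
                     label = sprintf("y_t=%d y_c=%d", case$y_t, case$y_c))
    if (case$emitted) {
      expect_identical(cands$y_t, case$y_t)
      expect_identical(cands$y_c, case$y_c)
      expect_identical(cands$alt, p$alt)
      expect_identical(cands$ref_pos, 30L)
    }
  }
})

test_that("candidate detection is invariant under read order", {
  p <- mk_pair(5L, 1L)
  shuf <- p$tumor[sample(nrow(p$tumor)), ]
  a <- detect_candidates(p$tumor, p$control)
  b <- detect_candidates(shuf, p$control)
  b$mutant_read_names <- lapply(b$mutant_read_names, sort)
  a$mutant_read_names <- lapply(a$mutant_read_names, sort)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("positions absent from the control are flagged, not lost", {
  p <- mk_pair(5L, 0L, n_c = 0L)
  cands <- detect_candidates(p$tumor, p$control)
  expect_identical(nrow(cands), 1L)
  expect_identical(cands$y_c, 0L)
  expect_identical(cands$n_c, 0L)
  expect_identical(cands$flags, "low-control-coverage")
})

test_that("mutant reads with a perfect genome hit are discarded in the re-check", {
  p <- mk_pair(5L, 0L)
  cands <- detect_candidates(p$tumor, p$control)
  cs <- manual_collapsed(full_span_layout(
    sprintf("t%02d", 1:15),
    c(rep(set_base(REF, 30, p$alt), 5), rep(REF, 10))))
  cs$alignments$read_name <- sub("/1$", "/1", cs$alignments$read_name)
  # the read names in the pileup follow manual_collapsed's /1 suffix
  expect_true(all(cands$mutant_read_names[[1]] %in% cs$alignments$read_name))

  # genome lacking the alt haplotype: no perfect hits, candidate unchanged
  g1 <- Biostrings::DNAStringSet(c(g1 = paste0(random_seq(50, 5), REF)))
  re1 <- recheck_mutant_reads(cands[1, ], cs, g1)
  expect_identical(re1$status, "candidate")
  expect_identical(re1$y_t, 5L)

  # genome containing the mutant haplotype: every mutant read matches
  # perfectly somewhere -> candidate filtered
  g2 <- Biostrings::DNAStringSet(c(
    g1 = paste0(random_seq(50, 5), REF),
    extra = paste0("ACGT", set_base(REF, 30, p$alt), "TTTT")))
  re2 <- recheck_mutant_reads(cands[1, ], cs, g2)
  expect_identical(re2$y_t, 0L)
  expect_identical(re2$status, "filtered")
  expect_identical(re2$filter_reasons[[1]], "perfect-hit")
})

test_that("cis analysis passes concordant haplotypes seen in the normal", {
  p <- mk_pair(5L, 0L, cis_at = 37L, cis_in_normal = TRUE)
  cand <- detect_candidates(p$tumor, p$control)[1, ]
  res <- analyze_cis_context(cand, p$tumor, p$control)
  expect_identical(res$cand$status, "candidate")
  expect_identical(res$cis$cis_variants$ref_pos, 37L)
  expect_equal(res$cis$concordance, 1.0)
  expect_true(res$cis$observed_in_normal)
  # context-supportive n: reference reads carrying the reference base at 37
  # are NOT consistent with the mutant copy's haplotype
  expect_identical(res$cand$n_t, 0L)
})

test_that("discordant cis haplotypes are filtered", {
  p <- mk_pair(5L, 0L)
  # split mutant reads onto two incompatible haplotypes: 3 carry (37,G-like),
  # 2 carry (52,A-like)
  alt37 <- alt_for(base_at(REF, 37))
  alt52 <- alt_for(base_at(REF, 52))
  tpu <- data.table::copy(p$tumor)
  tpu$base[tpu$read_name %in% c("t01", "t02", "t03") & tpu$ref_pos == 37] <-
    alt37
  tpu$base[tpu$read_name %in% c("t04", "t05") & tpu$ref_pos == 52] <- alt52
  cand <- detect_candidates(tpu, p$control)[1, ]
  res <- analyze_cis_context(cand, tpu, p$control)
  expect_identical(res$cand$status, "filtered")
  expect_identical(res$cand$filter_reasons[[1]], "cis-discordant")
  expect_lt(res$cis$concordance, 0.9)
})

test_that("a cis haplotype unseen in the normal is filtered; empty cis passes", {
  p_abs <- mk_pair(5L, 0L, cis_at = 37L, cis_in_normal = FALSE)
  cand <- detect_candidates(p_abs$tumor, p_abs$control)[1, ]
  res <- analyze_cis_context(cand, p_abs$tumor, p_abs$control)
  expect_identical(res$cand$filter_reasons[[1]], "cis-absent-in-normal")

  p_none <- mk_pair(5L, 0L)   # mutation on a copy identical to the reference
  cand2 <- detect_candidates(p_none$tumor, p_none$control)[1, ]
  res2 <- analyze_cis_context(cand2, p_none$tumor, p_none$control)
  expect_identical(res2$cand$status, "candidate")
  expect_identical(nrow(res2$cis$cis_variants), 0L)
  expect_identical(res2$cand$n_t, 10L)  # all reference reads support context
})

test_that("review filters catch low base quality, strand bias and position bias", {
  # clean candidate: qualities 37, mixed strands, spread cycles
  p <- mk_pair(6L, 0L)
  cand <- detect_candidates(p$tumor, p$control)[1, ]
  dec <- apply_review_filters(cand, p$tumor)
  expect_true(dec$decision$passes)

  # low base quality on the mutant bases only
  alt <- p$alt
  lay <- full_span_layout(sprintf("t%02d", 1:16),
                          c(rep(set_base(REF, 30, alt), 6), rep(REF, 10)),
                          qual = c(rep(14L, 6), rep(37L, 10)))
  tpu_lowq <- build_pileup(manual_collapsed(lay), manual_rroi(REF))
  cand_lowq <- detect_candidates(tpu_lowq, p$control)[1, ]
  dec_lowq <- apply_review_filters(cand_lowq, tpu_lowq)
  expect_identical(dec_lowq$decision$reasons, "low-base-quality")

  # 10 mutant reads all forward at a balanced locus, mutant cycles spread by
  # staggering the read starts so only the strand rule can fire
  stagger <- data.frame(
    read_name = sprintf("t%02d", 1:50),
    ref_start = rep(seq(0L, 20L, by = 5L), 10),
    stringsAsFactors = FALSE)
  stagger$seq <- vapply(seq_len(50), function(i) {
    s <- substr(REF, stagger$ref_start[i] + 1, stagger$ref_start[i] + 80)
    if (i <= 10) s <- set_base(s, 30 - stagger$ref_start[i], alt)
    s
  }, character(1))
  stagger$qual_int <- 37L
  stagger$strand <- c(rep("+", 10), rep_len(c("+", "-"), 40))
  tpu_sb <- build_pileup(manual_collapsed(stagger), manual_rroi(REF))
  cand_sb <- detect_candidates(tpu_sb, p$control)[1, ]
  dec_sb <- apply_review_filters(cand_sb, tpu_sb)
  expect_identical(dec_sb$decision$reasons, "strand-bias")
  # oracle: two-sided Fisher exact p by hypergeometric enumeration over the
  # 2x2 table (10,0 mutant fwd/rev vs 20,20 non-mutant fwd/rev)
  ks <- 0:10
  probs <- stats::dhyper(ks, 10 + 20, 0 + 20, 10 + 0)
  p_obs <- stats::dhyper(10, 30, 20, 10)
  p_enum <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_lt(p_enum, 0.01)
  expect_equal(p_enum,
               stats::fisher.test(matrix(c(10, 0, 20, 20), 2))$p.value,
               tolerance = 1e-6)

  # all mutant bases at the same sequencing cycle (full-span + strand "+"
  # reads put the mutant base at one cycle)
  lay_pb <- full_span_layout(
    sprintf("t%02d", 1:16),
    c(rep(set_base(REF, 30, alt), 6), rep(REF, 10)),
    strand = "+")
  tpu_pb <- build_pileup(manual_collapsed(lay_pb), manual_rroi(REF))
  cand_pb <- detect_candidates(tpu_pb, p$control)[1, ]
  dec_pb <- apply_review_filters(cand_pb, tpu_pb)
  expect_true("position-bias" %in% dec_pb$decision$reasons)
})

test_that("no emitted candidate ever violates the read-count bounds", {
  set.seed(404)
  for (rep in 1:10) {
    y_t <- sample(0:8, 1)
    y_c <- sample(0:6, 1)
    p <- mk_pair(y_t, y_c)
    cands <- detect_candidates(p$tumor, p$control)
    if (nrow(cands)) {
      expect_true(all(cands$y_t >= 4L))
      expect_true(all(cands$y_c <= 3L))
    } else {
      expect_true(y_t < 4L || y_c > 3L)
    }
  }
})
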