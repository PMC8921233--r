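#' Homology-search thresholds for calling a region repetitive
#'
#' A region of interest is repetitive when its sequence aligns to at least
#' two genomic loci (the locus itself included) with at most `max_gaps` gap
#' openings, identity above `min_identity` and a length difference below
#' `max_len_diff`.
#'
#' @param min_identity minimum alignment identity, exclusive (default 0.90).
#' @param max_gaps maximum number of gap openings (default 1).
#' @param max_len_diff maximum fractional length difference, exclusive
#'   (default 0.15).
#' @param min_seed_len minimum region length for the homology search
#'   (default 40 bp); shorter regions are a configuration error.
#' @param word_size exact-match word size used to seed the search.
#' @return list with class `rroi_params`.
#' @export
rroi_params <- function(min_identity = 0.90, max_gaps = 1,
                        max_len_diff = 0.15, min_seed_len = 40,
                        word_size = 16) {
  assert_scalar_number(min_identity, "min_identity", 0, 1)
  assert_scalar_number(max_gaps, "max_gaps", 0)
  assert_scalar_number(max_len_diff, "max_len_diff", 0, 1)
  structure(list(min_identity = min_identity, max_gaps = max_gaps,
                 max_len_diff = max_len_diff, min_seed_len = min_seed_len,
                 word_size = word_size),
            class = "rroi_params")
}

#' Find all genomic copies of a seed region
#'
#' Self-homology search: the seed sequence is aligned against the whole
#' genome (both strands) with a word-seeded gapped aligner, and every locus
#' meeting the repetitiveness thresholds is reported as a `RepeatCopy`,
#' including the seed's own locus (`is_seed_self_hit`). Identity is defined
#' as matches over aligned columns with gaps counted as columns; the gap
#' count is the number of gap openings; the length difference is
#' `|hit span - seed length| / seed length`.
#'
#' @param seed a [genomic_interval()] (0-based half-open).
#' @param genome genome as returned by [load_genome()] (or a FASTA path).
#' @param params an [rroi_params()] object.
#' @return data.frame of accepted copies, ordered by (chrom, start):
#'   chrom, start, end (0-based half-open), strand, identity, gap_count,
#'   length_diff_frac, is_seed_self_hit.
#' @export
find_copies <- function(seed, genome, params = rroi_params()) {
  genome <- load_genome(genome)
  seed_seq <- interval_seq(genome, seed$chrom, seed$start, seed$end)
  L <- nchar(seed_seq)
  if (L < params$min_seed_len)
    stopf("seed region is %d bp, below the minimum search length of %d bp",
          L, params$min_seed_len)

  hits <- data.table::rbindlist(c(
    lapply(names(genome), function(ctg)
      scan_contig_for_copies(seed_seq, ctg, genome[[ctg]], "+", params)),
    lapply(names(genome), function(ctg)
      scan_contig_for_copies(seed_seq, ctg, genome[[ctg]], "-", params))))
  if (nrow(hits) == 0L)
    stopf("internal error: homology search returned no hits (self-hit must exist)")

  # accept thresholds
  hits <- hits[hits$gap_count <= params$max_gaps &
               hits$identity > params$min_identity &
               hits$length_diff_frac < params$max_len_diff, ]
  # collapse overlapping hits on the same contig/strand (keep best identity)
  hits <- dedupe_hits(hits)
  hits$is_seed_self_hit <- hits$chrom == seed$chrom &
    pmin(hits$end, seed$end) - pmax(hits$start, seed$start) >=
      0.5 * (seed$end - seed$start)
  data.table::setorder(hits, chrom, start)
  as.data.frame(hits)
}

#' @noRd
scan_contig_for_copies <- function(seed_seq, contig_name, contig, strand,
                                   params) {
  L <- nchar(seed_seq)
  query <- if (strand == "+") seed_seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed_seq)))
  k <- min(params$word_size, L)
  offsets <- unique(c(seq(1L, L - k + 1L, by = max(1L, k %/% 2L)), L - k + 1L))
  diags <- integer(0)
  for (off in offsets) {
    word <- substr(query, off, off + k - 1L)
    mp <- Biostrings::matchPattern(word, contig)
    if (length(mp)) diags <- c(diags, IRanges::start(mp) - off + 1L)
  }
  if (!length(diags)) return(NULL)
  diags <- sort(diags)
  cl <- cumsum(c(1L, diff(diags) > L %/% 2L))
  starts <- vapply(split(diags, cl), function(d) as.integer(round(stats::median(d))),
                   integer(1))
  pad <- max(20L, ceiling(0.2 * L))
  clen <- length(contig)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    ws <- max(1L, starts[i] - pad)
    we <- min(clen, starts[i] + L - 1L + pad)
    if (we - ws + 1L < params$min_seed_len) next
    win <- as.character(Biostrings::subseq(contig, ws, we))
    aln <- pairwise_align(query, win, type = "global-local",
                          scoring = homology_scoring())
    span_start <- ws + aln$s_start - 1L  # 1-based contig coords
    span_end <- ws + aln$s_end - 1L
    hit_len <- span_end - span_start + 1L
    out[[i]] <- data.table::data.table(
      chrom = contig_name,
      start = span_start - 1L,           # back to 0-based half-open
      end = span_end,
      strand = strand,
      identity = aln$identity,
      gap_count = aln$n_gap_open,
      length_diff_frac = abs(hit_len - L) / L)
  }
  data.table::rbindlist(out)
}

#' @noRd
dedupe_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  data.table::setorder(hits, chrom, start, -identity)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(hits)) {
      if (hits$chrom[j] != hits$chrom[i] || hits$start[j] >= hits$end[i]) break
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov > 0.5 * (hits$end[j] - hits$start[j])) keep[j] <- FALSE
    }
  }
  hits[keep, ]
}

#' Is a region repetitive?
#'
#' A region is repetitive when the homology search returned at least two
#' accepted hits — the self-hit plus one or more additional copies.
#' @param copies data.frame from [find_copies()].
#' @return logical.
#' @export
classify_repetitive <- function(copies) {
  if (nrow(copies) == 0L)
    stopf("internal error: empty copy list (the self-hit must always exist)")
  nrow(copies) >= 2L
}

#' Build a repetitive region of interest (RROI)
#'
#' Designates the seed locus as the single reference copy, extracts its
#' sequence extended by `flank_bp` on each side (truncated at contig ends,
#' with the achieved flanks recorded) and bundles it with the copy table.
#' The flanks prevent the loss of reads overlapping the copy boundaries
#' during realignment.
#'
#' @param seed a [genomic_interval()].
#' @param copies accepted copies from [find_copies()].
#' @param genome genome object or FASTA path.
#' @param flank_bp flank length in bp (default 100).
#' @param rroi_id identifier; defaults to `chrom_start_end` of the seed.
#' @return An object of class `rroi`.
#' @export
build_rroi <- function(seed, copies, genome, flank_bp = 100,
                       rroi_id = NULL) {
  if (flank_bp < 0) stopf("flank_bp must be non-negative")
  if (!classify_repetitive(copies))
    stopf("region %s:%d-%d is not repetitive (single hit)",
          seed$chrom, seed$start, seed$end)
  genome <- load_genome(genome)
  clen <- length(genome[[seed$chrom]])
  fs <- max(0L, seed$start - as.integer(flank_bp))
  fe <- min(clen, seed$end + as.integer(flank_bp))
  flank_left <- seed$start - fs
  flank_right <- fe - seed$end
  structure(list(
    rroi_id = rroi_id %||% sprintf("%s_%d_%d", seed$chrom, seed$start, seed$end),
    seed = seed,
    copies = copies,
    reference_copy = seed,
    flank_bp = as.integer(flank_bp),
    flank_left = as.integer(flank_left),
    flank_right = as.integer(flank_right),
    truncated = flank_left < flank_bp || flank_right < flank_bp,
    reference_sequence = interval_seq(genome, seed$chrom, fs, fe)),
    class = "rroi")
}

#' @export
print.rroi <- function(x, ...) {
  cat(sprintf("<rroi> %s  seed %s:%d-%d  copies: %d  ref seq: %d bp (flanks %d/%d)\n",
              x$rroi_id, x$seed$chrom, x$seed$start, x$seed$end,
              nrow(x$copies), nchar(x$reference_sequence),
              x$flank_left, x$flank_right))
  invisible(x)
}

#' Build the RROI set for a BED of candidate regions
#'
#' Runs the self-homology search for every BED record; repetitive records
#' become RROIs and the rest are listed in a skip report with the reason.
#'
#' @param bed BED file path or data.frame with chrom, start, end and an
#'   optional name column (0-based half-open).
#' @param genome genome object or FASTA path.
#' @param params an [rroi_params()] object.
#' @param flank_bp flank length per RROI (default 100).
#' @return An object of class `rroi_set`: named list of `rroi` objects, a
#'   skip report, and the parameters used.
#' @export
build_rroi_set <- function(bed, genome, params = rroi_params(),
                           flank_bp = 100) {
  genome <- load_genome(genome)
  if (is.character(bed)) bed <- read_bed(bed)
  required <- c("chrom", "start", "end")
  if (!all(required %in% names(bed)))
    stopf("BED input must have columns chrom, start, end")
  if (is.null(bed$name)) bed$name <- rep(NA_character_, nrow(bed))

  rrois <- list()
  skipped <- list()
  for (i in seq_len(nrow(bed))) {
    id <- if (!is.na(bed$name[i]) && nzchar(bed$name[i])) bed$name[i] else
      sprintf("%s_%d_%d", bed$chrom[i], bed$start[i], bed$end[i])
    if (id %in% names(rrois)) stopf("duplicate rroi_id '%s' in BED", id)
    seed <- genomic_interval(bed$chrom[i], bed$start[i], bed$end[i])
    copies <- find_copies(seed, genome, params)
    if (classify_repetitive(copies)) {
      rrois[[id]] <- build_rroi(seed, copies, genome, flank_bp, rroi_id = id)
    } else {
      skipped[[length(skipped) + 1L]] <- data.frame(
        rroi_id = id, chrom = bed$chrom[i], start = bed$start[i],
        end = bed$end[i], reason = "single-hit (not repetitive)",
        stringsAsFactors = FALSE)
    }
  }
  warn_overlapping_rrois(rrois)
  structure(list(
    rrois = rrois,
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(rroi_id = character(), chrom = character(),
                 start = integer(), end = integer(), reason = character()),
    params = params, flank_bp = as.integer(flank_bp),
    version = as.character(utils::packageVersion("repcall"))),
    class = "rroi_set")
}

#' @noRd
warn_overlapping_rrois <- function(rrois) {
  if (length(rrois) < 2L) return(invisible())
  iv <- do.call(rbind, lapply(rrois, function(r)
    data.frame(id = r$rroi_id, chrom = r$seed$chrom,
               start = r$seed$start, end = r$seed$end)))
  gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov))
    warning(sprintf(paste0("%d pair(s) of RROIs overlap; shared reads are ",
                           "processed per RROI and calls deduplicated by ",
                           "genomic position"), length(ov)))
  invisible()
}

#' @export
print.rroi_set <- function(x, ...) {
  cat(sprintf("<rroi_set> %d RROIs, %d regions skipped (thresholds: identity > %.2f, gaps <= %d, len diff < %.2f)\n",
              length(x$rrois), nrow(x$skipped), x$params$min_identity,
              x$params$max_gaps, x$params$max_len_diff))
  invisible(x)
}

#' Write / read an RROI manifest directory
#'
#' The manifest is self-describing plain text: one TSV of copy coordinates
#' per RROI, one FASTA of flanked reference-copy sequences, a skip report
#' and JSON run metadata recording the thresholds and package version.
#' Identical inputs yield byte-identical manifests.
#'
#' @param rroi_set an `rroi_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_rroi_set <- function(rroi_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- Biostrings::DNAStringSet(
    vapply(rroi_set$rrois, function(r) r$reference_sequence, character(1)))
  names(refs) <- vapply(rroi_set$rrois, function(r) r$rroi_id, character(1))
  Biostrings::writeXStringSet(refs, file.path(dir, "reference_copies.fa"))
  for (r in rroi_set$rrois) {
    tab <- cbind(rroi_id = r$rroi_id, r$copies)
    utils::write.table(tab, file.path(dir, paste0(r$rroi_id, ".copies.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(rroi_set$skipped, file.path(dir, "skipped.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(params = unclass(rroi_set$params),
               flank_bp = rroi_set$flank_bp,
               version = rroi_set$version,
               rrois = lapply(rroi_set$rrois, function(r) list(
                 rroi_id = r$rroi_id,
                 seed = as.list(unclass(r$seed)[c("chrom", "start", "end", "strand")]),
                 flank_left = r$flank_left, flank_right = r$flank_right,
                 truncated = r$truncated)))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_rroi_set
#' @param genome genome object or FASTA path (sequences are re-checked
#'   against the stored reference copies on load).
#' @export
read_rroi_set <- function(dir, genome) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"))
  genome <- load_genome(genome)
  rrois <- list()
  for (m in meta$rrois) {
    copies <- utils::read.table(
      file.path(dir, paste0(m$rroi_id, ".copies.tsv")),
      sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    copies$rroi_id <- NULL
    seed <- genomic_interval(m$seed$chrom, m$seed$start, m$seed$end)
    rrois[[m$rroi_id]] <- build_rroi(seed, copies, genome,
                                     flank_bp = meta$flank_bp,
                                     rroi_id = m$rroi_id)
  }
  skipped <- utils::read.table(file.path(dir, "skipped.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  structure(list(rrois = rrois, skipped = skipped,
                 params = do.call(rroi_params, meta$params),
                 flank_bp = meta$flank_bp, version = meta$version),
            class = "rroi_set")
}
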