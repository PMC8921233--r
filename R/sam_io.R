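#' Read-alignment tables
#'
#' Tumour and normal alignments are handled as plain tables with one row per
#' aligned read segment: `qname`, `is_read1`, `chrom`, `pos` (0-based
#' leftmost), `end` (0-based exclusive), `strand`, `mapq`, `cigar`, `seq`
#' (forward-genome orientation, as in SAM), `qual` (Phred+33 string),
#' `is_duplicate`. [read_alignments()] normalizes a data.frame, a SAM text
#' file, or an indexed BAM (via Rsamtools) into this form.
#'
#' @param x data.frame/data.table in the above layout, or a path to a
#'   `.sam`/`.bam` file.
#' @return a `data.table` of read alignments.
#' @export
read_alignments <- function(x) {
  if (is.data.frame(x)) return(normalize_read_table(x))
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("alignment file not found: %s", x)
    if (grepl("\\.sam$", x, ignore.case = TRUE)) return(read_sam(x))
    if (grepl("\\.bam$", x, ignore.case = TRUE)) return(read_bam(x))
    stopf("unrecognized alignment file type: %s", x)
  }
  stopf("alignments must be a data.frame or a SAM/BAM path")
}

#' @noRd
normalize_read_table <- function(df) {
  dt <- data.table::as.data.table(df)
  req <- c("qname", "chrom", "pos", "strand", "mapq", "seq", "qual")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stopf("read table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(dt$is_read1)) dt$is_read1 <- TRUE
  if (is.null(dt$is_duplicate)) dt$is_duplicate <- FALSE
  if (is.null(dt$cigar)) dt$cigar <- paste0(nchar(dt$seq), "M")
  if (is.null(dt$end)) dt$end <- dt$pos + cigar_ref_span(dt$cigar)
  stopifnot(all(nchar(dt$seq) == nchar(dt$qual)))
  dt
}

#' @noRd
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(normalize_read_table(empty_read_table()))
  f <- data.table::as.data.table(
    do.call(rbind, lapply(strsplit(lines, "\t"), `[`, 1:11)))
  flag <- as.integer(f$V2)
  normalize_read_table(data.table::data.table(
    qname = f$V1,
    is_read1 = !bitwAnd(flag, 128L),
    chrom = f$V3,
    pos = as.integer(f$V4) - 1L,
    strand = ifelse(bitwAnd(flag, 16L), "-", "+"),
    mapq = as.integer(f$V5),
    cigar = f$V6,
    seq = f$V10,
    qual = f$V11,
    is_duplicate = bitwAnd(flag, 1024L) > 0L))
}

#' @noRd
read_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("reading BAM requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  normalize_read_table(data.table::data.table(
    qname = b$qname,
    is_read1 = !bitwAnd(flag, 128L),
    chrom = as.character(b$rname),
    pos = b$pos - 1L,
    strand = ifelse(bitwAnd(flag, 16L), "-", "+"),
    mapq = b$mapq,
    cigar = b$cigar,
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    is_duplicate = bitwAnd(flag, 1024L) > 0L))
}

#' @noRd
empty_read_table <- function() {
  data.table::data.table(
    qname = character(), is_read1 = logical(), chrom = character(),
    pos = integer(), end = integer(), strand = character(),
    mapq = integer(), cigar = character(), seq = character(),
    qual = character(), is_duplicate = logical())
}

#' Write a read-alignment table as SAM text
#'
#' @param reads read-alignment table.
#' @param contigs named integer vector of contig lengths for the header.
#' @param path output path.
#' @param paired emit paired-end flags (default TRUE when both mates occur).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, contigs, path, paired = NULL) {
  reads <- normalize_read_table(reads)
  if (is.null(paired)) paired <- any(!reads$is_read1)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  data.table::setorder(reads, chrom, pos)
  flag <- ifelse(paired, 1L + 2L, 0L) +
    ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(paired & reads$is_read1, 64L, 0L) +
    ifelse(paired & !reads$is_read1, 128L, 0L) +
    ifelse(reads$is_duplicate, 1024L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, flag, reads$chrom, reads$pos + 1L,
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}
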