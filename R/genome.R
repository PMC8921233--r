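#' Load a reference genome
#'
#' Accepts a FASTA path or an existing `DNAStringSet` and returns a named
#' `DNAStringSet` (names truncated at the first whitespace, as alignment
#' tools do).
#' @param genome FASTA file path or `DNAStringSet`.
#' @return named `DNAStringSet`.
#' @export
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stopf("genome contigs must be named")
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1L) {
    if (!file.exists(genome)) stopf("genome FASTA not found: %s", genome)
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  stopf("genome must be a FASTA path or a DNAStringSet")
}

#' Construct a genomic interval (0-based, half-open)
#'
#' @param chrom contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand "+" or "-".
#' @return A one-row data.frame with class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  if (end <= start) stopf("interval end (%d) must exceed start (%d)", end, start)
  if (start < 0) stopf("interval start must be >= 0")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  structure(data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(end), strand = strand,
                       stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

#' Extract the sequence of a 0-based half-open interval
#' @noRd
interval_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stopf("contig '%s' not present in the genome", chrom)
  clen <- length(genome[[chrom]])
  if (start < 0 || end > clen)
    stopf("interval %s:%d-%d outside contig bounds (length %d)",
          chrom, start, end, clen)
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end)))
}

#' Read a BED3+ file into a 0-based interval data.frame
#'
#' Uses [rtracklayer::import()] for parsing; coordinates are returned
#' 0-based half-open. A malformed line raises an error naming the file.
#' @param path BED file path.
#' @return data.frame with chrom, start, end, name.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  if (length(readLines(path, warn = FALSE)) == 0L) {
    warning("empty BED file: ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stopf("malformed BED '%s': %s",
                                           path, conditionMessage(e)))
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, stringsAsFactors = FALSE)
}
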