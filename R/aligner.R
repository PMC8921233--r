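#' Aligner scoring parameters
#'
#' Scoring scheme for the gapped aligner used throughout the package. The
#' defaults for read realignment (match +1, mismatch -4, gap open -6, gap
#' extend -1) favour soft-clipping over forcing divergent read ends into the
#' alignment, which is the behaviour the collapsed pileups rely on: clipped
#' bases never enter a pileup column.
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening penalty (positive number, subtracted).
#' @param gap_ext gap extension penalty (positive number, subtracted).
#' @return A list with class `aligner_scoring`.
#' @export
aligner_scoring <- function(match = 1, mismatch = -4, gap_open = 6,
                            gap_ext = 1) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "aligner_scoring")
}

#' Scoring used for the self-homology (copy finding) search: tolerant of the
#' ~10% divergence allowed between repeat copies.
#' @rdname aligner_scoring
#' @export
homology_scoring <- function() aligner_scoring(match = 2, mismatch = -3,
                                               gap_open = 5, gap_ext = 2)

#' Gapped alignment of queries against a single subject sequence
#'
#' The aligner contract: deterministic gapped alignment reporting, per query,
#' the aligned spans, a CIGAR-like operation string (`S`oft-clip, `=` match,
#' `X` mismatch, `I`nsertion, `D`eletion), match/mismatch/gap tallies and the
#' soft-clip fraction. `type = "local"` is used for read realignment (ends
#' may be clipped); `type = "global-local"` aligns the whole query against a
#' local window of the subject and is used by the homology search, where
#' identity must reflect full-length divergence.
#'
#' Backed by the package's compiled affine-gap dynamic-programming aligner
#' (full Smith-Waterman with traceback); scores agree with
#' [Biostrings::pairwiseAlignment()] under the same scoring scheme.
#'
#' @param queries character vector or `DNAStringSet` of query sequences
#'   (ACGT alphabet).
#' @param subject single subject sequence (character or `DNAString`).
#' @param type `"local"` or `"global-local"`.
#' @param scoring an [aligner_scoring()] object.
#' @return A `data.table` with one row per query: `query_id`, `q_len`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (1-based, aligned spans),
#'   `score`, `n_match`, `n_mismatch`, `n_gap_open`, `n_gap_cols`,
#'   `aligned_cols`, `identity` (matches / aligned columns, gaps counted as
#'   columns), `cigar`, `clip_left`, `clip_right`, `softclip_frac`.
#' @export
pairwise_align <- function(queries, subject,
                           type = c("local", "global-local"),
                           scoring = aligner_scoring()) {
  type <- match.arg(type)
  queries <- as.character(queries)
  if (length(queries) == 0L) return(empty_alignment_table())
  subject <- as.character(subject)
  mode <- if (type == "local") 0L else 1L
  raw <- .sw_align(queries, subject, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_ext, mode)
  qlen <- nchar(queries)
  clip_left <- pmax(0L, raw$q_start - 1L)
  clip_right <- ifelse(raw$q_end > 0L, qlen - raw$q_end, qlen)
  cigar <- paste0(
    ifelse(clip_left > 0L, paste0(clip_left, "S"), ""),
    raw$cigar,
    ifelse(clip_right > 0L, paste0(clip_right, "S"), ""))
  data.table::data.table(
    query_id = seq_along(queries), q_len = qlen,
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = raw$s_start, s_end = raw$s_end, score = raw$score,
    n_match = raw$n_match, n_mismatch = raw$n_mismatch,
    n_gap_open = raw$n_gap_open, n_gap_cols = raw$n_gap_cols,
    aligned_cols = raw$aligned_cols, cigar = cigar,
    clip_left = clip_left, clip_right = clip_right,
    softclip_frac = (clip_left + clip_right) / qlen,
    identity = raw$n_match / pmax(1L, raw$aligned_cols))
}

#' @noRd
empty_alignment_table <- function() {
  data.table::data.table(
    query_id = integer(), q_len = integer(), q_start = integer(),
    q_end = integer(), s_start = integer(), s_end = integer(),
    score = numeric(), n_match = integer(), n_mismatch = integer(),
    n_gap_open = integer(), n_gap_cols = integer(), aligned_cols = integer(),
    cigar = character(), clip_left = integer(), clip_right = integer(),
    softclip_frac = numeric(), identity = numeric())
}

#' Parse a CIGAR-like string into an operation table
#' @param cigar single CIGAR string using ops S,=,X,M,I,D.
#' @return data.table with columns `op`, `len`.
#' @noRd
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([SMIDX=])", cigar, perl = TRUE)[[1]]
  parts <- regmatches(cigar, list(m))[[1]]
  data.table::data.table(
    op = sub("^\\d+", "", parts),
    len = as.integer(sub("[SMIDX=]$", "", parts)))
}

#' Reference span consumed by a CIGAR string
#' @noRd
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
  }, integer(1), USE.NAMES = FALSE)
}
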