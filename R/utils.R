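#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internal draws do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  invisible(x)
}

#' Round to a number of significant figures for display
#'
#' Matches the reporting style of the burden summaries (2 significant
#' figures); full precision is retained in the underlying fields.
#' @noRd
signif2 <- function(x, digits = 2) signif(x, digits)

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
other_bases <- function(base) DNA_BASES[DNA_BASES != base]

#' @noRd
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Phred string <-> integer vectors (Sanger +33 encoding)
#' @noRd
phred_to_int <- function(qual) as.integer(charToRaw(qual)) - 33L

#' @noRd
int_to_phred <- function(q) rawToChar(as.raw(q + 33L))
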