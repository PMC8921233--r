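#' Sample the Beta posterior of a mutant allele frequency
#'
#' With a uniform prior, observing `y` mutant reads and `n` non-mutant
#' context-supportive reads gives the posterior
#' `MAF | y, n ~ Beta(y + 1, n + 1)`. Draws are i.i.d. and reproducible for
#' a given seed.
#'
#' @param y mutant read count (>= 0).
#' @param n non-mutant context-supportive coverage (>= 0).
#' @param M number of Monte-Carlo draws (>= 1).
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return numeric vector of `M` draws in \[0, 1\].
#' @export
sample_maf_posterior <- function(y, n, M, seed = NULL) {
  assert_scalar_number(y, "y", 0)
  assert_scalar_number(n, "n", 0)
  assert_scalar_number(M, "M", 1)
  if (is.null(seed)) stats::rbeta(M, y + 1, n + 1)
  else with_seed(seed, stats::rbeta(M, y + 1, n + 1))
}

#' Monte-Carlo posterior probability that the tumour MAF exceeds the control
#'
#' Draws `M` paired samples from the tumour posterior
#' `Beta(y_t + 1, n_t + 1)` and the control posterior
#' `Beta(y_c + 1, n_c + 1)` and estimates
#' `Pr[MAF_t > MAF_c]` as the fraction of pairs where the tumour draw is
#' strictly greater (floating-point ties count as non-exceedance). A
#' candidate is classified `somatic` when the probability reaches the 0.95
#' threshold and `potentially_germline` (to be discarded) below it.
#'
#' @param y_t,n_t tumour mutant reads and context-supportive coverage.
#' @param y_c,n_c control mutant reads and context-supportive coverage.
#' @param M Monte-Carlo sample count (default 10000, giving a standard
#'   error of at most 0.005 near the decision boundary).
#' @param seed integer seed (default 20210829).
#' @param threshold classification threshold (default 0.95; a probability
#'   exactly at the threshold is somatic).
#' @return object of class `posterior_result`: `prob`, `M`, `seed`,
#'   `classification`, `mc_standard_error`.
#' @export
prob_tumor_exceeds_control <- function(y_t, n_t, y_c, n_c, M = 10000,
                                       seed = 20210829, threshold = 0.95) {
  for (v in c("y_t", "n_t", "y_c", "n_c"))
    assert_scalar_number(get(v), v, 0)
  assert_scalar_number(M, "M", 1)
  prob <- with_seed(seed, {
    maf_t <- stats::rbeta(M, y_t + 1, n_t + 1)
    maf_c <- stats::rbeta(M, y_c + 1, n_c + 1)
    mean(maf_t > maf_c)
  })
  structure(list(
    prob = prob, M = as.integer(M), seed = as.integer(seed),
    classification = if (prob >= threshold) "somatic" else
      "potentially_germline",
    mc_standard_error = sqrt(prob * (1 - prob) / M)),
    class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("<posterior_result> Pr[MAF_t > MAF_c] = %.4f (+/- %.4f, M = %d, seed = %d) -> %s\n",
              x$prob, x$mc_standard_error, x$M, x$seed, x$classification))
  invisible(x)
}

#' Exact probability that one Beta variate exceeds another
#'
#' Deterministic numerical-integration oracle for the Monte-Carlo estimate:
#' `Pr(X > Y)` with `X ~ Beta(y_t + 1, n_t + 1)` and
#' `Y ~ Beta(y_c + 1, n_c + 1)`, computed as the integral of
#' `f_X(x) * F_Y(x)` over \[0, 1\] to an absolute error below 1e-8.
#'
#' @inheritParams prob_tumor_exceeds_control
#' @return probability in \[0, 1\].
#' @export
exact_prob_oracle <- function(y_t, n_t, y_c, n_c) {
  f <- function(x) stats::dbeta(x, y_t + 1, n_t + 1) *
    stats::pbeta(x, y_c + 1, n_c + 1)
  r <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-10,
                        subdivisions = 500L)
  if (r$message != "OK" || r$abs.error > 1e-8)
    stopf("integration did not converge (error %.3g)", r$abs.error)
  min(1, max(0, r$value))
}

#' Load a panel of normals
#'
#' Accepts a TSV with columns chrom, pos (1-based), ref, alt, carriers,
#' panel_size, or a VCF with AC/AN INFO fields (read via VariantAnnotation).
#'
#' @param path file path, or a data.frame already in the TSV layout.
#' @return object of class `panel_of_normals` (a keyed data.table).
#' @export
read_pon <- function(path) {
  if (is.data.frame(path)) {
    pon <- data.table::as.data.table(path)
  } else if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stopf("reading a VCF panel requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    info <- VariantAnnotation::info(v)
    ac <- vapply(info$AC, function(x) as.integer(x[1]), integer(1))
    pon <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
      carriers = ac,
      panel_size = as.integer(info$AN))
  } else {
    pon <- data.table::as.data.table(
      utils::read.table(path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE))
  }
  req <- c("chrom", "pos", "ref", "alt", "carriers", "panel_size")
  miss <- setdiff(req, names(pon))
  if (length(miss)) stopf("panel of normals lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(pon$carriers > pon$panel_size | pon$carriers < 0)
  if (length(bad))
    stopf("malformed panel record %s:%d %s>%s (carriers %d of %d)",
          pon$chrom[bad[1]], pon$pos[bad[1]], pon$ref[bad[1]],
          pon$alt[bad[1]], pon$carriers[bad[1]], pon$panel_size[bad[1]])
  data.table::setkey(pon, chrom, pos, alt)
  structure(pon, class = c("panel_of_normals", class(pon)))
}

#' Filter a candidate against a panel of normals
#'
#' Germline variants under-covered in the matched normal recur across
#' unrelated normal genomes; a candidate whose (locus, alt) is carried by
#' more than `max_carriers` panel members is filtered with reason
#' `panel-of-normals`.
#'
#' @param cand one-row candidate table carrying genomic coordinates
#'   (`chrom`, `genome_pos` 1-based) as added by the pipeline.
#' @param pon a `panel_of_normals` from [read_pon()].
#' @param max_carriers maximum tolerated carriers (default 0).
#' @return the updated candidate.
#' @export
apply_panel_of_normals <- function(cand, pon, max_carriers = 0) {
  if (is.null(pon)) return(cand)
  hit <- pon[pon$chrom == cand$chrom & pon$pos == cand$genome_pos &
             pon$alt == cand$alt, ]
  if (nrow(hit) && any(hit$carriers > max_carriers))
    cand <- fail_candidate(cand, "panel-of-normals")
  cand
}

#' Simulate a cohort of clear somatic and clear germline candidates
#'
#' Generates read-count configurations for benchmarking the germline
#' classifier. Somatic candidates draw a tumour VAF uniformly from
#' `vaf_range` and carry its expected mutant-read count at `coverage`
#' context-supportive reads, with zero mutant reads in the control;
#' germline candidates carry the same expected count in both samples.
#' Using expected counts makes every configuration unambiguous ("clear"),
#' so classification errors measure the stability of the Monte-Carlo
#' posterior itself rather than binomial sampling noise in the cohort.
#'
#' @param n_somatic,n_germline cohort sizes.
#' @param coverage per-sample context-supportive coverage (default 30).
#' @param vaf_range tumour VAF range (default 0.2-0.5).
#' @param seed RNG seed.
#' @return data.frame with y_t, n_t, y_c, n_c, vaf and truth
#'   ("somatic"/"germline").
#' @export
simulate_classifier_cohort <- function(n_somatic, n_germline, coverage = 30,
                                       vaf_range = c(0.2, 0.5), seed = 1) {
  with_seed(seed, {
    v_s <- stats::runif(n_somatic, vaf_range[1], vaf_range[2])
    v_g <- stats::runif(n_germline, vaf_range[1], vaf_range[2])
    y_s <- pmax(1L, as.integer(round(coverage * v_s)))
    y_g <- pmax(1L, as.integer(round(coverage * v_g)))
    data.frame(
      y_t = c(y_s, y_g),
      n_t = coverage - c(y_s, y_g),
      y_c = c(rep(0L, n_somatic), y_g),
      n_c = c(rep(coverage, n_somatic), coverage - y_g),
      vaf = c(v_s, v_g),
      truth = rep(c("somatic", "germline"), c(n_somatic, n_germline)),
      stringsAsFactors = FALSE)
  })
}
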