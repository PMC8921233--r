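#' Pipeline run configuration
#'
#' Collects every input path/object and tunable threshold of the caller.
#' All thresholds are exposed; the defaults are the calling conditions used
#' throughout the package documentation.
#'
#' @param genome reference genome (FASTA path or DNAStringSet).
#' @param tumor,normal read alignments ([read_alignments()] inputs).
#' @param rroi_set prebuilt `rroi_set`, or NULL to build from `bed`.
#' @param bed BED of candidate regions (used when `rroi_set` is NULL).
#' @param pon optional panel of normals ([read_pon()] input).
#' @param out optional output prefix; writes `<out>.calls.tsv`,
#'   `<out>.somatic.vcf` and `<out>.run.json`.
#' @param min_identity,max_gaps,max_len_diff,flank RROI thresholds.
#' @param min_tumor_reads,max_control_reads candidate thresholds (4 / 3).
#' @param min_base_quality pileup base-quality floor (Phred 13).
#' @param bq_min mean mutant base-quality cutoff (Phred 20).
#' @param concordance_min cis concordance minimum (0.9).
#' @param min_normal_cis_reads control support per cis variant (2).
#' @param strand_p,strand_frac,pos_window_frac bias-rule parameters.
#' @param posterior_threshold somatic classification threshold (0.95).
#' @param M Monte-Carlo sample count (10000).
#' @param max_pon_carriers panel-of-normals carrier tolerance (0).
#' @param max_softclip realignment drop threshold (0.5).
#' @param seed run-level seed; each candidate's posterior uses a seed
#'   derived from it reproducibly.
#' @return list with class `run_config`.
#' @export
run_config <- function(genome, tumor, normal, rroi_set = NULL, bed = NULL,
                       pon = NULL, out = NULL,
                       min_identity = 0.90, max_gaps = 1,
                       max_len_diff = 0.15, flank = 100,
                       min_tumor_reads = 4, max_control_reads = 3,
                       min_base_quality = 13, bq_min = 20,
                       concordance_min = 0.9, min_normal_cis_reads = 2,
                       strand_p = 0.01, strand_frac = 0.9,
                       pos_window_frac = 0.1,
                       posterior_threshold = 0.95, M = 10000,
                       max_pon_carriers = 0, max_softclip = 0.5,
                       seed = 1) {
  if (is.null(rroi_set) && is.null(bed))
    stopf("either a prebuilt rroi_set or a BED must be supplied")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full somatic caller on a tumour/normal pair
#'
#' Executes collapse, pileup, candidate detection, the mutant-read genome
#' re-check, in-cis haplotype analysis, review filters, the beta-binomial
#' Monte-Carlo germline posterior and the panel-of-normals filter, in that
#' order. Every candidate is retained in the candidate table with its first
#' failing reason; only somatic-classified calls enter the VCF. Calls from
#' overlapping RROIs are deduplicated by the genomic position of the
#' reference copy.
#'
#' @param config a [run_config()].
#' @return list with class `pipeline_result`: `candidates` (full table),
#'   `somatic` (passing subset), `rroi_set`, `counters`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(methods::is(config, "run_config"))
  genome <- load_genome(config$genome)
  rroi_set <- config$rroi_set %||% build_rroi_set(
    config$bed, genome,
    rroi_params(min_identity = config$min_identity,
                max_gaps = config$max_gaps,
                max_len_diff = config$max_len_diff),
    flank_bp = config$flank)
  pon <- if (!is.null(config$pon)) read_pon(config$pon) else NULL

  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))

  tcol <- stage("collapse-tumor",
                collapse_sample(config$tumor, rroi_set, "tumor",
                                max_softclip = config$max_softclip))
  ncol_ <- stage("collapse-normal",
                 collapse_sample(config$normal, rroi_set, "normal",
                                 max_softclip = config$max_softclip))
  tpu <- stage("pileup-tumor",
               build_pileup_set(tcol, rroi_set, config$min_base_quality))
  npu <- stage("pileup-normal",
               build_pileup_set(ncol_, rroi_set, config$min_base_quality))
  cands <- stage("detect-candidates",
                 detect_candidates(tpu, npu, config$min_tumor_reads,
                                   config$max_control_reads))

  counters <- list(
    rrois = length(rroi_set$rrois),
    tumor_alignments = nrow(tcol$alignments),
    normal_alignments = nrow(ncol_$alignments),
    tumor_dropped = as.list(tcol$dropped),
    normal_dropped = as.list(ncol_$dropped),
    candidates = nrow(cands))

  out_rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    cand <- stage("recheck", recheck_mutant_reads(
      cand, tcol, genome, config$min_tumor_reads))
    if (cand$status == "candidate") {
      res <- stage("cis-analysis", analyze_cis_context(
        cand, tpu, npu, config$concordance_min,
        config$min_normal_cis_reads))
      cand <- res$cand
      cand$cis <- cis_string(res$cis)
    } else cand$cis <- ""
    if (cand$status == "candidate") {
      rev <- stage("review-filters", apply_review_filters(
        cand, tpu, config$bq_min, config$strand_p, config$strand_frac,
        config$pos_window_frac))
      cand <- rev$cand
    }
    if (cand$status == "candidate") {
      post <- prob_tumor_exceeds_control(
        cand$y_t, cand$n_t, cand$y_c, cand$n_c, M = config$M,
        seed = (config$seed + i) %% .Machine$integer.max,
        threshold = config$posterior_threshold)
      cand$prob <- post$prob
      cand$posterior_seed <- post$seed
      if (post$classification == "somatic") cand$status <- "somatic"
      else cand <- fail_candidate(cand, "potentially-germline")
    } else {
      cand$prob <- NA_real_
      cand$posterior_seed <- NA_integer_
    }
    cand <- add_genomic_coords(cand, rroi_set)
    if (cand$status == "somatic" && !is.null(pon)) {
      cand <- apply_panel_of_normals(cand, pon, config$max_pon_carriers)
      if (length(cand$filter_reasons[[1]])) cand$status <- "filtered"
    }
    out_rows[[i]] <- cand
  }
  cands <- data.table::rbindlist(out_rows)
  if (nrow(cands)) {
    # overlapping RROIs can report the same genomic event twice
    dup <- duplicated(paste(cands$chrom, cands$genome_pos, cands$alt,
                            cands$status))
    cands <- cands[!dup, ]
  }
  somatic <- cands[cands$status == "somatic", ]
  counters$filtered <- nrow(cands) - nrow(somatic)
  counters$somatic <- nrow(somatic)

  result <- structure(list(candidates = cands, somatic = somatic,
                           rroi_set = rroi_set, counters = counters,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out)) write_pipeline_outputs(result, genome)
  result
}

#' @noRd
cis_string <- function(cis) {
  if (nrow(cis$cis_variants) == 0L) return("")
  paste(sprintf("%d%s", cis$cis_variants$ref_pos, cis$cis_variants$base),
        collapse = ",")
}

#' @noRd
add_genomic_coords <- function(cand, rroi_set) {
  r <- rroi_set$rrois[[cand$rroi_id]]
  cand$chrom <- r$seed$chrom
  # 1-based genomic position of the collapsed coordinate on the reference copy
  cand$genome_pos <- r$seed$start + (cand$ref_pos - r$flank_left) + 1L
  cand
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d RROI(s), %d candidate(s), %d somatic call(s)\n",
              x$counters$rrois, x$counters$candidates, x$counters$somatic))
  if (nrow(x$somatic))
    print(x$somatic[, c("rroi_id", "chrom", "genome_pos", "ref_base", "alt",
                        "y_t", "n_t", "y_c", "n_c", "prob")])
  invisible(x)
}

#' Flatten a candidate table for TSV serialization
#' @noRd
flatten_candidates <- function(cands) {
  out <- data.table::copy(cands)
  out$mutant_read_names <- vapply(out$mutant_read_names, paste,
                                  character(1), collapse = ",")
  out$filter_reasons <- vapply(out$filter_reasons, function(r)
    if (length(r)) r[1] else "", character(1))
  data.table::setnames(out, "filter_reasons", "first_filter_reason")
  out
}

#' @noRd
write_pipeline_outputs <- function(result, genome) {
  prefix <- result$config$out
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(flatten_candidates(result$candidates),
                     paste0(prefix, ".calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_vcf(result$somatic, result$rroi_set, paste0(prefix, ".somatic.vcf"),
            config = result$config)
  meta <- result$counters
  meta$seed <- result$config$seed
  meta$version <- as.character(utils::packageVersion("repcall"))
  jsonlite::write_json(meta, paste0(prefix, ".run.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(prefix)
}

#' Write somatic calls as VCF 4.2
#'
#' Positions are 1-based on the reference-copy locus; since the true source
#' copy of a collapsed call is unidentifiable by construction, the call is
#' anchored to the reference copy and the copy multiplicity is carried in
#' INFO/NCOPIES.
#'
#' @param calls somatic call table from [run_pipeline()].
#' @param rroi_set the `rroi_set` used.
#' @param path output path.
#' @param config optional `run_config` whose digest is embedded in the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, rroi_set, path, config = NULL) {
  contigs <- unique(vapply(rroi_set$rrois, function(r) r$seed$chrom,
                           character(1)))
  digest <- if (!is.null(config))
    sprintf("##repcall_config=seed=%d,M=%d,posterior_threshold=%g,min_tumor_reads=%d,max_control_reads=%d",
            config$seed, config$M, config$posterior_threshold,
            config$min_tumor_reads, config$max_control_reads) else NULL
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=repcall-%s", utils::packageVersion("repcall")),
    digest,
    sprintf("##contig=<ID=%s>", contigs),
    '##INFO=<ID=RROI,Number=1,Type=String,Description="Repetitive region of interest">',
    '##INFO=<ID=NCOPIES,Number=1,Type=Integer,Description="Number of collapsed copies">',
    '##INFO=<ID=YT,Number=1,Type=Integer,Description="Tumor mutant reads">',
    '##INFO=<ID=NT,Number=1,Type=Integer,Description="Tumor context-supportive coverage">',
    '##INFO=<ID=YC,Number=1,Type=Integer,Description="Control mutant reads">',
    '##INFO=<ID=NC,Number=1,Type=Integer,Description="Control context-supportive coverage">',
    '##INFO=<ID=PP,Number=1,Type=Float,Description="Pr[MAF_t > MAF_c]">',
    '##INFO=<ID=CIS,Number=1,Type=String,Description="In-cis variants (collapsed coordinates)">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    if (any(!calls$ref_base %in% DNA_BASES))
      stopf("call at a position without a reference base")
    ncopies <- vapply(calls$rroi_id, function(id)
      nrow(rroi_set$rrois[[id]]$copies), integer(1))
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tRROI=%s;NCOPIES=%d;YT=%d;NT=%d;YC=%d;NC=%d;PP=%s;CIS=%s",
      calls$chrom, calls$genome_pos, calls$ref_base, calls$alt,
      calls$rroi_id, ncopies, calls$y_t, calls$n_t, calls$y_c, calls$n_c,
      format(calls$prob, digits = 6),
      ifelse(nzchar(calls$cis), calls$cis, "."))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Cohort mutational-burden summary
#'
#' Rates are computed exactly and displayed to 2 significant figures. When
#' a count of excluded mutations is given (e.g. calls concentrated in a
#' single candidate driver locus), a recount without them is included.
#'
#' @param n_mutations total somatic mutations.
#' @param n_cases number of cases.
#' @param mb_per_case megabases of repetitive sequence analyzed per case.
#' @param excluded optional number of mutations to exclude in the recount.
#' @return object of class `burden_summary`.
#' @export
report_burden <- function(n_mutations, n_cases, mb_per_case,
                          excluded = NULL) {
  assert_scalar_number(n_mutations, "n_mutations", 0)
  assert_scalar_number(n_cases, "n_cases", 1)
  assert_scalar_number(mb_per_case, "mb_per_case", 1e-12)
  if (!is.null(excluded) && excluded > n_mutations)
    stopf("excluded (%d) exceeds n_mutations (%d)", excluded, n_mutations)
  res <- list(
    n_mutations = n_mutations, n_cases = n_cases,
    mb_per_case = mb_per_case,
    mutations_per_case = n_mutations / n_cases,
    mutations_per_mb = n_mutations / (n_cases * mb_per_case))
  if (!is.null(excluded)) {
    res$excluded <- excluded
    res$recount_mutations_per_mb <-
      (n_mutations - excluded) / (n_cases * mb_per_case)
  }
  structure(res, class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf("<burden_summary> %d mutations / %d cases (%.2g Mb each): %.2g per case, %.2g per Mb\n",
              x$n_mutations, x$n_cases, x$mb_per_case,
              signif2(x$mutations_per_case), signif2(x$mutations_per_mb)))
  if (!is.null(x$excluded))
    cat(sprintf("  excluding %d: %.2g per Mb\n", x$excluded,
                signif2(x$recount_mutations_per_mb)))
  invisible(x)
}

#' Mutation density by mapping quality
#'
#' The QC view motivating the whole approach: binning the genome by the
#' average mapping quality of its reads and counting somatic mutations per
#' megabase in each bin shows whether a call set is blind to low-mapq
#' (repetitive) territory.
#'
#' @param mean_mapq mapping quality (0-60) of the reads covering each
#'   mutation (one value per mutation).
#' @param territory_mb megabases of genome per bin.
#' @param breaks bin breaks over \[0, 60\] (default every 10; bins are
#'   left-closed, last bin closed).
#' @return data.frame with bin, n_mutations, territory_mb, density
#'   (mutations per Mb; NA where the territory is empty).
#' @export
mapq_density_histogram <- function(mean_mapq, territory_mb,
                                   breaks = seq(0, 60, by = 10)) {
  if (length(mean_mapq) && (min(mean_mapq) < 0 || max(mean_mapq) > 60))
    stopf("mapping qualities must lie in [0, 60]")
  nb <- length(breaks) - 1L
  if (length(territory_mb) != nb)
    stopf("territory_mb must have one entry per bin (%d)", nb)
  idx <- cut(mean_mapq, breaks, right = FALSE, include.lowest = TRUE,
             labels = FALSE)
  idx[mean_mapq >= breaks[nb + 1L]] <- nb  # close the last bin at 60
  counts <- tabulate(idx, nbins = nb)
  data.frame(
    bin = sprintf("[%g,%g%s", breaks[-length(breaks)], breaks[-1],
                  c(rep(")", nb - 1L), "]")),
    n_mutations = counts,
    territory_mb = territory_mb,
    density = ifelse(territory_mb > 0, counts / territory_mb, NA_real_))
}
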