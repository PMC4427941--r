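# Robust chromosome-21 z-scores for unenriched versus
# methylation-depleted (MCIp-enriched) cell-free DNA samples, anchored
# on a known-euploid reference panel.

#' Chromosome-21 read fraction per sample
#'
#' `counts(chr21) / sum(counts)` over all included chromosomes, per
#' sample and treatment.
#'
#' @param counts Long table with `sample_id`, `treatment`, `chrom`,
#'   `count` (and optionally `euploid_known`), or a named numeric
#'   vector of per-chromosome counts for a single sample.
#' @param target_chrom Chromosome of interest (default `"chr21"`).
#' @return data.table per sample/treatment with `chr21_fraction`, or a
#'   single fraction for a named vector input.
#' @export
chr21_fraction <- function(counts, target_chrom = "chr21") {
  if (is.numeric(counts) && !is.null(names(counts))) {
    if (any(counts < 0)) stop_("negative counts")
    tot <- sum(counts)
    if (tot <= 0) stop_("zero total count")
    return(unname(sum(counts[names(counts) == target_chrom]) / tot))
  }
  dt <- as.data.table(counts)
  stopifnot(all(c("sample_id", "treatment", "chrom", "count") %in% names(dt)))
  if (any(dt$count < 0)) stop_("negative counts")
  keep_known <- "euploid_known" %in% names(dt)
  out <- dt[, {
    tot <- sum(count)
    if (tot <= 0) stop_("zero total count for sample '%s' (%s)", sample_id[1], treatment[1])
    res <- list(chr21_fraction = sum(count[chrom == target_chrom]) / tot)
    if (keep_known) res$euploid_known <- euploid_known[1]
    res
  }, by = .(sample_id, treatment)]
  out[]
}

#' Robust euploid-anchored z-scores
#'
#' Within each treatment stratum independently, the median and the
#' median absolute deviation (MAD) of the chromosome-21 fraction are
#' computed over known-euploid samples only, and every sample in the
#' stratum is scored as `z = (fraction - median) / MAD`. The MAD is the
#' raw median of absolute deviations from the median (no 1.4826
#' normal-consistency factor), matching the robust z formula as
#' printed; `scaled_mad = TRUE` selects the scaled variant. By
#' construction the median z over the known euploids of a stratum is
#' exactly 0.
#'
#' @param counts Long count table as in [chr21_fraction()], with an
#'   `euploid_known` logical column.
#' @param target_chrom Chromosome of interest.
#' @param scaled_mad Apply the 1.4826 consistency factor.
#' @return A `zscore_result` data.table: `sample_id`, `treatment`,
#'   `euploid_known`, `chr21_fraction`, `z`.
#' @export
robust_z <- function(counts, target_chrom = "chr21", scaled_mad = FALSE) {
  dt <- as.data.table(counts)
  if (!"euploid_known" %in% names(dt))
    stop_("counts need an 'euploid_known' column")
  fr <- chr21_fraction(dt, target_chrom)
  out <- fr[, {
    eu <- chr21_fraction[euploid_known == TRUE]
    if (length(eu) < 3L)
      stop_("treatment stratum '%s' has fewer than 3 known-euploid samples", treatment[1])
    med <- median(eu)
    mad0 <- median(abs(eu - med)) * if (scaled_mad) 1.4826 else 1
    if (mad0 == 0)
      stop_("zero MAD among known euploids in treatment stratum '%s'", treatment[1])
    .(sample_id = sample_id, euploid_known = euploid_known,
      chr21_fraction = chr21_fraction, z = (chr21_fraction - med) / mad0)
  }, by = treatment]
  setcolorder(out, c("sample_id", "treatment", "euploid_known",
                     "chr21_fraction", "z"))
  setattr(out, "class", c("zscore_result", class(data.table())))
  out[]
}

#' Per-sample z-score enrichment fold
#'
#' For samples measured under both treatments, the ratio of the
#' enriched to the unenriched z-score. The fold of a sample with a
#' zero unenriched z is undefined (`NA`). The summary (mean and range)
#' is taken over `samples` when given, otherwise over all samples with
#' a finite fold.
#'
#' @param zscores A `zscore_result` with treatments `"unenriched"` and
#'   `"enriched"`.
#' @param samples Optional sample ids over which to summarise (e.g.
#'   the confirmed trisomy samples).
#' @return List with `per_sample` (table incl. `fold`), `mean_fold`,
#'   `range_fold`.
#' @export
enrichment_fold <- function(zscores, samples = NULL) {
  dt <- as.data.table(zscores)
  wide <- dcast(dt, sample_id ~ treatment, value.var = "z")
  if (!all(c("unenriched", "enriched") %in% names(wide)))
    stop_("zscores must contain both 'unenriched' and 'enriched' treatments")
  wide <- wide[!is.na(unenriched) & !is.na(enriched)]
  wide[, fold := fifelse(unenriched != 0, enriched / unenriched, NA_real_)]
  if (any(is.na(wide$fold)))
    warning("fold undefined for sample(s) with zero unenriched z")
  sub <- if (is.null(samples)) wide[is.finite(fold)] else wide[sample_id %in% samples]
  list(per_sample = wide[],
       mean_fold = mean(sub$fold, na.rm = TRUE),
       range_fold = if (nrow(sub)) range(sub$fold, na.rm = TRUE) else c(NA_real_, NA_real_))
}
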