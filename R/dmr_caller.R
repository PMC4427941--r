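# Differentially methylated region calling between two sample groups:
# per-site group summary statistics, a Welch t-statistic per CpG site,
# |t| filtering, proximity grouping into DMRs, and annotation of the
# resulting calls against genomic feature sets.

#' Per-site summary statistics for a sample group
#'
#' The mean and standard deviation of the per-sample methylation
#' fractions are computed for each CpG site covered (at
#' `>= min_coverage` reads) in at least `min_samples` samples. The
#' standard deviation uses the n-1 denominator.
#'
#' @param methylomes List of at least two `methylome` objects.
#' @param min_coverage Per-sample coverage floor for a fraction to count.
#' @param min_samples Minimum covering samples for a site to be emitted.
#' @return data.table with `chrom`, `pos`, `n`, `mean`, `sd`.
#' @export
group_site_stats <- function(methylomes, min_coverage = 1L, min_samples = 2L) {
  if (length(methylomes) < 2L)
    stop_("a sample group needs at least 2 samples (got %d)", length(methylomes))
  per <- rbindlist(lapply(methylomes, site_levels))
  per <- per[coverage >= min_coverage]
  out <- per[, .(n = .N, mean = mean(level), sd = sd(level)), by = .(chrom, pos)]
  out <- out[n >= min_samples]
  setkey(out, chrom, pos)
  out[]
}

#' Welch t-statistic per CpG site between two groups
#'
#' `t = (mean_A - mean_B) / sqrt(sd_A^2/n_A + sd_B^2/n_B)`, oriented so
#' that positive values mean higher methylation in group A. Sites
#' missing in either group, or with fewer than two samples in either,
#' are skipped (a message reports how many). When both groups have zero
#' variance the statistic is 0 if the means agree and a signed infinite
#' sentinel otherwise, so that maximally separated constant sites pass
#' any finite |t| threshold rather than being dropped.
#'
#' @param stats_a,stats_b Tables from [group_site_stats()].
#' @return data.table with `chrom`, `pos`, `t_stat`, `diff_`
#'   (`mean_A - mean_B`), sorted by `chrom`, `pos`.
#' @export
site_t <- function(stats_a, stats_b) {
  a <- as.data.table(stats_a)
  b <- as.data.table(stats_b)
  m <- merge(a[, .(chrom, pos, na = n, ma = mean, sa = sd)],
             b[, .(chrom, pos, nb = n, mb = mean, sb = sd)],
             by = c("chrom", "pos"))
  skipped <- nrow(a) + nrow(b) - 2L * nrow(m)
  usable <- m$na >= 2L & m$nb >= 2L & !is.na(m$sa) & !is.na(m$sb)
  skipped <- skipped + sum(!usable)
  if (skipped > 0L)
    message(sprintf("site_t: skipped %d site(s) missing or with <2 samples in a group", skipped))
  m <- m[usable]
  d <- m$ma - m$mb
  se <- sqrt(m$sa^2 / m$na + m$sb^2 / m$nb)
  t_val <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  out <- data.table(chrom = m$chrom, pos = m$pos, t_stat = t_val, diff_ = d)
  setorder(out, chrom, pos)
  out[]
}

#' Remove sites with a sub-threshold |t|
#'
#' Retains exactly the sites with `|t| >= t_min`; a site at the
#' threshold is kept (the removal rule is strict `|t| < t_min`).
#'
#' @param tstats Table from [site_t()].
#' @param t_min Absolute t threshold (default 5).
#' @return Filtered table, same columns.
#' @export
filter_sites <- function(tstats, t_min = 5) {
  dt <- as.data.table(tstats)
  dt[abs(t_stat) >= t_min]
}

#' Group filtered CpG sites into differentially methylated regions
#'
#' Consecutive surviving sites on the same chromosome are grouped while
#' the distance between successive CpG anchor positions is strictly
#' below `max_gap`; with `same_sign` (the default) a sign change in the
#' mean difference also closes the group. Groups with at least
#' `min_cpg` sites are reported as DMRs spanning the first member
#' position through the last member position + 2 (half-open, covering
#' the final CpG dinucleotide).
#'
#' @param filtered Table from [filter_sites()], sorted by chrom, pos.
#' @param max_gap Strict upper bound on the gap between members (bp).
#' @param min_cpg Minimum member CpG sites per DMR.
#' @param same_sign Split groups at sign changes of the difference.
#' @return A `dmr_set` data.table: `chrom`, `start`, `end`, `n_cpg`,
#'   `direction` (`hyper_in_A` / `hyper_in_B`), `mean_diff`,
#'   `mean_abs_t` (over finite member t), `member_positions` (list).
#' @export
call_dmrs <- function(filtered, max_gap = 300L, min_cpg = 9L, same_sign = TRUE) {
  dt <- as.data.table(filtered)
  if (nrow(dt) == 0L) return(empty_dmr_set())
  if (anyDuplicated(rle(dt$chrom)$values) ||
      dt[, is.unsorted(pos), by = chrom][, any(V1)])
    stop_("input sites must be sorted by chromosome then position")
  new_chrom <- c(TRUE, dt$chrom[-1] != dt$chrom[-nrow(dt)])
  gap_break <- c(TRUE, diff(dt$pos) >= max_gap) & !new_chrom
  gap_break[1] <- FALSE
  sgn <- sign(dt$diff_)
  sign_break <- if (same_sign) c(FALSE, sgn[-1] != sgn[-length(sgn)]) & !new_chrom
                else rep(FALSE, nrow(dt))
  dt[, gid := cumsum(new_chrom | gap_break | sign_break)]
  dmrs <- dt[, {
    ft <- t_stat[is.finite(t_stat)]
    .(chrom = chrom[1], start = pos[1], end = pos[.N] + 2L, n_cpg = .N,
      direction = if (diff_[1] > 0) "hyper_in_A" else "hyper_in_B",
      mean_diff = mean(diff_),
      mean_abs_t = if (length(ft)) mean(abs(ft)) else Inf,
      member_positions = list(pos))
  }, by = gid][n_cpg >= min_cpg]
  dmrs[, gid := NULL]
  setorder(dmrs, chrom, start)
  as_dmr_set(dmrs)
}

empty_dmr_set <- function() {
  as_dmr_set(data.table(chrom = character(), start = integer(), end = integer(),
                        n_cpg = integer(), direction = character(),
                        mean_diff = numeric(), mean_abs_t = numeric(),
                        member_positions = list()))
}

as_dmr_set <- function(dt) {
  setattr(dt, "class", c("dmr_set", class(data.table())))
  dt[]
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("<dmr_set> %d DMRs (%d hyper_in_A, %d hyper_in_B)\n",
              nrow(x), sum(x$direction == "hyper_in_A"),
              sum(x$direction == "hyper_in_B")))
  if (nrow(x)) print(as.data.table(x)[, .(chrom, start, end, n_cpg, direction)],
                     topn = 3, nrows = 6)
  invisible(x)
}

#' Annotate DMRs against genomic feature sets
#'
#' For each feature set, the fraction of DMRs with at least 1 bp of
#' overlap (half-open convention: touching only at a boundary does not
#' count). If `genes` is supplied, DMRs are additionally partitioned
#' into intragenic (overlapping a gene) and intergenic.
#'
#' @param dmrs A `dmr_set`.
#' @param feature_sets Named list of `region_set`s.
#' @param genes Optional gene `region_set` for the partition.
#' @return List with `overlap` (named fractions), `n_dmrs`, and when
#'   genes are given, `intragenic` / `intergenic` fractions.
#' @export
annotate_dmrs <- function(dmrs, feature_sets, genes = NULL) {
  dt <- as.data.table(dmrs)
  res <- vapply(feature_sets, function(fs) {
    if (nrow(dt) == 0L) return(NA_real_)
    mean(overlaps_any_region(dt, regions_dt(fs)))
  }, numeric(1))
  out <- list(overlap = res, n_dmrs = nrow(dt))
  if (!is.null(genes)) {
    intra <- if (nrow(dt)) mean(overlaps_any_region(dt, regions_dt(genes))) else NA_real_
    out$intragenic <- intra
    out$intergenic <- 1 - intra
  }
  out
}

#' Fraction of one DMR set overlapped by another
#'
#' The fraction of regions in `dmrs_a` having at least 1 bp overlap
#' with any region in `dmrs_b`. Undefined (NA, with a warning) when
#' `dmrs_a` is empty.
#'
#' @param dmrs_a,dmrs_b DMR sets (or any half-open interval tables).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
dmr_overlap <- function(dmrs_a, dmrs_b) {
  a <- as.data.table(dmrs_a)
  b <- as.data.table(dmrs_b)
  if (nrow(a) == 0L) {
    warning("empty query DMR set; overlap fraction undefined")
    return(NA_real_)
  }
  mean(overlaps_any_region(a, b))
}

#' Write DMRs as BED6+
#'
#' Score is the mean |t| over finite member statistics, capped at 1000
#' as BED requires; columns beyond the sixth carry `n_cpg` and
#' `mean_diff`.
#'
#' @param dmrs A `dmr_set`.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dt <- as.data.table(dmrs)
  out <- dt[, .(chrom, start, end,
                name = sprintf("dmr_%05d", .I),
                score = round(pmin(ifelse(is.finite(mean_abs_t), mean_abs_t, 1000), 1000), 2),
                strand = ".", n_cpg, mean_diff = round(mean_diff, 4))]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
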