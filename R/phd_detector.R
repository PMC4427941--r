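# Megabase-scale placenta hypomethylated domain (PHD) detection:
# 50 kbp genome binning with per-group methylation, CpG and gene
# density, contiguous-run domain calling, and density-stratified
# differential methylation with a descriptive loess smooth.

#' Bin the genome and summarise methylation, CpG and gene density
#'
#' Bins tile each chromosome half-open from 0 in steps of `bin_size`
#' (the last bin of a chromosome may be short). Each group's bin mean
#' is the unweighted mean of the per-site group means whose anchor
#' position falls in the bin, undefined (NA) when fewer than
#' `min_sites_per_bin` sites are present. `cpg_count` counts CpG loci
#' per bin; `gene_count` counts gene intervals overlapping the bin, so
#' a long gene may be counted in several bins.
#'
#' @param group_levels Named list of site-level tables (one per group,
#'   e.g. from [group_mean_levels()]).
#' @param cpg_positions Table with `chrom`, `pos` of all CpG loci.
#' @param chrom_sizes Table with `chrom`, `length`.
#' @param genes Optional gene `region_set`.
#' @param bin_size Bin width in bp (default 50,000).
#' @param min_sites_per_bin Minimum sites for a defined bin mean.
#' @return A `genomic_bins` data.table: `chrom`, `start`, `end`,
#'   `cpg_count`, `gene_count`, and `mean_<group>` / `n_<group>`
#'   columns per group.
#' @export
bin_genome <- function(group_levels, cpg_positions, chrom_sizes, genes = NULL,
                       bin_size = 50000L, min_sites_per_bin = 1L) {
  sizes <- as.data.table(chrom_sizes)
  stopifnot(all(c("chrom", "length") %in% names(sizes)))
  cpg <- as.data.table(cpg_positions)
  known <- sizes$chrom
  for (nm in names(group_levels)) {
    bad <- setdiff(unique(group_levels[[nm]]$chrom), known)
    if (length(bad)) stop_("unknown chromosome '%s' in group '%s'", bad[1], nm)
  }
  if (length(setdiff(unique(cpg$chrom), known)))
    stop_("unknown chromosome in CpG positions")

  bins <- sizes[, {
    s <- seq(0L, length - 1L, by = bin_size)
    .(start = as.integer(s), end = as.integer(pmin(s + bin_size, length)))
  }, by = chrom]
  bins[, bin_id := .I]

  bin_index <- function(ch, p) {
    key <- paste0(ch, ":", p %/% bin_size * bin_size)
    match(key, paste0(bins$chrom, ":", bins$start))
  }
  cc <- tabulate(bin_index(cpg$chrom, cpg$pos), nbins = nrow(bins))
  bins[, cpg_count := cc]

  if (!is.null(genes)) {
    gdt <- regions_dt(genes)
    gc <- integer(nrow(bins))
    for (ch in unique(bins$chrom)) {
      bi <- which(bins$chrom == ch)
      gi <- which(gdt$chrom == ch)
      if (length(gi) == 0L) next
      gc[bi] <- IRanges::countOverlaps(
        half_open_to_iranges(bins$start[bi], bins$end[bi]),
        half_open_to_iranges(gdt$start[gi], gdt$end[gi]))
    }
    bins[, gene_count := gc]
  } else bins[, gene_count := 0L]

  for (nm in names(group_levels)) {
    lv <- as.data.table(group_levels[[nm]])
    bi <- bin_index(lv$chrom, lv$pos)
    agg <- data.table(bin = bi, level = lv$level)[, .(m = mean(level), k = .N), by = bin]
    mcol <- rep(NA_real_, nrow(bins)); ncol_ <- integer(nrow(bins))
    mcol[agg$bin] <- agg$m; ncol_[agg$bin] <- agg$k
    mcol[ncol_ < min_sites_per_bin] <- NA_real_
    bins[, paste0("mean_", nm) := mcol]
    bins[, paste0("n_", nm) := ncol_]
  }
  setattr(bins, "class", c("genomic_bins", class(data.table())))
  setattr(bins, "groups", names(group_levels))
  setattr(bins, "bin_size", as.integer(bin_size))
  bins[]
}

#' Call contiguous hypomethylated domains
#'
#' A bin qualifies when both group means are defined, the reference
#' mean exceeds the target mean by at least `delta`, and the bin holds
#' at least `min_cpg_per_bin` CpG loci. Maximal runs of consecutive
#' qualifying bins (no gap tolerance) of length `>= min_run` become
#' domains; domain-level means weight member bins by their CpG count.
#'
#' @param bins A `genomic_bins` table.
#' @param target_group,reference_group Group names, e.g. `"placenta"`
#'   and `"non_pregnant_ccf"`.
#' @param delta Minimum per-bin hypomethylation (fraction, > 0).
#' @param min_run Minimum consecutive qualifying bins (default 10,
#'   i.e. 500 kbp at the default bin size).
#' @param min_cpg_per_bin Minimum CpG loci per qualifying bin.
#' @return A `phd_set` data.table: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_meth_target`, `mean_meth_reference`.
#' @export
call_phds <- function(bins, target_group, reference_group, delta = 0.15,
                      min_run = 10L, min_cpg_per_bin = 10L) {
  if (!is.numeric(delta) || delta <= 0) stop_("delta must be > 0")
  dt <- as.data.table(bins)
  tc <- paste0("mean_", target_group); rc <- paste0("mean_", reference_group)
  if (!all(c(tc, rc) %in% names(dt)))
    stop_("bins lack means for the requested groups")
  tm <- dt[[tc]]; rm_ <- dt[[rc]]
  qual <- !is.na(tm) & !is.na(rm_) & (rm_ - tm >= delta) &
    dt$cpg_count >= min_cpg_per_bin
  dt[, qual := qual]
  dt[, run_id := rleid(chrom, qual)]
  doms <- dt[qual == TRUE, .(
    chrom = chrom[1], start = start[1], end = end[.N], n_bins = .N,
    mean_meth_target = weighted.mean(get(tc), w = cpg_count),
    mean_meth_reference = weighted.mean(get(rc), w = cpg_count)
  ), by = run_id][n_bins >= min_run]
  doms[, run_id := NULL]
  setorder(doms, chrom, start)
  setattr(doms, "class", c("phd_set", class(data.table())))
  doms[]
}

#' @export
print.phd_set <- function(x, ...) {
  tot <- sum(as.numeric(x$end - x$start))
  cat(sprintf("<phd_set> %d domains covering %.2f Mbp\n", nrow(x), tot / 1e6))
  invisible(x)
}

#' Differential methylation stratified by CpG density
#'
#' Bins with defined means in both groups are stratified by their CpG
#' count; per stratum the bin count and the mean target-minus-reference
#' difference are reported (negative values indicate hypomethylation of
#' the target group). A loess fit of the difference on CpG count is
#' returned as a descriptive smoothed curve; it plays no role in
#' domain calling.
#'
#' @param bins A `genomic_bins` table.
#' @param target_group,reference_group Group names.
#' @param breaks CpG-count breakpoints defining the strata.
#' @param span Loess span (default 0.3).
#' @return List with `table` (stratum, n_bins, mean_diff, mean_target,
#'   mean_reference) and `curve` (`cpg_count`, `fitted`).
#' @export
density_stratified_diff <- function(bins, target_group, reference_group,
                                    breaks, span = 0.3) {
  dt <- as.data.table(bins)
  tc <- paste0("mean_", target_group); rc <- paste0("mean_", reference_group)
  ok <- dt[!is.na(get(tc)) & !is.na(get(rc)),
           .(cpg_count, tm = get(tc), rm_ = get(rc))]
  if (nrow(ok) == 0L) stop_("no bins with defined means in both groups")
  ok[, diff_ := tm - rm_]
  strat <- cut(ok$cpg_count, breaks = breaks, include.lowest = TRUE, right = FALSE)
  tab <- data.table(stratum = factor(levels(strat), levels = levels(strat)))
  agg <- ok[, .(n_bins = .N, mean_diff = mean(diff_), mean_target = mean(tm),
                mean_reference = mean(rm_)), by = .(stratum = strat)]
  tab <- merge(tab, agg, by = "stratum", all.x = TRUE, sort = FALSE)
  tab[is.na(n_bins), n_bins := 0L]
  fit <- loess(diff_ ~ cpg_count, data = ok, span = span, degree = 2)
  grid <- sort(unique(ok$cpg_count))
  curve <- data.table(cpg_count = grid,
                      fitted = predict(fit, newdata = data.frame(cpg_count = grid)))
  list(table = tab[], curve = curve[])
}

#' Fraction of DMRs falling inside hypomethylated domains
#'
#' @param dmrs A `dmr_set` (typically the hypomethylated, autosomal
#'   subset).
#' @param phds A `phd_set`.
#' @return Fraction of DMRs with >= 1 bp overlap to any domain, or `NA`
#'   (with a warning) when the DMR set is empty.
#' @export
dmr_phd_overlap <- function(dmrs, phds) {
  a <- as.data.table(dmrs)
  if (nrow(a) == 0L) {
    warning("empty DMR set; overlap fraction undefined")
    return(NA_real_)
  }
  mean(overlaps_any_region(a, as.data.table(phds)))
}
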