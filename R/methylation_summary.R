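# Global and regional methylation summaries: per-context levels,
# 1%-bin histograms, low/intermediate/high site classification,
# region profiles with matched random background, group correlation.

#' Per-site methylation levels of one sample
#'
#' Returns `meth / (meth + unmeth)` for every included call of the
#' requested context with coverage of at least one read.
#'
#' @param m A `methylome`.
#' @param context Cytosine context to extract (default CpG).
#' @return data.table with `chrom`, `pos`, `level`, `coverage`.
#' @export
site_levels <- function(m, context = "CpG") {
  stopifnot(inherits(m, "methylome"))
  keep <- m$calls$included & m$calls$context == context &
    (m$calls$meth + m$calls$unmeth) > 0L
  m$calls[which(keep),
          .(chrom, pos, level = meth / (meth + unmeth),
            coverage = meth + unmeth)]
}

#' Global methylation per cytosine context
#'
#' Pooled-count methylation `sum(meth) / sum(meth + unmeth)` over
#' included sites, per context. Contexts with no covered sites are
#' reported as `NA` (undefined), not 0.
#'
#' @param m A `methylome`.
#' @return Named numeric vector over `CpG`, `CHG`, `CHH`.
#' @export
context_methylation <- function(m) {
  stopifnot(inherits(m, "methylome"))
  keep <- m$calls$included & (m$calls$meth + m$calls$unmeth) > 0L
  agg <- m$calls[which(keep),
                 .(rate = sum(meth) / sum(meth + unmeth)), by = context]
  out <- setNames(rep(NA_real_, length(VALID_CONTEXTS)), VALID_CONTEXTS)
  out[agg$context] <- agg$rate
  out
}

#' Mean per-site methylation across a sample group
#'
#' The group level at a site is the unweighted mean of the per-sample
#' methylation fractions (not a pooled-count fraction, which would
#' weight deeply covered samples). A site enters only if covered in at
#' least `min_samples` samples.
#'
#' @param methylomes List of `methylome` objects from one group.
#' @param min_samples Minimum number of covering samples per site.
#' @param context Cytosine context (default CpG).
#' @return data.table with `chrom`, `pos`, `level` (group mean) and `n`
#'   (number of covering samples), keyed by `chrom`, `pos`.
#' @export
group_mean_levels <- function(methylomes, min_samples = 1L, context = "CpG") {
  if (length(methylomes) == 0L) stop_("empty sample group")
  per <- rbindlist(lapply(methylomes, site_levels, context = context))
  out <- per[, .(level = mean(level), n = .N), by = .(chrom, pos)][n >= min_samples]
  setkey(out, chrom, pos)
  out[]
}

#' Classify sites into low / intermediate / high methylation
#'
#' Low is strictly below `low_cut`, high strictly above `high_cut`;
#' the intermediate class is the closed interval between them, so
#' levels exactly at a cutoff are intermediate.
#'
#' @param levels Numeric vector of mean levels in `[0, 1]`, or a table
#'   with a `level` column.
#' @param low_cut,high_cut Class boundaries (defaults 0.20 and 0.75).
#' @return Named fractions `low`, `intermediate`, `high`, summing to 1.
#' @export
classify_sites <- function(levels, low_cut = 0.20, high_cut = 0.75) {
  if (low_cut >= high_cut) stop_("low_cut must be below high_cut")
  x <- if (is.data.frame(levels)) levels[["level"]] else levels
  if (length(x) == 0L) stop_("no sites to classify")
  c(low = mean(x < low_cut),
    intermediate = mean(x >= low_cut & x <= high_cut),
    high = mean(x > high_cut))
}

#' Methylation histogram with 1% bins
#'
#' Levels fall into 100 half-open bins `[k%, (k+1)%)`; a level of
#' exactly 100% is assigned to the last bin. Proportions sum to 1.
#'
#' @inheritParams classify_sites
#' @return A `meth_histogram`: list with `bin_width` (percent),
#'   `proportions` (length 100), `counts`, `n_sites`.
#' @export
histogram_1pct <- function(levels) {
  x <- if (is.data.frame(levels)) levels[["level"]] else levels
  if (length(x) == 0L) stop_("cannot histogram an empty level set")
  if (any(x < 0 | x > 1)) stop_("levels must lie in [0, 1]")
  idx <- pmin(floor(x * 100), 99)
  counts <- tabulate(idx + 1L, nbins = 100L)
  structure(list(bin_width = 1, proportions = counts / length(x),
                 counts = counts, n_sites = length(x)),
            class = "meth_histogram")
}

#' @export
print.meth_histogram <- function(x, ...) {
  cat(sprintf("<meth_histogram> %d sites in 100 x %g%% bins; mass in [75,100]: %.3f\n",
              x$n_sites, x$bin_width, sum(x$proportions[76:100])))
  invisible(x)
}

#' Methylation profile of a region set with matched random background
#'
#' Returns the group mean levels of CpG sites inside the regions
#' ("enriched") together with the levels of an equally sized random
#' sample of CpG sites located strictly outside the regions
#' ("unenriched"). Sampling is uniform without replacement and seeded,
#' so a fixed seed reproduces the background exactly.
#'
#' @param mean_levels Site-level table (e.g. from [group_mean_levels()]).
#' @param regions A `region_set`.
#' @param seed Integer seed for the background sample.
#' @return List with numeric vectors `enriched` and `unenriched` of
#'   identical length.
#' @export
region_profile <- function(mean_levels, regions, seed = 1L) {
  dt <- as.data.table(mean_levels)
  rdt <- regions_dt(regions)
  if (nrow(rdt) == 0L) stop_("region set is empty")
  inside <- points_in_region(dt$chrom, dt$pos, rdt)
  n_in <- sum(inside)
  if (n_in == 0L) stop_("no CpG sites fall inside the regions")
  pool <- which(!inside)
  if (length(pool) < n_in)
    stop_("not enough CpG sites outside the regions to match the enriched set (%d needed, %d available)",
          n_in, length(pool))
  picked <- local_seed(seed, pool[sample.int(length(pool), n_in)])
  list(enriched = dt$level[inside], unenriched = dt$level[picked])
}

#' Pearson correlation of two group methylomes
#'
#' Computed over the intersection of sites. Requires at least two shared
#' sites; zero variance in either vector is undefined and reported as
#' `NA` with a warning.
#'
#' @param mean_levels_a,mean_levels_b Site-level tables with `chrom`,
#'   `pos`, `level`.
#' @return Pearson r, or `NA` if undefined.
#' @export
group_correlation <- function(mean_levels_a, mean_levels_b) {
  a <- as.data.table(mean_levels_a)
  b <- as.data.table(mean_levels_b)
  shared <- merge(a[, .(chrom, pos, la = level)], b[, .(chrom, pos, lb = level)],
                  by = c("chrom", "pos"))
  if (nrow(shared) < 2L) stop_("fewer than 2 shared sites")
  if (var(shared$la) == 0 || var(shared$lb) == 0) {
    warning("zero variance in one of the level vectors; correlation undefined")
    return(NA_real_)
  }
  cor(shared$la, shared$lb)
}
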