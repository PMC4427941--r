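# Cell-free DNA fragment statistics: length distributions, the
# long/short methylation fold-ratio per cytosine context, MCIp
# paired-read filtering and size-fraction comparison, and
# short-fragment enrichment in regulatory region sets.

#' Fragment length histogram and modal length
#'
#' Counts per 1 bp length bin plus the modal length; ties are broken
#' toward the smallest length.
#'
#' @param fs A `fragment_set` (or a table with a `length` column).
#' @return List with `hist` (data.table `length`, `count`) and
#'   `modal_length`.
#' @export
length_histogram <- function(fs) {
  len <- fragment_lengths(fs)
  if (length(len) == 0L) stop_("no fragments")
  h <- data.table(length = len)[, .(count = .N), by = length]
  setorder(h, length)
  list(hist = h[], modal_length = h$length[which.max(h$count)])
}

fragment_lengths <- function(fs) {
  if (inherits(fs, "fragment_set")) fs$fragments$length
  else as.data.table(fs)$length
}

#' Methylation fold-ratio of long versus short fragments
#'
#' Per cytosine context, the per-cytosine methylation rate in long
#' fragments (`length > cutoff`) divided by the rate in short fragments.
#' Fragments of exactly `cutoff` bp fall in the short class by default
#' (`boundary = "short"`); `boundary = "drop"` excludes them, mirroring
#' a strict `<`/`>` split. Contexts with an empty size class or a zero
#' short-fragment rate are undefined (`NA`).
#'
#' @param fs A `fragment_set`.
#' @param cutoff Length cutoff in bp (default 200).
#' @param boundary How to treat fragments of exactly `cutoff` bp.
#' @return data.table per context: call counts, rates and `fold_ratio`.
#' @export
methylation_by_length <- function(fs, cutoff = 200L,
                                  boundary = c("short", "drop")) {
  stopifnot(inherits(fs, "fragment_set"))
  boundary <- match.arg(boundary)
  calls <- merge(fs$calls, fs$fragments[, .(frag_id, length)], by = "frag_id")
  calls[, size_class := fifelse(length > cutoff, "long",
                         fifelse(length < cutoff, "short",
                                 if (boundary == "short") "short" else NA_character_))]
  calls <- calls[!is.na(size_class)]
  agg <- calls[, .(n = .N, n_meth = sum(meth)), by = .(context, size_class)]
  out <- dcast(agg, context ~ size_class, value.var = c("n", "n_meth"), fill = 0L)
  for (cl in c("n_long", "n_short", "n_meth_long", "n_meth_short"))
    if (!cl %in% names(out)) out[, (cl) := 0L]
  out[, rate_long := fifelse(n_long > 0, n_meth_long / n_long, NA_real_)]
  out[, rate_short := fifelse(n_short > 0, n_meth_short / n_short, NA_real_)]
  out[, fold_ratio := fifelse(!is.na(rate_long) & !is.na(rate_short) & rate_short > 0,
                              rate_long / rate_short, NA_real_)]
  setorder(out, context)
  out[]
}

#' Filter MCIp paired reads
#'
#' Discards pairs whose mates map to different chromosomes and pairs
#' with a size above `max_size` (500 bp by default). Size is the
#' distance between the start sites of the two paired-end reads; a
#' negative size on a concordant pair indicates mis-ordered mates and
#' is an error.
#'
#' @param pairs Table with `chrom1`, `start1`, `chrom2`, `start2`.
#' @param max_size Maximum retained pair size in bp.
#' @return List with `kept` (pairs plus `size`) and `discarded`
#'   (named tally: `oversize`, `discordant`).
#' @export
mcip_pair_filter <- function(pairs, max_size = 500L) {
  dt <- as.data.table(pairs)
  stopifnot(all(c("chrom1", "start1", "chrom2", "start2") %in% names(dt)))
  discordant <- dt$chrom1 != dt$chrom2
  conc <- dt[!discordant]
  size <- conc$start2 - conc$start1
  if (any(size < 0)) stop_("negative pair size: mates are mis-ordered")
  conc[, size := size]
  kept <- conc[size <= max_size]
  list(kept = kept[],
       discarded = c(oversize = sum(size > max_size), discordant = sum(discordant)))
}

#' Compare MCIp size fractions
#'
#' For the unmethylated and methylated capture fractions, the
#' proportion of fragments longer than `threshold` bp, and their fold
#' difference (methylated over unmethylated). The fold is undefined
#' when the unmethylated proportion is zero.
#'
#' @param unmeth,meth `fragment_set`s (or tables with `length`).
#' @param threshold Length threshold in bp (default 300).
#' @return List with per-fraction summaries (`n`, `proportion_gt`),
#'   `threshold` and `fold`.
#' @export
fraction_size_comparison <- function(unmeth, meth, threshold = 300L) {
  lu <- fragment_lengths(unmeth); lm <- fragment_lengths(meth)
  if (length(lu) == 0L || length(lm) == 0L)
    stop_("both size fractions must be non-empty")
  pu <- mean(lu > threshold); pm <- mean(lm > threshold)
  fold <- if (pu > 0) pm / pu else {
    warning("unmethylated proportion is zero; fold undefined")
    NA_real_
  }
  list(unmethylated = list(n = length(lu), proportion_gt = pu),
       methylated = list(n = length(lm), proportion_gt = pm),
       threshold = threshold, fold = fold)
}

#' Short-fragment proportion within region sets
#'
#' A fragment belongs to a region set when its midpoint
#' (`floor((start + end)/2)`, half-open membership) falls inside one of
#' the set's intervals. For each region set, and for the genome
#' overall, the proportion of member fragments shorter than `cutoff`
#' bp is reported; sets with no member fragments are undefined (`NA`).
#'
#' @param fs A `fragment_set`.
#' @param region_sets Named list of `region_set`s.
#' @param cutoff Short-fragment cutoff in bp (default 100; strict `<`).
#' @return data.table: `region_set`, `n_fragments`, `prop_short`.
#' @export
short_fragment_region_enrichment <- function(fs, region_sets, cutoff = 100L) {
  stopifnot(inherits(fs, "fragment_set"))
  fr <- fs$fragments
  mid <- fr$start + (fr$end - fr$start) %/% 2L
  rows <- lapply(names(region_sets), function(nm) {
    member <- points_in_region(fr$chrom, mid, region_sets[[nm]])
    n <- sum(member)
    data.table(region_set = nm, n_fragments = n,
               prop_short = if (n > 0) mean(fr$length[member] < cutoff) else NA_real_)
  })
  genome <- data.table(region_set = "genome", n_fragments = nrow(fr),
                       prop_short = if (nrow(fr)) mean(fr$length < cutoff) else NA_real_)
  rbindlist(c(rows, list(genome)))
}
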