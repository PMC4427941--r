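# Input/output for per-cytosine methylation calls, BED region sets,
# bedGraph tracks and cell-free DNA fragment tables, plus the
# forward-strand collapse of CpG calls.

VALID_CONTEXTS <- c("CpG", "CHG", "CHH")

#' Construct a sample methylome
#'
#' A methylome holds one sample's per-cytosine methylation calls as a
#' `data.table` with columns `chrom`, `pos` (0-based forward-strand
#' coordinate), `strand`, `context` (`CpG`, `CHG` or `CHH`), `meth`,
#' `unmeth`, `tri` (trinucleotide, `"."` when unknown) and `included`
#' (whether the call meets the coverage floor and enters statistics).
#'
#' @param calls data.frame/data.table of calls (see Details).
#' @param sample_id Sample identifier.
#' @param group Sample group label, e.g. `"placenta"` or
#'   `"non_pregnant_ccf"`.
#' @param min_coverage Minimum read coverage (`meth + unmeth`) for a call
#'   to be flagged `included`. Calls below the floor are retained but
#'   excluded from statistics.
#' @param collapsed Whether CpG calls are already strand-collapsed.
#' @return An object of class `methylome`.
#' @export
methylome <- function(calls, sample_id = "sample", group = "custom",
                      min_coverage = 1L, collapsed = FALSE) {
  calls <- as.data.table(calls)
  required <- c("chrom", "pos", "strand", "context", "meth", "unmeth")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols))
    stop_("methylome calls lack column(s): %s", paste(missing_cols, collapse = ", "))
  if (!"tri" %in% names(calls)) calls[, tri := "."]
  bad_ctx <- setdiff(unique(calls$context), VALID_CONTEXTS)
  if (length(bad_ctx))
    stop_("unknown cytosine context: %s", paste(bad_ctx, collapse = ", "))
  if (nrow(calls) && (any(calls$meth < 0) || any(calls$unmeth < 0)))
    stop_("negative methylation counts")
  calls[, `:=`(pos = as.integer(pos), meth = as.integer(meth),
               unmeth = as.integer(unmeth))]
  setorder(calls, chrom, pos)
  calls[, included := (meth + unmeth) >= min_coverage]
  setcolorder(calls, c("chrom", "pos", "strand", "context", "meth",
                       "unmeth", "tri", "included"))
  structure(
    list(calls = calls[], sample_id = sample_id, group = group,
         min_coverage = as.integer(min_coverage), collapsed = collapsed),
    class = "methylome"
  )
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf(
    "<methylome> sample '%s' (group %s): %d calls (%d included), %s\n",
    x$sample_id, x$group, nrow(x$calls), sum(x$calls$included),
    if (x$collapsed) "CpG strand-collapsed" else "uncollapsed"))
  invisible(x)
}

#' Read a per-cytosine methylation report
#'
#' Reads the tab-separated cytosine report dialect emitted by upstream
#' bisulfite methylation callers: `chrom`, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide.
#' Positions are converted to the package's internal 0-based convention.
#'
#' @param path Path to the report.
#' @inheritParams methylome
#' @return A `methylome`. Both strands are retained until
#'   [collapse_strands()] is applied.
#' @export
read_cytosine_report <- function(path, sample_id = basename(path),
                                 group = "custom", min_coverage = 1L) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0L) {
    empty <- data.table(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        meth = integer(), unmeth = integer(), tri = character())
    return(methylome(empty, sample_id, group, min_coverage))
  }
  bad <- which(nf != 7L)
  if (length(bad))
    stop_("malformed cytosine report line %d in %s: expected 7 tab-separated fields, found %d",
          bad[1], path, nf[bad[1]])
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "pos", "strand", "meth", "unmeth",
                            "context", "tri"),
              colClasses = list(character = c(1, 3, 6, 7)))
  bad_ctx <- which(!dt$context %in% VALID_CONTEXTS)
  if (length(bad_ctx))
    stop_("unknown context '%s' at line %d of %s",
          dt$context[bad_ctx[1]], bad_ctx[1], path)
  if (any(!is.finite(dt$pos)) || any(dt$pos < 1))
    stop_("non-positive 1-based position in %s", path)
  dt[, pos := as.integer(pos) - 1L]  # 1-based dialect -> 0-based internal
  methylome(dt, sample_id, group, min_coverage)
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]: positions are written 1-based.
#'
#' @param m A `methylome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(m, path) {
  stopifnot(inherits(m, "methylome"))
  out <- m$calls[, .(chrom, pos = pos + 1L, strand, meth, unmeth, context, tri)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Collapse strand-specific CpG calls to forward-strand loci
#'
#' Methylation calls mapped to the reverse strand of a CpG dinucleotide
#' are moved to the position of the plus-strand C (one base upstream) and
#' their read counts summed with any plus-strand call there, after which
#' methylation levels are recomputed from the summed counts. Counts are
#' always summed, never averaged, under the assumption that
#' strand-specific CpG methylation is uncommon. Non-CpG contexts pass
#' through unchanged. The operation is idempotent and conserves total
#' methylated and unmethylated counts.
#'
#' @param m A `methylome`.
#' @return A `methylome` with one call per CpG locus, anchored at the
#'   plus-strand C coordinate.
#' @export
collapse_strands <- function(m) {
  stopifnot(inherits(m, "methylome"))
  calls <- m$calls
  # plain-vector subsetting: do not let auto-indexing mutate the input
  is_cpg <- calls$context == "CpG"
  cpg <- calls[which(is_cpg)]
  other <- calls[which(!is_cpg)]
  if (nrow(cpg)) {
    if (anyDuplicated(cpg[, .(chrom, pos, strand)]))
      stop_("duplicate CpG record: two entries at the same position and strand")
    cpg[, pos := ifelse(strand == "-", pos - 1L, pos)]
    if (anyDuplicated(cpg[which(cpg$strand == "+"), .(chrom, pos)]))
      stop_("duplicate record: two plus-strand CpG entries at the same position")
    cpg <- cpg[, .(
      strand = "+",
      meth = sum(meth), unmeth = sum(unmeth),
      tri = if (any(strand == "+")) tri[strand == "+"][1] else tri[1]
    ), by = .(chrom, pos)]
    cpg[, context := "CpG"]
  }
  out <- rbind(cpg, other, use.names = TRUE, fill = TRUE)
  methylome(out, m$sample_id, m$group, m$min_coverage, collapsed = TRUE)
}

#' Construct / read / write BED region sets
#'
#' A region set is a named collection of 0-based half-open genomic
#' intervals. `read_bed()` accepts BED3+ and ignores columns beyond the
#' third; `merge = TRUE` sorts and merges overlapping intervals.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param name Region set name.
#' @return An object of class `region_set`.
#' @export
region_set <- function(intervals, name = "regions") {
  dt <- as.data.table(intervals)[, .(chrom = as.character(chrom),
                                     start = as.integer(start),
                                     end = as.integer(end))]
  if (nrow(dt) && any(dt$start >= dt$end))
    stop_("degenerate interval: start >= end")
  setorder(dt, chrom, start, end)
  structure(list(name = name, intervals = dt[]), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> '%s': %d intervals on %d chromosome(s)\n",
              x$name, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' @rdname region_set
#' @param path BED file path.
#' @param merge Merge overlapping intervals after sorting.
#' @export
read_bed <- function(path, name = basename(path), merge = FALSE) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0L)
    return(region_set(data.table(chrom = character(), start = integer(),
                                 end = integer()), name))
  if (any(nf < 3L))
    stop_("malformed BED line %d in %s: fewer than 3 fields", which(nf < 3L)[1], path)
  dt <- fread(path, sep = "\t", header = FALSE, select = 1:3,
              col.names = c("chrom", "start", "end"),
              colClasses = list(character = 1))
  bad <- which(dt$start >= dt$end)
  if (length(bad))
    stop_("degenerate interval at line %d of %s: start >= end", bad[1], path)
  rs <- region_set(dt, name)
  if (merge) rs <- merge_regions(rs)
  rs
}

#' @rdname region_set
#' @export
merge_regions <- function(x) {
  dt <- regions_dt(x)
  if (nrow(dt) == 0L) return(region_set(dt, if (inherits(x, "region_set")) x$name else "regions"))
  merged <- dt[, {
    r <- IRanges::reduce(half_open_to_iranges(start, end))
    .(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  }, by = chrom]
  region_set(merged, if (inherits(x, "region_set")) x$name else "regions")
}

#' @rdname region_set
#' @param x A `region_set` (or coercible table) to write.
#' @export
write_bed <- function(x, path) {
  dt <- regions_dt(x)
  fwrite(dt[, .(chrom, start, end)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write cell-free DNA fragment tables
#'
#' Fragment records are tab-separated lines `chrom`, `start`, `end`
#' (0-based half-open) and a semicolon-joined per-cytosine call list
#' `offset:context:M|U` (`.` when a fragment carries no calls). Offsets
#' are relative to the fragment start and must lie in `[0, length)`.
#'
#' @param path Fragment TSV path.
#' @return A `fragment_set`: a list with `fragments`
#'   (`frag_id`, `chrom`, `start`, `end`, `length`) and `calls`
#'   (`frag_id`, `offset`, `context`, `meth`).
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0L)
    return(fragment_set(data.table(chrom = character(), start = integer(),
                                   end = integer()),
                        data.table(frag_id = integer(), offset = integer(),
                                   context = character(), meth = logical())))
  if (any(nf != 4L))
    stop_("malformed fragment line %d in %s: expected 4 fields", which(nf != 4L)[1], path)
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "call_str"),
              colClasses = list(character = c(1, 4)))
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop_("invalid fragment at line %d of %s: end <= start", bad[1], path)
  dt[, frag_id := .I]
  calls <- parse_call_strings(dt$call_str, dt$frag_id)
  frags <- dt[, .(frag_id, chrom, start = as.integer(start), end = as.integer(end))]
  fragment_set(frags, calls)
}

parse_call_strings <- function(call_str, frag_id) {
  has <- !(is.na(call_str) | call_str == "." | call_str == "")
  if (!any(has))
    return(data.table(frag_id = integer(), offset = integer(),
                      context = character(), meth = logical()))
  pieces <- strsplit(call_str[has], ";", fixed = TRUE)
  ids <- rep(frag_id[has], lengths(pieces))
  flat <- unlist(pieces, use.names = FALSE)
  parts <- tstrsplit(flat, ":", fixed = TRUE)
  if (length(parts) != 3L) stop_("malformed fragment call triplet '%s'", flat[1])
  state <- parts[[3]]
  if (any(!state %in% c("M", "U")))
    stop_("fragment call state must be 'M' or 'U'")
  ctx <- parts[[2]]
  bad_ctx <- setdiff(unique(ctx), VALID_CONTEXTS)
  if (length(bad_ctx)) stop_("unknown context in fragment calls: %s", bad_ctx[1])
  data.table(frag_id = ids, offset = as.integer(parts[[1]]),
             context = ctx, meth = state == "M")
}

#' @rdname read_fragments
#' @param fragments,calls Components of a fragment set (see return value).
#' @export
fragment_set <- function(fragments, calls = NULL) {
  frags <- as.data.table(fragments)
  if (!"frag_id" %in% names(frags)) frags[, frag_id := .I]
  frags[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (nrow(frags) && any(frags$end <= frags$start))
    stop_("invalid fragment: end <= start")
  frags[, length := end - start]
  setcolorder(frags, c("frag_id", "chrom", "start", "end", "length"))
  if (is.null(calls))
    calls <- data.table(frag_id = integer(), offset = integer(),
                        context = character(), meth = logical())
  calls <- as.data.table(calls)
  if (nrow(calls)) {
    len <- frags[calls, on = "frag_id", x.length]
    if (any(is.na(len)))
      stop_("fragment call references unknown fragment id")
    if (any(calls$offset < 0L) || any(calls$offset >= len))
      stop_("fragment call offset outside [0, length)")
  }
  structure(list(fragments = frags[], calls = calls[]), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments, %d cytosine calls\n",
              nrow(x$fragments), nrow(x$calls)))
  invisible(x)
}

#' @rdname read_fragments
#' @param fs A `fragment_set`.
#' @export
write_fragments <- function(fs, path) {
  stopifnot(inherits(fs, "fragment_set"))
  if (nrow(fs$calls)) {
    call_str <- fs$calls[, .(s = paste(sprintf("%d:%s:%s", offset, context,
                                               ifelse(meth, "M", "U")),
                                       collapse = ";")), by = frag_id]
  } else {
    call_str <- data.table(frag_id = integer(), s = character())
  }
  out <- copy(fs$fragments)
  out[, s := call_str[out, on = "frag_id", s]]
  out[is.na(s), s := "."]
  fwrite(out[, .(chrom, start, end, s)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Subset a fragment set by fragment id
#' @param fs A `fragment_set`.
#' @param ids Fragment ids to keep.
#' @export
subset_fragments <- function(fs, ids) {
  stopifnot(inherits(fs, "fragment_set"))
  fragment_set(fs$fragments[frag_id %in% ids],
               fs$calls[frag_id %in% ids])
}

#' Write a per-bin mean methylation bedGraph track
#'
#' @param bins A `genomic_bins` table from [bin_genome()].
#' @param group Group whose bin means to write.
#' @param path Output path.
#' @export
write_bedgraph <- function(bins, group, path) {
  col <- paste0("mean_", group)
  if (!col %in% names(bins)) stop_("no bin means for group '%s'", group)
  dt <- as.data.table(bins)[!is.na(get(col)),
                            .(chrom, start, end, value = get(col))]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
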