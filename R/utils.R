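# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Half-open [start, end) intervals -> IRanges (1-based closed).
half_open_to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = as.integer(end))
}

# For each query interval (half-open), does it overlap >=1 bp of any subject
# interval (half-open) on the same chromosome?
overlaps_any_region <- function(q, s) {
  stopifnot(all(c("chrom", "start", "end") %in% names(q)),
            all(c("chrom", "start", "end") %in% names(s)))
  hit <- logical(nrow(q))
  if (nrow(q) == 0L || nrow(s) == 0L) return(hit)
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    si <- which(s$chrom == ch)
    if (length(si) == 0L) next
    ov <- IRanges::countOverlaps(
      half_open_to_iranges(q$start[qi], q$end[qi]),
      half_open_to_iranges(s$start[si], s$end[si])
    )
    hit[qi] <- ov > 0L
  }
  hit
}

# For point positions (0-based), membership in half-open regions.
points_in_region <- function(chrom, pos, regions) {
  q <- data.table(chrom = chrom, start = pos, end = pos + 1L)
  overlaps_any_region(q, regions_dt(regions))
}

regions_dt <- function(x) {
  if (inherits(x, "region_set")) x$intervals else as.data.table(x)
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("'%s' must be a single finite number", name)
  invisible(x)
}
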