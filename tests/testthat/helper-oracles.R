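# Independent brute-force oracles used to verify the implementation.
# These deliberately use plain loops and base R, not the package's code
# paths.

# Literal DMR rule enumerator: drop |t| < t_min, then walk sorted sites
# accumulating runs with gap < max_gap (and uniform sign when
# same_sign), emitting runs of >= min_cpg sites.
oracle_dmrs <- function(sites, t_min = 5, max_gap = 300, min_cpg = 9,
                        same_sign = TRUE) {
  df <- as.data.frame(sites)
  df <- df[abs(df$t_stat) >= t_min, , drop = FALSE]
  out <- list()
  flush <- function(run) {
    if (length(run$pos) >= min_cpg)
      out[[length(out) + 1L]] <<- data.frame(
        chrom = run$chrom, start = run$pos[1],
        end = run$pos[length(run$pos)] + 2L,
        n_cpg = length(run$pos),
        direction = if (run$sgn > 0) "hyper_in_A" else "hyper_in_B")
  }
  run <- NULL
  if (nrow(df)) for (i in seq_len(nrow(df))) {
    sgn <- sign(df$diff_[i])
    brk <- is.null(run) || df$chrom[i] != run$chrom ||
      (df$pos[i] - run$pos[length(run$pos)]) >= max_gap ||
      (same_sign && sgn != run$sgn)
    if (brk) {
      if (!is.null(run)) flush(run)
      run <- list(chrom = df$chrom[i], pos = df$pos[i], sgn = sgn)
    } else run$pos <- c(run$pos, df$pos[i])
  }
  if (!is.null(run)) flush(run)
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpg = integer(), direction = character()))
  do.call(rbind, out)
}

# Random filtered-site instance for the grouping rule (t straddles the
# threshold, sign tied to diff).
random_site_instance <- function(seed, max_sites = 200) {
  set.seed(seed)
  n <- sample.int(max_sites, 1)
  chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(c0) {
    k <- sum(chrom == c0)
    cumsum(sample(c(10:80, 250:350, 500:700), k, replace = TRUE))
  }))
  t_val <- runif(n, -9, 9)
  t_val[sample.int(n, max(1, n %/% 10))] <- sample(c(-5, 5), max(1, n %/% 10),
                                                   replace = TRUE)
  data.table(chrom = chrom, pos = as.integer(pos), t_stat = t_val,
             diff_ = sign(t_val) * runif(n, 0.05, 0.6))
}

# O(n*m) interval overlap (half-open).
oracle_overlap_any <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  })
}

# Reciprocal-overlap matching of called vs planted intervals.
recip_match <- function(called, truth, min_recip = 0.5) {
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  hit_truth <- rep(FALSE, nrow(truth))
  hit_called <- rep(FALSE, nrow(called))
  for (i in seq_len(nrow(called))) for (j in seq_len(nrow(truth))) {
    if (called$chrom[i] != truth$chrom[j]) next
    o <- ov(called$start[i], called$end[i], truth$start[j], truth$end[j])
    if (o >= min_recip * (called$end[i] - called$start[i]) &&
        o >= min_recip * (truth$end[j] - truth$start[j])) {
      hit_truth[j] <- TRUE; hit_called[i] <- TRUE
    }
  }
  list(sensitivity = if (nrow(truth)) mean(hit_truth) else NA_real_,
       precision = if (nrow(called)) mean(hit_called) else NA_real_)
}

# Brute-force per-bin unweighted mean of site values.
oracle_bin_means <- function(levels, bin_size, bins) {
  sapply(seq_len(nrow(bins)), function(i) {
    v <- levels$level[levels$chrom == bins$chrom[i] &
                        levels$pos >= bins$start[i] & levels$pos < bins$end[i]]
    if (length(v)) mean(v) else NA_real_
  })
}
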