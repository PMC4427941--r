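library(data.table)

# Write report lines to a temp file and return its path.
write_report <- function(lines) {
  tmp <- tempfile(fileext = ".cx.tsv")
  writeLines(lines, tmp)
  tmp
}

# A random uncollapsed methylome of paired-strand CpG loci (plus some
# non-CpG calls), for conservation / round-trip properties.
random_paired_methylome <- function(seed, n_loci = 2000,
                                    chroms = c("chr1", "chr2")) {
  set.seed(seed)
  ch <- sample(chroms, n_loci, replace = TRUE)
  pos <- integer(n_loci)
  for (c0 in chroms) {
    idx <- which(ch == c0)
    pos[idx] <- sort(sample.int(1e6, length(idx)) * 2L)  # even => no locus abuts another
  }
  mp <- rpois(n_loci, 4); up <- rpois(n_loci, 3)
  mm <- rpois(n_loci, 4); um <- rpois(n_loci, 3)
  calls <- rbind(
    data.table(chrom = ch, pos = pos, strand = "+", context = "CpG",
               meth = mp, unmeth = up, tri = "CGA"),
    data.table(chrom = ch, pos = pos + 1L, strand = "-", context = "CpG",
               meth = mm, unmeth = um, tri = "CGT"),
    data.table(chrom = "chr1", pos = sample.int(1e6, 50) * 2L + 1L,
               strand = "+", context = "CHH",
               meth = rpois(50, 1), unmeth = rpois(50, 9), tri = "CAA"))
  methylome(calls, sample_id = sprintf("rnd_%d", seed), group = "custom")
}

# Collapsed methylome with exact per-site levels (coverage 10).
methylome_from_levels <- function(levels_dt, sample_id = "s", group = "custom",
                                  coverage = 10L) {
  dt <- as.data.table(levels_dt)
  calls <- dt[, .(chrom, pos, strand = "+", context = "CpG",
                  meth = as.integer(round(level * coverage)),
                  unmeth = as.integer(coverage - round(level * coverage)),
                  tri = "CGA")]
  methylome(calls, sample_id = sample_id, group = group, collapsed = TRUE)
}

# Group stats table built directly (bypasses methylome plumbing).
stats_table <- function(chrom, pos, n, mean, sd) {
  data.table(chrom = chrom, pos = as.integer(pos), n = as.integer(n),
             mean = mean, sd = sd)
}

tiny_regions <- function(...) {
  region_set(rbindlist(list(...)), "test")
}

reg <- function(chrom, start, end) data.table(chrom = chrom, start = start, end = end)
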