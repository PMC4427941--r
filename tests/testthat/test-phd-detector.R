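make_bins_fixture <- function(chrom_len = 1e6, bin_size = 50000L) {
  set.seed(41)
  pos <- sort(sample.int(chrom_len - 2L, 3000))
  lvA <- data.table(chrom = "chr1", pos = pos, level = runif(3000, 0.6, 0.9))
  # B tracks A closely so no bin qualifies by chance before planting
  lvB <- data.table(chrom = "chr1", pos = pos,
                    level = pmin(pmax(lvA$level + rnorm(3000, 0, 0.02), 0), 1))
  cs <- data.table(chrom = "chr1", length = chrom_len)
  bin_genome(list(A = lvA, B = lvB), data.table(chrom = "chr1", pos = pos),
             cs, bin_size = bin_size)
}

test_that("genome binning tiles chromosomes and aggregates sites and genes", {
  lv <- data.table(chrom = "chr1", pos = c(10L, 20L, 60000L),
                   level = c(0.4, 0.8, 0.5))
  cs <- data.table(chrom = "chr1", length = 120000L)
  genes <- tiny_regions(reg("chr1", c(40000L, 110000L), c(70000L, 119000L)))
  bins <- bin_genome(list(g = lv), lv[, .(chrom, pos)], cs, genes = genes)
  expect_equal(bins$start, c(0L, 50000L, 100000L))
  expect_equal(bins$end, c(50000L, 100000L, 120000L))   # last bin short
  expect_equal(bins$mean_g, c(0.6, 0.5, NA))
  expect_equal(bins$cpg_count, c(2L, 1L, 0L))
  expect_equal(bins$gene_count, c(1L, 1L, 1L))  # first gene counted in two bins
  expect_error(bin_genome(list(g = data.table(chrom = "chrX", pos = 1L, level = 0.5)),
                          lv[, .(chrom, pos)], cs), "unknown chromosome")
})

test_that("bin means match brute-force assignment and counts are conserved", {
  bins <- make_bins_fixture()
  set.seed(41)
  pos <- sort(sample.int(1e6 - 2L, 3000))
  lvA <- data.table(chrom = "chr1", pos = pos, level = runif(3000, 0.6, 0.9))
  brute <- oracle_bin_means(lvA, 50000L, bins)
  expect_equal(bins$mean_A, brute, tolerance = 1e-12)
  expect_equal(sum(bins$cpg_count), 3000L)
  expect_equal(bins$end - bins$start, rep(50000L, 20))
})

test_that("PHD calling recovers a planted contiguous run and nothing under the null", {
  bins <- make_bins_fixture()
  # plant 12 consecutive hypomethylated bins in group A (bins 5..16)
  idx <- 5:16
  bins2 <- copy(bins)
  bins2[idx, mean_A := mean_A - 0.25]
  phds <- call_phds(bins2, "A", "B", delta = 0.15, min_run = 10,
                    min_cpg_per_bin = 10)
  expect_equal(nrow(phds), 1L)
  expect_equal(phds$n_bins, 12L)
  expect_equal(phds$start, bins2$start[5])
  expect_equal(phds$end, bins2$end[16])
  expect_lt(phds$mean_meth_target, phds$mean_meth_reference - 0.15)

  # alternating qualifying bins never form a run
  alt <- copy(bins)
  alt[seq(1, 20, by = 2), mean_A := mean_A - 0.25]
  expect_equal(nrow(call_phds(alt, "A", "B", min_run = 2)), 0L)

  # identical groups yield no domains for any positive delta
  same <- copy(bins)[, mean_A := mean_B]
  expect_equal(nrow(call_phds(same, "A", "B", delta = 0.01, min_run = 1)), 0L)
  expect_error(call_phds(bins, "A", "B", delta = 0), "delta")
})

test_that("called domains are disjoint, maximal and CpG-weighted", {
  bins <- make_bins_fixture()
  bins2 <- copy(bins)
  bins2[c(3:13, 15:19), mean_A := mean_B - 0.3]
  phds <- call_phds(bins2, "A", "B", delta = 0.15, min_run = 5,
                    min_cpg_per_bin = 1)
  expect_equal(nrow(phds), 2L)
  expect_true(all(phds$end[-nrow(phds)] <= phds$start[-1]))
  # maximality: the bins flanking each domain do not qualify
  for (i in seq_len(nrow(phds))) {
    lo <- bins2[end == phds$start[i]]
    hi <- bins2[start == phds$end[i]]
    for (fl in list(lo, hi)) if (nrow(fl))
      expect_false(fl$mean_B - fl$mean_A >= 0.15)
  }
  w <- bins2[3:13]
  expect_equal(phds$mean_meth_target[1],
               weighted.mean(w$mean_A, w$cpg_count), tolerance = 1e-12)
})

test_that("density-stratified differences aggregate correctly and fit a smooth", {
  bins <- make_bins_fixture()
  same <- copy(bins)[, mean_A := mean_B]
  ds <- density_stratified_diff(same, "A", "B", breaks = c(0, 100, 200, Inf),
                                span = 0.9)
  expect_true(all(abs(ds$table$mean_diff[ds$table$n_bins > 0]) < 1e-12))

  one <- density_stratified_diff(bins, "A", "B", breaks = c(0, Inf), span = 0.9)
  expect_equal(one$table$n_bins, 20L)
  expect_equal(one$table$mean_diff, mean(bins$mean_A - bins$mean_B),
               tolerance = 1e-12)

  empty_stratum <- density_stratified_diff(bins, "A", "B",
                                           breaks = c(0, 1, 100, 1e6), span = 0.9)
  expect_equal(empty_stratum$table$n_bins[1], 0L)
  expect_true(is.na(empty_stratum$table$mean_diff[1]))
  expect_true(all(is.finite(one$curve$fitted)))
})

test_that("a planted density-dependent effect shows up in the strata", {
  set.seed(43)
  n_bins <- 200
  cpg_count <- sample(20:400, n_bins, replace = TRUE)
  ref <- runif(n_bins, 0.7, 0.8)
  tgt <- ref - 0.3 * (1 - cpg_count / 400)   # weaker hypomethylation at high density
  bins <- data.table(chrom = "chr1", start = (0:(n_bins - 1)) * 50000L,
                     end = (1:n_bins) * 50000L, bin_id = 1:n_bins,
                     cpg_count = cpg_count, gene_count = 0L,
                     mean_T = tgt, mean_R = ref)
  ds <- density_stratified_diff(bins, "T", "R", breaks = c(0, 100, 200, 300, Inf))
  md <- ds$table$mean_diff
  expect_true(all(diff(md) > 0))   # increases toward 0 with density
})

test_that("DMR-in-domain fraction matches planted placement", {
  phds <- reg("chr1", c(0L, 1e6L), c(5e5L, 15e5L))
  inside <- reg("chr1", c(100L, 1100000L), c(400L, 1100300L))
  outside <- reg("chr1", c(6e5L, 2e6L), c(6.1e5L, 2000300L))
  expect_equal(dmr_phd_overlap(rbind(inside, outside), phds), 0.5)
  expect_equal(dmr_phd_overlap(inside, phds), 1)
  expect_equal(dmr_phd_overlap(outside, phds), 0)
  expect_warning(ov <- dmr_phd_overlap(inside[0], phds), "empty")
  expect_true(is.na(ov))
})
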