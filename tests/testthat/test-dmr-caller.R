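test_that("group site stats compute per-sample-fraction mean and n-1 sd", {
  ms <- lapply(1:3, function(i)
    methylome_from_levels(data.table(chrom = "chr1", pos = 100L, level = 0.5),
                          paste0("s", i)))
  st <- group_site_stats(ms)
  expect_equal(st$mean, 0.5)
  expect_equal(st$sd, 0)
  expect_equal(st$n, 3L)

  ms2 <- list(methylome_from_levels(data.table(chrom = "chr1", pos = 100L, level = 0)),
              methylome_from_levels(data.table(chrom = "chr1", pos = 100L, level = 1)))
  st2 <- group_site_stats(ms2)
  expect_equal(st2$mean, 0.5)
  expect_equal(st2$sd, sqrt(0.5), tolerance = 1e-12)  # 0.7071

  ms3 <- list(methylome_from_levels(data.table(chrom = "chr1", pos = c(100L, 200L),
                                               level = c(0.5, 0.5))),
              methylome_from_levels(data.table(chrom = "chr1", pos = 100L, level = 0.5)))
  expect_equal(group_site_stats(ms3, min_samples = 2)$pos, 100L)
  expect_error(group_site_stats(ms3[1]), "at least 2")
})

test_that("Welch t matches the hand-evaluated formula and degenerate rules", {
  a <- stats_table("chr1", 100, 5, 0.9, 0.05)
  b <- stats_table("chr1", 100, 5, 0.1, 0.05)
  ts <- site_t(a, b)
  expect_equal(ts$t_stat, 0.8 / sqrt(2 * 0.05^2 / 5), tolerance = 1e-12)
  expect_equal(ts$t_stat, 25.298, tolerance = 1e-4)
  expect_equal(ts$diff_, 0.8)

  expect_equal(site_t(a, a)$t_stat, 0)

  za <- stats_table("chr1", 100, 5, 0.8, 0)
  zb <- stats_table("chr1", 100, 5, 0.5, 0)
  expect_identical(site_t(za, zb)$t_stat, Inf)
  expect_identical(site_t(zb, za)$t_stat, -Inf)
  expect_true(nrow(filter_sites(site_t(za, zb))) == 1L)
})

test_that("t filtering is strict below and inclusive at the threshold", {
  dt <- data.table(chrom = "chr1", pos = c(1L, 2L, 3L),
                   t_stat = c(4.999, -5, 5), diff_ = c(0.1, -0.1, 0.1))
  kept <- filter_sites(dt)
  expect_equal(kept$pos, c(2L, 3L))
})

test_that("DMR grouping follows the gap, size and sign rules", {
  mk <- function(pos, t) data.table(chrom = "chr1", pos = as.integer(pos),
                                    t_stat = t, diff_ = sign(t) * 0.3)
  nine <- mk(seq(100, 500, by = 50), 6)
  d <- call_dmrs(nine)
  expect_equal(nrow(d), 1L)
  expect_equal(d$n_cpg, 9L)
  expect_equal(d$direction, "hyper_in_A")
  expect_equal(d$start, 100L)
  expect_equal(d$end, 502L)
  expect_equal(d$member_positions[[1]], seq(100L, 500L, by = 50L))

  eight <- mk(seq(100, 450, by = 50), 6)
  expect_equal(nrow(call_dmrs(eight)), 0L)

  # exactly 300 bp apart splits (strict < 300)
  split2 <- mk(c(seq(100, 500, 50), seq(800, 1200, 50)), 6)
  d2 <- call_dmrs(split2)
  expect_equal(nrow(d2), 2L)
  near <- mk(c(seq(100, 500, 50), seq(799, 1199, 50)), 6)
  expect_equal(nrow(call_dmrs(near)), 1L)

  # sign change closes a group
  flip <- mk(seq(100, 950, by = 50), c(rep(6, 9), rep(-6, 9)))
  d3 <- call_dmrs(flip)
  expect_equal(d3$direction, c("hyper_in_A", "hyper_in_B"))
  d4 <- call_dmrs(flip, same_sign = FALSE)
  expect_equal(nrow(d4), 1L)
  expect_equal(d4$n_cpg, 18L)

  expect_error(call_dmrs(mk(c(200, 100), 6)), "sorted")
})

test_that("DMR grouping matches the brute-force enumerator on random instances", {
  for (seed in 1:40) {
    inst <- random_site_instance(seed)
    got <- as.data.frame(call_dmrs(filter_sites(inst))[, .(chrom, start, end,
                                                           n_cpg, direction)])
    want <- oracle_dmrs(inst)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("swapping groups flips every t sign and DMR direction", {
  set.seed(31)
  pos <- sort(sample.int(1e5, 400))
  a <- stats_table("chr1", pos, 6, runif(400), runif(400, 0.01, 0.2))
  b <- stats_table("chr1", pos, 6, runif(400), runif(400, 0.01, 0.2))
  tab <- site_t(a, b); tba <- site_t(b, a)
  expect_equal(tba$t_stat, -tab$t_stat, tolerance = 1e-15)
  dab <- call_dmrs(filter_sites(tab), min_cpg = 2)
  dba <- call_dmrs(filter_sites(tba), min_cpg = 2)
  expect_equal(dba$start, dab$start)
  expect_equal(dba$end, dab$end)
  expect_equal(dba$direction,
               ifelse(dab$direction == "hyper_in_A", "hyper_in_B", "hyper_in_A"))
})

test_that("every called DMR satisfies its structural invariants", {
  for (seed in 1:10) {
    inst <- random_site_instance(seed + 100)
    d <- call_dmrs(filter_sites(inst), min_cpg = 3)
    if (nrow(d) == 0) next
    for (i in seq_len(nrow(d))) {
      mem <- d$member_positions[[i]]
      expect_gte(length(mem), 3)
      expect_true(all(diff(mem) < 300))
      sub <- inst[chrom == d$chrom[i] & pos %in% mem]
      expect_true(all(abs(sub$t_stat) >= 5))
      expect_equal(length(unique(sign(sub$diff_))), 1L)
      expect_equal(d$end[i], mem[length(mem)] + 2L)
    }
  }
})

test_that("DMR annotation uses half-open overlap and partitions by genes", {
  dmrs <- call_dmrs(data.table(chrom = "chr1",
                               pos = c(100L, 150L, 200L, 1000L, 1050L, 1100L),
                               t_stat = 6, diff_ = 0.3), min_cpg = 3)
  expect_equal(nrow(dmrs), 2L)
  islands <- tiny_regions(reg("chr1", 90L, 300L))
  touching <- tiny_regions(reg("chr1", 0L, 100L))   # ends exactly at DMR start
  genes <- tiny_regions(reg("chr1", 900L, 2000L))
  ann <- annotate_dmrs(dmrs, list(cgi = islands, touch = touching), genes = genes)
  expect_equal(unname(ann$overlap["cgi"]), 0.5)
  expect_equal(unname(ann$overlap["touch"]), 0)
  expect_equal(ann$intragenic, 0.5)
  expect_equal(ann$intergenic, 0.5)
})

test_that("DMR set overlap fraction matches brute force", {
  expect_warning(ov <- dmr_overlap(data.table(chrom = character(),
                                              start = integer(), end = integer()),
                                   reg("chr1", 1, 2)), "empty")
  expect_true(is.na(ov))
  a <- reg("chr1", c(0L, 100L, 300L), c(50L, 200L, 400L))
  expect_equal(dmr_overlap(a, a), 1)
  b <- reg("chr1", 500L, 600L)
  expect_equal(dmr_overlap(a, b), 0)
  set.seed(17)
  ra <- reg(sample(c("chr1", "chr2"), 100, TRUE), s <- sample.int(1e4, 100), s + sample.int(200, 100))
  rb <- reg(sample(c("chr1", "chr2"), 60, TRUE), s2 <- sample.int(1e4, 60), s2 + sample.int(200, 60))
  expect_equal(dmr_overlap(ra, rb), mean(oracle_overlap_any(ra, rb)))
})
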