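frag_table <- function(lengths, chrom = "chr1", start = 1000L) {
  data.table(frag_id = seq_along(lengths), chrom = chrom,
             start = start, end = start + as.integer(lengths))
}

fs_with_calls <- function(lengths, calls) {
  fragment_set(frag_table(lengths), calls)
}

test_that("length histogram counts every fragment and breaks ties low", {
  fs <- fragment_set(frag_table(c(168, 168, 150)))
  lh <- length_histogram(fs)
  expect_equal(sum(lh$hist$count), 3L)
  expect_equal(lh$modal_length, 168L)
  tie <- fragment_set(frag_table(c(166, 166, 168, 168, 150)))
  expect_equal(length_histogram(tie)$modal_length, 166L)
  expect_error(length_histogram(fragment_set(frag_table(integer()))), "no fragments")
})

test_that("simulated cfDNA lengths peak at the configured mode", {
  cfg <- sim_config(seed = 2, fragment_model = list(n_fragments = 50000L))
  pmf <- fragment_length_pmf(cfg$fragment_model)
  expect_equal(pmf$length[which.max(pmf$prob)], 168L)   # exact analytic mode
  fr <- simulate_fragments(cfg)
  lh <- length_histogram(fr$fragments)
  expect_lte(abs(lh$modal_length - 168), 3)             # 1 bp bins are noisy
})

test_that("long/short fold ratio is the per-context rate ratio", {
  # 10 long calls at rate 0.5, 10 short at rate 0.1
  calls <- data.table(
    frag_id = rep(c(1L, 2L), each = 10),
    offset = rep(0:9, 2), context = "CpG",
    meth = c(rep(c(TRUE, FALSE), c(5, 5)), rep(c(TRUE, FALSE), c(1, 9))))
  fs <- fs_with_calls(c(250L, 150L), calls)
  r <- methylation_by_length(fs)
  expect_equal(r$fold_ratio, 5)
  expect_equal(r$rate_long, 0.5)
  expect_equal(r$rate_short, 0.1)

  same <- copy(calls)[, meth := rep(c(TRUE, FALSE), 10)]
  expect_equal(methylation_by_length(fs_with_calls(c(250L, 150L), same))$fold_ratio, 1)
})

test_that("exactly-cutoff fragments are short by default and droppable", {
  calls <- data.table(frag_id = c(1L, 1L, 2L), offset = c(0L, 1L, 0L),
                      context = "CpG", meth = c(TRUE, TRUE, FALSE))
  fs <- fs_with_calls(c(200L, 300L), calls)
  r <- methylation_by_length(fs, cutoff = 200)
  expect_equal(r$n_short, 2L)              # the 200 bp fragment counts as short
  r2 <- methylation_by_length(fs, cutoff = 200, boundary = "drop")
  expect_equal(r2$n_short, 0L)
  expect_true(is.na(r2$fold_ratio))        # empty short class -> undefined
})

test_that("fold ratio is invariant to fragment order and input duplication", {
  cfg <- sim_config(seed = 5, fragment_model = list(n_fragments = 4000L))
  fs <- simulate_fragments(cfg)$fragments
  base <- methylation_by_length(fs)
  perm <- fragment_set(fs$fragments[sample(.N)], fs$calls)
  expect_equal(methylation_by_length(perm)$fold_ratio, base$fold_ratio)
  dup <- fragment_set(
    rbind(fs$fragments, copy(fs$fragments)[, frag_id := frag_id + nrow(fs$fragments)]),
    rbind(fs$calls, copy(fs$calls)[, frag_id := frag_id + nrow(fs$fragments)]))
  expect_equal(methylation_by_length(dup)$fold_ratio, base$fold_ratio)
})

test_that("MCIp pair filter applies the size and concordance rules", {
  pairs <- data.table(chrom1 = c("chr1", "chr1", "chr1", "chr2"),
                      start1 = c(1000L, 2000L, 3000L, 100L),
                      chrom2 = c("chr1", "chr1", "chr2", "chr2"),
                      start2 = c(1320L, 2501L, 3100L, 500L))
  res <- mcip_pair_filter(pairs)
  expect_equal(res$kept$size, c(320L, 400L))
  expect_equal(unname(res$discarded["oversize"]), 1L)   # size 501 dropped
  expect_equal(unname(res$discarded["discordant"]), 1L)
  keep500 <- mcip_pair_filter(data.table(chrom1 = "chr1", start1 = 0L,
                                         chrom2 = "chr1", start2 = 500L))
  expect_equal(nrow(keep500$kept), 1L)
  expect_error(mcip_pair_filter(data.table(chrom1 = "chr1", start1 = 100L,
                                           chrom2 = "chr1", start2 = 50L)),
               "mis-ordered")
})

test_that("size-fraction comparison reports proportions and fold", {
  u <- fragment_set(frag_table(c(150, 150, 350, 150)))
  m <- fragment_set(frag_table(c(150, 350, 350, 150)))
  fsc <- fraction_size_comparison(u, m)
  expect_equal(fsc$unmethylated$proportion_gt, 0.25)
  expect_equal(fsc$methylated$proportion_gt, 0.5)
  expect_equal(fsc$fold, 2)
  expect_equal(fraction_size_comparison(u, u)$fold, 1)
  short <- fragment_set(frag_table(c(100, 120)))
  expect_warning(f0 <- fraction_size_comparison(short, short, threshold = 300),
                 "zero")
  expect_true(is.na(f0$fold))
  expect_equal(f0$methylated$proportion_gt, 0)
})

test_that("short-fragment proportions use midpoint membership", {
  # fragments: 80 bp centered in promoter, 168 bp centered in promoter,
  # 80 bp outside, midpoint exactly at region end -> outside
  fr <- data.table(frag_id = 1:4, chrom = "chr1",
                   start = c(1000L, 1000L, 5000L, 1960L),
                   end = c(1080L, 1168L, 5080L, 2040L))
  promoters <- tiny_regions(reg("chr1", 900L, 2000L))
  res <- short_fragment_region_enrichment(fragment_set(fr), list(promoter = promoters))
  prom <- res[region_set == "promoter"]
  expect_equal(prom$n_fragments, 2L)         # midpoint 2000 is outside [900,2000)
  expect_equal(prom$prop_short, 0.5)
  expect_equal(res[region_set == "genome"]$prop_short, 0.75)

  none <- short_fragment_region_enrichment(
    fragment_set(fr), list(far = tiny_regions(reg("chr2", 0L, 100L))))
  expect_true(is.na(none[region_set == "far"]$prop_short))
})

test_that("planted short-fragment excess in regions is detected", {
  set.seed(77)
  inside <- data.table(chrom = "chr1",
                       start = s <- sample(1000:1800, 300, TRUE),
                       end = s + sample(c(80L, 168L), 300, TRUE, prob = c(0.4, 0.6)))
  outside <- data.table(chrom = "chr1",
                        start = s2 <- sample(10000:50000, 700, TRUE),
                        end = s2 + sample(c(80L, 168L), 700, TRUE, prob = c(0.05, 0.95)))
  fs <- fragment_set(rbind(inside, outside))
  promoters <- tiny_regions(reg("chr1", 900L, 2100L))
  res <- short_fragment_region_enrichment(fs, list(promoter = promoters))
  expect_gt(res[region_set == "promoter"]$prop_short,
            res[region_set == "genome"]$prop_short)
})
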