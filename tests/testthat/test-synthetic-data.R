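small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             genome = data.frame(chrom = "chr1", length = 1e6),
             n_samples = c(non_pregnant_ccf = 3L, placenta = 3L),
             strand_split = FALSE, ...)
}

test_that("configuration validation rejects out-of-range plants instead of clamping", {
  expect_error(sim_config(n_dmrs = 5L, dmr_effect = 1.2), "clamping is not allowed")
  expect_error(sim_config(phd_depth = 0.9, n_phds = 2L), "outside")
  expect_error(sim_config(fetal_fraction = 1.5), "fetal_fraction")
  expect_error(sim_config(bogus_field = 1), "unknown")
  expect_error(sim_config(mixture_blood = list(weights = c(low = 0.5, intermediate = 0.5,
                                                           high = 0.5))), "sum to 1")
  expect_silent(sim_config(n_dmrs = 5L))
})

test_that("identical configs give byte-identical methylomes and fragments", {
  cfg <- small_cfg(seed = 42, n_dmrs = 3L, n_phds = 1L, phd_bins = 4L)
  a <- simulate_methylomes(cfg)
  b <- simulate_methylomes(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$methylomes$placenta[[2]]$calls,
                   b$methylomes$placenta[[2]]$calls)
  fa <- simulate_fragments(cfg); fb <- simulate_fragments(cfg)
  expect_identical(fa$fragments$fragments, fb$fragments$fragments)
  expect_identical(fa$fragments$calls, fb$fragments$calls)
  d <- simulate_methylomes(small_cfg(seed = 43, n_dmrs = 3L))
  expect_false(identical(a$methylomes$placenta[[1]]$calls,
                         d$methylomes$placenta[[1]]$calls))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_methylomes(small_cfg())); after <- runif(1)
  expect_identical(before, after)
})

test_that("emitted reports parse back through the reader unchanged", {
  cfg <- sim_config(seed = 9, genome = data.frame(chrom = "chr1", length = 5e5),
                    n_samples = c(placenta = 1L))   # strand-split default on
  m <- simulate_methylomes(cfg)$methylomes$placenta[[1]]
  p <- tempfile()
  write_cytosine_report(m, p)
  m2 <- read_cytosine_report(p, m$sample_id)
  expect_identical(m2$calls[, !"included"], m$calls[, !"included"])
  cc <- collapse_strands(m2)
  expect_equal(sum(cc$calls$meth), sum(m$calls$meth))
})

test_that("planted truth intervals live inside the genome and match the CpG map", {
  cfg <- small_cfg(seed = 5, n_dmrs = 10L, n_phds = 2L, phd_bins = 4L)
  sim <- simulate_methylomes(cfg)
  tr <- sim$truth
  expect_true(all(tr$dmrs$end <= 1e6 & tr$dmrs$start >= 0))
  expect_true(all(tr$phds$end <= 1e6))
  for (i in seq_len(nrow(tr$dmrs))) {
    n_inside <- sim$truth$cpg_positions[chrom == tr$dmrs$chrom[i] &
                                          pos >= tr$dmrs$start[i] &
                                          pos < tr$dmrs$end[i], .N]
    expect_equal(n_inside, cfg$dmr_n_cpg)
  }
  expect_equal(nrow(tr$phds), 2L)
  expect_true(all(tr$phds$end - tr$phds$start == 4L * cfg$bin_size))
})

test_that("fetal fraction 0 and 1 reduce the pregnant mixture to its endpoints", {
  base <- list(seed = 31, genome = data.frame(chrom = "chr1", length = 1e6),
               strand_split = FALSE,
               n_samples = c(non_pregnant_ccf = 6L, pregnant_ccf = 6L, placenta = 6L))
  cfg0 <- do.call(sim_config, c(base, fetal_fraction = 0))
  s0 <- simulate_methylomes(cfg0)
  lv_p <- group_mean_levels(s0$methylomes$pregnant_ccf)
  lv_m <- group_mean_levels(s0$methylomes$non_pregnant_ccf)
  expect_gt(suppressWarnings(stats::ks.test(lv_p$level, lv_m$level)$p.value), 1e-4)

  cfg1 <- do.call(sim_config, c(base, fetal_fraction = 1))
  s1 <- simulate_methylomes(cfg1)
  lv_p1 <- group_mean_levels(s1$methylomes$pregnant_ccf)
  lv_t1 <- group_mean_levels(s1$methylomes$placenta)
  expect_gt(suppressWarnings(stats::ks.test(lv_p1$level, lv_t1$level)$p.value), 1e-4)
  # and the mixture is not maternal-like at f = 1
  expect_lt(suppressWarnings(stats::ks.test(lv_p1$level,
                                            group_mean_levels(s1$methylomes$non_pregnant_ccf)$level)$p.value),
            1e-6)
})

test_that("fragment truth ratios honour the mode contract and calibration", {
  cfg <- small_cfg(seed = 2)
  fm0 <- cfg$fragment_model
  fm0$length_coefs[] <- 0
  cfg0 <- small_cfg(seed = 2, fragment_model = fm0)
  fr0 <- simulate_fragments(cfg0, "wgbs_ccf")
  expect_equal(unname(fr0$truth$true_ratio["CpG"]), 1)

  sheared <- simulate_fragments(cfg, "sheared_genomic")
  expect_equal(unname(sheared$truth$true_ratio["CpG"]), 1)

  fm5 <- calibrate_length_meth_coef(cfg$fragment_model, target_ratio = 5)
  expect_equal(unname(analytic_length_meth_ratio(fm5)["CpG"]), 5, tolerance = 1e-8)
  pmf <- fragment_length_pmf(cfg$fragment_model)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
})

test_that("MCIp capture follows its limits and null", {
  cfg <- small_cfg(seed = 6, fragment_model = list(n_fragments = 8000L))
  fr <- simulate_fragments(cfg)$fragments
  mc0 <- simulate_mcip(fr, list(intercept = 0, slope = 0), seed = 6)
  n_m <- nrow(mc0$methylated$fragments)
  expect_lt(abs(n_m / 8000 - 0.5), 4 * sqrt(0.25 / 8000))
  expect_equal(n_m + nrow(mc0$unmethylated$fragments), 8000L)
  expect_length(intersect(mc0$methylated$fragments$frag_id,
                          mc0$unmethylated$fragments$frag_id), 0)

  # all-unmethylated fragments with a -> -inf: nothing captured
  calls <- copy(fr$calls)[, meth := FALSE]
  fr_u <- fragment_set(fr$fragments, calls)
  mc_empty <- simulate_mcip(fr_u, list(intercept = -50, slope = 2), seed = 6)
  expect_equal(nrow(mc_empty$methylated$fragments), 0L)
})

test_that("trisomy cohort counts scale chr21 with effective fetal fraction", {
  cfg <- sim_config(seed = 8, trisomy_model = list(n_euploid = 10L, n_trisomy = 2L,
                                                   depth = 1e6, enrichment_factor = 1))
  tri <- simulate_trisomy_cohort(cfg$trisomy_model, seed = 8)
  expect_equal(nrow(tri$counts), (10L + 2L) * 2L * 22L)
  totals <- tri$counts[, .(tot = sum(count)), by = .(sample_id, treatment)]
  expect_true(all(totals$tot == 1e6))
  # enrichment factor 1: enriched and unenriched trisomy shares agree closely
  fr <- chr21_fraction(tri$counts)
  tr_fr <- fr[grepl("tri", sample_id)]
  expect_lt(max(abs(tr_fr[treatment == "enriched"]$chr21_fraction -
                      tr_fr[treatment == "unenriched"]$chr21_fraction)),
            6 * sqrt(0.013 / 1e6))
  expect_warning(simulate_trisomy_cohort(
    sim_config(seed = 8, trisomy_model = list(enrichment_factor = 0.5))$trisomy_model,
    seed = 8), "depleted")
})
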