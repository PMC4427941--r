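# Preset simulation configurations: the synthetic study conditions used
# throughout the package's analyses and validation suite. Each preset
# fixes the generator at the conditions of one synthetic study; scripts
# and tests vary only the seed.

#' Preset synthetic study configurations
#'
#' These constructors freeze the conditions of the package's synthetic
#' studies so that analyses, tests and the acceptance script all run
#' the same experiment:
#'
#' * `config_dmr_study()`: two groups of six samples on a 20 Mbp
#'   genome at 15x coverage with 50 planted 12-CpG DMRs of effect 0.4
#'   (89.5% hypermethylated in the reference group), the regime in
#'   which the |t| >= 5 / <300 bp / >=9 CpG caller is evaluated. The
#'   planted DMRs are the only systematic group difference: the global
#'   intermediate shift is disabled, since it is an iid per-site
#'   marginal emulation, not the spatially coherent difference a
#'   region caller should be benchmarked against. `n_dmrs = 0` gives
#'   the matched null.
#' * `config_phd_study()`: placenta versus non-pregnant cfDNA groups
#'   on a 60 Mbp genome with 10 planted 2 Mbp domains hypomethylated
#'   by 0.25. The placenta background tracks the blood background here
#'   (no global intermediate shift), isolating domain recovery from
#'   the marginal distribution shift; `n_phds = 0` is the matched null.
#' * `config_mixture_study()`: maternal, placental and pregnant-cfDNA
#'   groups with placenta-hypomethylated DMRs only, for studying how a
#'   maternal+placental read mixture at fetal fraction `f`
#'   recapitulates the planted differential methylation.
#' * `config_fragment_study()`: cfDNA fragment model, optionally
#'   calibrated so the analytic long/short CpG methylation rate ratio
#'   equals `target_ratio`.
#' * `config_trisomy_study()`: robust-z cohort at 10^6 region reads
#'   with a 151-sample known-euploid reference panel (odd-sized, so
#'   the in-panel median z is exactly zero); `n_trisomy = 0` gives the
#'   euploid-only calibration cohort.
#'
#' @param seed Master seed.
#' @param n_dmrs,n_phds,n_trisomy Number of planted features (0 for the
#'   matched null).
#' @param fetal_fraction Fetal fraction of the pregnant mixture.
#' @param target_ratio Optional analytic long/short CpG ratio to
#'   calibrate the length-methylation coefficient to.
#' @param n_fragments Fragments to simulate.
#' @return A [sim_config()].
#' @name study_configs
NULL

#' @rdname study_configs
#' @export
config_dmr_study <- function(seed, n_dmrs = 50L) {
  sim_config(seed = seed,
             genome = data.frame(chrom = c("chr1", "chr2"),
                                 length = c(1e7, 1e7)),
             n_samples = c(non_pregnant_ccf = 6L, placenta = 6L),
             n_dmrs = n_dmrs, placenta_intermediate_shift = 0,
             strand_split = FALSE)
}

#' @rdname study_configs
#' @export
config_phd_study <- function(seed, n_phds = 10L) {
  sim_config(seed = seed,
             genome = data.frame(chrom = c("chr1", "chr2"),
                                 length = c(3e7, 3e7)),
             n_samples = c(non_pregnant_ccf = 8L, placenta = 5L),
             n_phds = n_phds, phd_bins = 40L,
             placenta_intermediate_shift = 0,
             strand_split = FALSE)
}

#' @rdname study_configs
#' @export
config_mixture_study <- function(seed, fetal_fraction = 0.10) {
  sim_config(seed = seed,
             genome = data.frame(chrom = "chr1", length = 5e6),
             n_samples = c(non_pregnant_ccf = 6L, pregnant_ccf = 6L,
                           placenta = 6L),
             n_dmrs = 25L, prop_hyper_reference = 1,
             fetal_fraction = fetal_fraction, strand_split = FALSE)
}

#' @rdname study_configs
#' @export
config_fragment_study <- function(seed, target_ratio = NULL,
                                  n_fragments = 60000L) {
  cfg <- sim_config(seed = seed,
                    fragment_model = list(n_fragments = as.integer(n_fragments)))
  if (!is.null(target_ratio))
    cfg$fragment_model <- calibrate_length_meth_coef(cfg$fragment_model,
                                                     target_ratio)
  cfg
}

#' @rdname study_configs
#' @export
config_trisomy_study <- function(seed, n_trisomy = 3L) {
  sim_config(seed = seed,
             trisomy_model = list(n_euploid = 151L,
                                  n_trisomy = as.integer(n_trisomy),
                                  fetal_fraction = 0.10,
                                  enrichment_factor = 4, depth = 1e6))
}
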