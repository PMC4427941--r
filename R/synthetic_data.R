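# Seeded generators for every input the pipeline consumes, with known
# ground truth: bimodal per-CpG methylomes with planted DMRs and
# hypomethylated domains, beta-binomial read counts, maternal+placental
# read mixtures, cfDNA fragments with a length-dependent methylation
# model, MCIp capture fractionation, and euploid/trisomy-21 region
# count cohorts.

#' Simulation configuration
#'
#' Builds and validates the configuration driving all generators.
#' Defaults emulate the statistical structure of whole-genome bisulfite
#' data from blood-derived cell-free DNA and placenta: bimodal per-CpG
#' methylation (low mode 0.05, high mode 0.90; blood-like class weights
#' 0.10/0.10/0.80, with a placenta-specific shift of sites into the
#' intermediate mode), Poisson(15) per-sample coverage, beta-binomial
#' inter-individual variation (concentration 400), planted DMRs as
#' constitutively methylated loci (0.98) dropping by the planted effect
#' in the hypomethylated group, planted multi-bin hypomethylated
#' domains, fragment lengths peaked at 168 bp with a logistic
#' length-methylation dependence, and a robust-z trisomy cohort with a
#' 150-sample euploid reference panel.
#'
#' Configurations whose planted effects would push any site mean
#' outside `[0, 1]` are rejected rather than clamped.
#'
#' @param seed Integer master seed. Per-generator streams are derived
#'   from it (methylomes `seed + 1`, fragments `seed + 2`, MCIp
#'   `seed + 3`, trisomy `seed + 4`).
#' @param ... Overrides for any default field; see the package vignette
#'   for the full schema.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = data.table(chrom = c("chr1", "chr2"), length = c(3e7, 3e7)),
    cpg_background_rate = 0.005,      # CpG loci per bp outside islands
    island_rate_per_mb = 8,
    island_width = 1000L,
    island_cpg_rate = 0.02,           # per bp within an island
    non_cpg_per_mb = c(CHG = 20, CHH = 60),
    non_cpg_meth_rate = 0.002,
    n_samples = c(non_pregnant_ccf = 8L, pregnant_ccf = 7L,
                  buffy_coat = 7L, placenta = 5L),
    coverage_mean = 15,
    overdispersion = 400,             # beta-binomial concentration
    mixture_blood = list(
      weights = c(low = 0.10, intermediate = 0.10, high = 0.80),
      means = c(low = 0.05, intermediate = 0.50, high = 0.90),
      concentrations = c(low = 20, intermediate = 8, high = 20)),
    placenta_intermediate_shift = 0.45,
    n_dmrs = 0L,
    dmr_n_cpg = 12L,
    dmr_effect = 0.4,
    dmr_hyper_anchor = 0.98,
    prop_hyper_reference = 0.895,
    dmr_spacing = c(20L, 80L),
    n_phds = 0L,
    phd_bins = 40L,
    phd_depth = 0.25,
    phd_concentration = 30,
    bin_size = 50000L,
    fetal_fraction = 0.10,
    strand_split = TRUE,
    fragment_model = list(
      n_fragments = 50000L,
      modal_length = 168, length_sd = 30,
      dinucleosome_prop = 0.08, dinucleosome_mode = 332, dinucleosome_sd = 50,
      min_length = 60L, max_length = 1000L,
      cytosine_rates = c(CpG = 0.010, CHG = 0.004, CHH = 0.015),
      base_rates = c(CpG = 0.12, CHG = 0.002, CHH = 0.002),
      length_coefs = c(CpG = 1.2, CHG = 1.2, CHH = 1.2),  # logit per 100 bp
      ref_length = 168),
    mcip_model = list(intercept = -2, slope = 1.5),
    trisomy_model = list(
      n_euploid = 150L, n_euploid_test = 0L, n_trisomy = 3L,
      fetal_fraction = 0.10, enrichment_factor = 4, depth = 1e6,
      chr21_share = 0.013, n_autosomes = 22L)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_("unknown sim_config field(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && !is.data.frame(cfg[[nm]]) && is.list(dots[[nm]])) {
      repl <- dots[[nm]]
      bad <- setdiff(names(repl), names(cfg[[nm]]))
      if (length(bad)) stop_("unknown field(s) in %s: %s", nm, paste(bad, collapse = ", "))
      cfg[[nm]][names(repl)] <- repl
    } else cfg[[nm]] <- dots[[nm]]
  }
  cfg$genome <- as.data.table(cfg$genome)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  v <- character()
  chk01 <- function(x, nm) if (any(x < 0 | x > 1)) v <<- c(v, sprintf("%s outside [0,1]", nm))
  if (!all(c("chrom", "length") %in% names(cfg$genome)) || nrow(cfg$genome) == 0L)
    v <- c(v, "genome must list (chrom, length)")
  mb <- cfg$mixture_blood
  if (abs(sum(mb$weights) - 1) > 1e-9) v <- c(v, "mixture weights must sum to 1")
  chk01(mb$means, "mixture means")
  chk01(cfg$placenta_intermediate_shift, "placenta_intermediate_shift")
  chk01(cfg$fetal_fraction, "fetal_fraction")
  chk01(cfg$non_cpg_meth_rate, "non_cpg_meth_rate")
  if (cfg$coverage_mean <= 0) v <- c(v, "coverage_mean must be positive")
  if (cfg$overdispersion <= 0) v <- c(v, "overdispersion must be positive")
  if (cfg$n_dmrs > 0) {
    if (cfg$dmr_effect <= 0) v <- c(v, "dmr_effect must be positive")
    hi <- cfg$dmr_hyper_anchor; lo <- hi - cfg$dmr_effect
    if (hi > 1 || hi < 0 || lo < 0 || lo > 1)
      v <- c(v, sprintf("planted DMR means %.3f/%.3f leave [0,1]; clamping is not allowed", hi, lo))
  }
  if (cfg$n_phds > 0) {
    base <- sum(mb$weights * mb$means)
    if (base - cfg$phd_depth < 0 || base - cfg$phd_depth > 1)
      v <- c(v, "phd_depth pushes the in-domain mean outside [0,1]")
  }
  fm <- cfg$fragment_model
  if (any(fm$base_rates <= 0 | fm$base_rates >= 1))
    v <- c(v, "fragment base_rates must lie strictly inside (0,1)")
  tm <- cfg$trisomy_model
  chk01(tm$chr21_share, "chr21_share")
  chk01(tm$fetal_fraction, "trisomy fetal_fraction")
  if (tm$n_euploid < 3) v <- c(v, "need >= 3 known-euploid samples per treatment")
  if (length(v)) stop_("invalid simulation config:\n  - %s", paste(v, collapse = "\n  - "))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> seed %d; genome %.1f Mbp; %d DMRs, %d PHDs planted; groups: %s\n",
    x$seed, sum(x$genome$length) / 1e6, x$n_dmrs, x$n_phds,
    paste(sprintf("%s(%d)", names(x$n_samples), x$n_samples), collapse = ", ")))
  invisible(x)
}

# ---- methylome simulation ---------------------------------------------------

mixture_mean <- function(mix) sum(mix$weights * mix$means)

draw_mixture_means <- function(n, mix) {
  comp <- sample.int(3L, n, replace = TRUE, prob = mix$weights)
  mu <- numeric(n)
  for (k in 1:3) {
    idx <- comp == k
    if (!any(idx)) next
    m <- mix$means[k]; cc <- mix$concentrations[k]
    mu[idx] <- rbeta(sum(idx), m * cc, (1 - m) * cc)
  }
  mu
}

draw_sample_levels <- function(mu, kappa) {
  p <- mu
  mid <- mu > 0 & mu < 1
  p[mid] <- rbeta(sum(mid), mu[mid] * kappa, (1 - mu[mid]) * kappa)
  p
}

#' Simulate group methylomes with planted DMRs and hypomethylated domains
#'
#' CpG loci are placed by a background-plus-island density model. Each
#' site receives a "blood" true mean from the bimodal mixture, shared
#' by the blood-like groups (`non_pregnant_ccf`, `buffy_coat`); the
#' placenta mean equals the blood mean except that a configured
#' fraction of sites is redrawn from the intermediate mode, sites in
#' planted hypomethylated domains are redrawn around
#' `mixture mean - phd_depth`, and planted DMR loci are overwritten
#' with the anchor means. Per sample, coverage is Poisson and
#' methylated counts beta-binomial around the group mean; the
#' `pregnant_ccf` group is emitted as a per-read mixture
#' `(1 - f) * maternal + f * placental`. With `strand_split`, each CpG
#' locus is emitted as a plus-strand call and a paired reverse-strand
#' call one base downstream, with reads apportioned at random between
#' strands, so that [collapse_strands()] reconstructs the locus.
#'
#' A fixed config (including seed) yields byte-identical output.
#'
#' @param config A `sim_config`.
#' @param groups Which groups to emit (default: all in
#'   `config$n_samples`).
#' @return List with `methylomes` (named list: group -> list of
#'   `methylome`) and `truth` (planted DMR/PHD intervals, site means,
#'   CpG positions).
#' @export
simulate_methylomes <- function(config, groups = names(config$n_samples)) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed + 1L, {
    geno <- config$genome
    cpg <- simulate_cpg_positions(config)
    planted <- plant_loci(config, cpg)
    cpg <- planted$cpg
    truth_dmrs <- planted$dmrs
    truth_phds <- planted$phds

    n_sites <- nrow(cpg)
    mu_blood <- draw_mixture_means(n_sites, config$mixture_blood)
    mu_plac <- mu_blood
    shift <- runif(n_sites) < config$placenta_intermediate_shift
    if (any(shift)) {
      mm <- config$mixture_blood$means["intermediate"]
      cc <- config$mixture_blood$concentrations["intermediate"]
      mu_plac[shift] <- rbeta(sum(shift), mm * cc, (1 - mm) * cc)
    }
    if (nrow(truth_phds)) {
      in_phd <- points_in_region(cpg$chrom, cpg$pos, truth_phds)
      if (any(in_phd)) {
        m <- mixture_mean(config$mixture_blood) - config$phd_depth
        cc <- config$phd_concentration
        mu_plac[in_phd] <- rbeta(sum(in_phd), m * cc, (1 - m) * cc)
      }
    }
    if (nrow(truth_dmrs)) {
      hi <- config$dmr_hyper_anchor; lo <- hi - config$dmr_effect
      for (i in seq_len(nrow(truth_dmrs))) {
        idx <- which(cpg$chrom == truth_dmrs$chrom[i] &
                     cpg$pos >= truth_dmrs$start[i] & cpg$pos < truth_dmrs$end[i])
        if (truth_dmrs$direction[i] == "hyper_in_reference") {
          mu_blood[idx] <- hi; mu_plac[idx] <- lo
        } else {
          mu_blood[idx] <- lo; mu_plac[idx] <- hi
        }
      }
    }

    non_cpg <- simulate_non_cpg_sites(config)
    methylomes <- list()
    for (g in groups) {
      n_g <- config$n_samples[[g]]
      samples <- vector("list", n_g)
      for (s in seq_len(n_g)) {
        sid <- sprintf("%s_%02d", g, s)
        samples[[s]] <- simulate_one_sample(config, g, sid, cpg,
                                            mu_blood, mu_plac, non_cpg)
      }
      methylomes[[g]] <- samples
    }
    truth <- list(
      cpg_positions = cpg,
      dmrs = truth_dmrs, phds = truth_phds,
      site_means = data.table(chrom = cpg$chrom, pos = cpg$pos,
                              mu_blood = mu_blood, mu_placenta = mu_plac))
    list(methylomes = methylomes, truth = truth)
  })
}

simulate_cpg_positions <- function(config) {
  out <- config$genome[, {
    n_bg <- rpois(1, cpg_background_rate_ * (length - 2L))
    pos <- sample.int(length - 2L, min(n_bg, length - 2L))
    n_isl <- rpois(1, island_rate_per_mb_ * length / 1e6)
    if (n_isl > 0) {
      centers <- sample.int(max(length - config$island_width - 2L, 1L), n_isl,
                            replace = TRUE)
      k <- rpois(n_isl, config$island_cpg_rate * config$island_width)
      ipos <- unlist(Map(function(c0, kk) {
        if (kk == 0) integer() else c0 + sample.int(config$island_width, kk,
                                                    replace = TRUE) - 1L
      }, centers, k))
      pos <- c(pos, ipos)
    }
    .(pos = sort(unique(as.integer(pos))))
  }, by = chrom,
  env = list(cpg_background_rate_ = config$cpg_background_rate,
             island_rate_per_mb_ = config$island_rate_per_mb)]
  out
}

plant_loci <- function(config, cpg) {
  geno <- config$genome
  dmrs <- data.table(chrom = character(), start = integer(), end = integer(),
                     n_cpg = integer(), direction = character(),
                     effect = numeric())
  phds <- data.table(chrom = character(), start = integer(), end = integer(),
                     n_bins = integer(), depth = numeric())
  if (config$n_phds > 0) {
    bs <- config$bin_size
    span <- config$phd_bins * bs
    taken <- data.table(chrom = character(), start = integer(), end = integer())
    for (i in seq_len(config$n_phds)) {
      for (try in 1:200) {
        ci <- sample.int(nrow(geno), 1, prob = geno$length)
        len <- geno$length[ci]
        if (len < span + 2 * bs) next
        start_bin <- sample.int((len - span) %/% bs - 1L, 1)
        s <- as.integer(start_bin * bs); e <- as.integer(s + span)
        pad <- data.table(chrom = geno$chrom[ci],
                          start = pmax(s - 2L * bs, 0L), end = e + 2L * bs)
        if (!any(overlaps_any_region(pad, taken))) {
          taken <- rbind(taken, pad[, .(chrom, start, end)])
          phds <- rbind(phds, data.table(chrom = geno$chrom[ci], start = s,
                                         end = e, n_bins = config$phd_bins,
                                         depth = config$phd_depth))
          break
        }
      }
    }
    setorder(phds, chrom, start)
  }
  if (config$n_dmrs > 0) {
    n_hyper_ref <- round(config$n_dmrs * config$prop_hyper_reference)
    dirs <- sample(c(rep("hyper_in_reference", n_hyper_ref),
                     rep("hyper_in_target", config$n_dmrs - n_hyper_ref)))
    taken <- data.table(chrom = character(), start = integer(), end = integer())
    for (i in seq_len(config$n_dmrs)) {
      for (try in 1:500) {
        ci <- sample.int(nrow(geno), 1, prob = geno$length)
        gaps <- sample(seq(config$dmr_spacing[1], config$dmr_spacing[2]),
                       config$dmr_n_cpg - 1L, replace = TRUE)
        span <- sum(gaps) + 2L
        s <- sample.int(geno$length[ci] - span - 1000L, 1)
        reg <- data.table(chrom = geno$chrom[ci], start = s - 400L, end = s + span + 400L)
        if (any(overlaps_any_region(reg, taken))) next
        taken <- rbind(taken, reg)
        positions <- as.integer(s + c(0L, cumsum(gaps)))
        # planted loci own their footprint: background CpGs there are dropped
        cpg <- cpg[!(chrom == geno$chrom[ci] & pos >= s - 1L & pos <= s + span + 1L)]
        cpg <- rbind(cpg, data.table(chrom = geno$chrom[ci], pos = positions))
        dmrs <- rbind(dmrs, data.table(chrom = geno$chrom[ci], start = s,
                                       end = as.integer(s + span),
                                       n_cpg = config$dmr_n_cpg,
                                       direction = dirs[i],
                                       effect = config$dmr_effect))
        break
      }
    }
    setorder(cpg, chrom, pos)
    setorder(dmrs, chrom, start)
  }
  list(cpg = cpg, dmrs = dmrs, phds = phds)
}

simulate_non_cpg_sites <- function(config) {
  rows <- list()
  for (ctx in names(config$non_cpg_per_mb)) {
    r <- config$genome[, {
      k <- rpois(1, config$non_cpg_per_mb[[ctx]] * length / 1e6)
      .(pos = sort(sample.int(length - 1L, min(k, length - 1L))))
    }, by = chrom]
    if (nrow(r)) { r[, context := ctx]; rows[[ctx]] <- r }
  }
  if (!length(rows))
    return(data.table(chrom = character(), pos = integer(), context = character()))
  rbindlist(rows)
}

simulate_one_sample <- function(config, group, sample_id, cpg,
                                mu_blood, mu_plac, non_cpg) {
  n <- nrow(cpg)
  kappa <- config$overdispersion
  cov <- rpois(n, config$coverage_mean)
  if (group == "pregnant_ccf") {
    f <- config$fetal_fraction
    pf <- draw_sample_levels(mu_plac, kappa)
    pm <- draw_sample_levels(mu_blood, kappa)
    nf <- rbinom(n, cov, f)
    meth <- rbinom(n, nf, pf) + rbinom(n, cov - nf, pm)
  } else {
    mu <- if (group == "placenta") mu_plac else mu_blood
    p <- draw_sample_levels(mu, kappa)
    meth <- rbinom(n, cov, p)
  }
  if (config$strand_split) {
    cov_p <- rbinom(n, cov, 0.5)
    meth_p <- rhyper(n, m = meth, n = cov - meth, k = cov_p)
    calls <- rbind(
      data.table(chrom = cpg$chrom, pos = cpg$pos, strand = "+",
                 context = "CpG", meth = meth_p, unmeth = cov_p - meth_p,
                 tri = "CGA"),
      data.table(chrom = cpg$chrom, pos = cpg$pos + 1L, strand = "-",
                 context = "CpG", meth = meth - meth_p,
                 unmeth = (cov - cov_p) - (meth - meth_p), tri = "CGT"))
  } else {
    calls <- data.table(chrom = cpg$chrom, pos = cpg$pos, strand = "+",
                        context = "CpG", meth = meth, unmeth = cov - meth,
                        tri = "CGA")
  }
  if (nrow(non_cpg)) {
    ncov <- rpois(nrow(non_cpg), config$coverage_mean)
    nmeth <- rbinom(nrow(non_cpg), ncov, config$non_cpg_meth_rate)
    calls <- rbind(calls,
                   data.table(chrom = non_cpg$chrom, pos = non_cpg$pos,
                              strand = "+", context = non_cpg$context,
                              meth = nmeth, unmeth = ncov - nmeth, tri = "CAA"))
  }
  methylome(calls, sample_id = sample_id, group = group,
            min_coverage = 1L, collapsed = FALSE)
}

# ---- fragment simulation ----------------------------------------------------

gamma_from_mode_sd <- function(mode, s) {
  theta <- (-mode + sqrt(mode^2 + 4 * s^2)) / 2
  list(shape = mode / theta + 1, scale = theta)
}

#' Exact length distribution of the fragment model
#'
#' The probability mass function of fragment length under the
#' mono/di-nucleosome gamma mixture, after rounding to integer bp and
#' clamping to `[min_length, max_length]`.
#'
#' @param model The `fragment_model` component of a [sim_config()].
#' @return data.table with `length` and `prob` (sums to 1).
#' @export
fragment_length_pmf <- function(model) {
  g1 <- gamma_from_mode_sd(model$modal_length, model$length_sd)
  g2 <- gamma_from_mode_sd(model$dinucleosome_mode, model$dinucleosome_sd)
  lens <- model$min_length:model$max_length
  cdf <- function(x) {
    (1 - model$dinucleosome_prop) * pgamma(x, g1$shape, scale = g1$scale) +
      model$dinucleosome_prop * pgamma(x, g2$shape, scale = g2$scale)
  }
  p <- cdf(lens + 0.5) - cdf(lens - 0.5)
  p[1] <- cdf(model$min_length + 0.5)
  p[length(p)] <- 1 - cdf(model$max_length - 0.5)
  data.table(length = lens, prob = p)
}

meth_prob_at_length <- function(model, len, context, mode) {
  base <- model$base_rates[[context]]
  if (mode == "sheared_genomic") return(rep(base, length(len)))
  plogis(qlogis(base) + model$length_coefs[[context]] *
           (len - model$ref_length) / 100)
}

#' Analytic long/short methylation rate ratio of the fragment model
#'
#' Computed exactly from the discrete length distribution: per context,
#' the expected per-cytosine methylation rate among cytosines on
#' fragments longer than `cutoff` divided by the rate on fragments of
#' at most `cutoff` bp (cytosine counts are proportional to length, so
#' lengths weight the average).
#'
#' @inheritParams fragment_length_pmf
#' @param mode `"wgbs_ccf"` (length-dependent methylation) or
#'   `"sheared_genomic"` (independent).
#' @param cutoff Long/short cutoff in bp.
#' @return Named ratio per context.
#' @export
analytic_length_meth_ratio <- function(model, mode = "wgbs_ccf", cutoff = 200L) {
  pmf <- fragment_length_pmf(model)
  vapply(names(model$base_rates), function(ctx) {
    p <- meth_prob_at_length(model, pmf$length, ctx, mode)
    w <- pmf$prob * pmf$length             # expected cytosines per length
    long <- pmf$length > cutoff
    (sum(w[long] * p[long]) / sum(w[long])) /
      (sum(w[!long] * p[!long]) / sum(w[!long]))
  }, numeric(1))
}

#' Calibrate the length-methylation coefficient to a target ratio
#'
#' Finds the logistic coefficient for one context such that the
#' analytic long/short rate ratio of [analytic_length_meth_ratio()]
#' equals `target_ratio`, holding the other model fields fixed.
#'
#' @inheritParams analytic_length_meth_ratio
#' @param target_ratio Desired ratio (> 0).
#' @param context Context to calibrate.
#' @return The updated fragment model.
#' @export
calibrate_length_meth_coef <- function(model, target_ratio, context = "CpG",
                                       cutoff = 200L) {
  if (target_ratio <= 0) stop_("target_ratio must be positive")
  f <- function(b) {
    m <- model; m$length_coefs[[context]] <- b
    analytic_length_meth_ratio(m, "wgbs_ccf", cutoff)[[context]] - target_ratio
  }
  # the ratio is 1 at b = 0 and saturates (non-monotonically) for large
  # |b|; walk outward from 0 along the relevant branch to bracket the
  # root closest to zero
  dir <- if (target_ratio >= 1) 1 else -1
  lo <- 0; f_lo <- f(0)
  hi <- NULL
  for (b in dir * seq(0.25, 30, by = 0.25)) {
    fb <- f(b)
    if (sign(fb) != sign(f_lo)) { hi <- b; break }
    lo <- b; f_lo <- fb
  }
  if (is.null(hi))
    stop_("target ratio %.3g is unattainable for this fragment model", target_ratio)
  b <- uniroot(f, lower = min(lo, hi), upper = max(lo, hi), tol = 1e-10)$root
  model$length_coefs[[context]] <- b
  model
}

#' Simulate cell-free DNA fragments with per-cytosine methylation calls
#'
#' Fragment lengths follow the mono/di-nucleosome gamma mixture (modal
#' length 168 bp by default); cytosines are placed at
#' context-specific densities along each fragment. In `wgbs_ccf` mode
#' the per-cytosine methylation probability is logistic in fragment
#' length; in `sheared_genomic` mode (emulating mechanically sheared
#' tissue DNA) it is length-independent, so the true long/short ratio
#' is exactly 1.
#'
#' @param config A `sim_config`.
#' @param mode `"wgbs_ccf"` or `"sheared_genomic"`.
#' @return List with `fragments` (a `fragment_set`) and `truth`
#'   (`mode`, analytic `true_ratio` per context).
#' @export
simulate_fragments <- function(config, mode = c("wgbs_ccf", "sheared_genomic")) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  fm <- config$fragment_model
  local_seed(config$seed + 2L, {
    n <- fm$n_fragments
    comp <- runif(n) < fm$dinucleosome_prop
    g1 <- gamma_from_mode_sd(fm$modal_length, fm$length_sd)
    g2 <- gamma_from_mode_sd(fm$dinucleosome_mode, fm$dinucleosome_sd)
    len <- numeric(n)
    len[!comp] <- rgamma(sum(!comp), g1$shape, scale = g1$scale)
    len[comp] <- rgamma(sum(comp), g2$shape, scale = g2$scale)
    len <- pmin(pmax(as.integer(round(len)), fm$min_length), fm$max_length)
    geno <- config$genome
    ci <- sample.int(nrow(geno), n, replace = TRUE, prob = geno$length)
    start <- as.integer(floor(runif(n) * (geno$length[ci] - len)))
    frags <- data.table(frag_id = seq_len(n), chrom = geno$chrom[ci],
                        start = start, end = start + len)
    calls <- rbindlist(lapply(names(fm$cytosine_rates), function(ctx) {
      k <- rpois(n, fm$cytosine_rates[[ctx]] * len)
      ids <- rep.int(seq_len(n), k)
      if (!length(ids))
        return(data.table(frag_id = integer(), offset = integer(),
                          context = character(), meth = logical()))
      flen <- len[ids]
      off <- as.integer(floor(runif(length(ids)) * flen))
      p <- meth_prob_at_length(fm, flen, ctx, mode)
      data.table(frag_id = ids, offset = off, context = ctx,
                 meth = runif(length(ids)) < p)
    }))
    list(fragments = fragment_set(frags[, .(frag_id, chrom, start, end)], calls),
         truth = list(mode = mode,
                      true_ratio = analytic_length_meth_ratio(fm, mode)))
  })
}

#' Simulate methyl-CpG immunoprecipitation fractionation
#'
#' Each fragment is assigned to the methylated (captured) fraction with
#' probability `plogis(intercept + slope * m)` where `m` is its number
#' of methylated CpG calls, emulating MBD-protein capture whose
#' affinity grows with methyl-CpG content. The partition is exhaustive
#' and exclusive.
#'
#' @param fs A `fragment_set`.
#' @param mcip_model List with `intercept` and `slope`.
#' @param seed Integer seed.
#' @return List with `methylated` and `unmethylated` `fragment_set`s.
#' @export
simulate_mcip <- function(fs, mcip_model = list(intercept = -2, slope = 1.5),
                          seed = 1L) {
  stopifnot(inherits(fs, "fragment_set"))
  local_seed(seed + 3L, {
    mcount <- fs$calls[context == "CpG" & meth == TRUE, .N, by = frag_id]
    m <- setNames(rep(0L, nrow(fs$fragments)), fs$fragments$frag_id)
    m[as.character(mcount$frag_id)] <- mcount$N
    p <- plogis(mcip_model$intercept + mcip_model$slope * as.numeric(m))
    captured <- runif(length(p)) < p
    list(methylated = subset_fragments(fs, fs$fragments$frag_id[captured]),
         unmethylated = subset_fragments(fs, fs$fragments$frag_id[!captured]))
  })
}

#' Simulate a euploid/trisomy-21 region count cohort
#'
#' Per sample and treatment, reads falling in the selected
#' (hypomethylated-domain) region subset are drawn multinomially over
#' autosomes. Chromosome 21 carries a baseline share `chr21_share` of
#' the region footprint; a trisomic fetus at fetal fraction `f`
#' inflates the expected chr21 share by `(1 + f_eff/2)` (renormalised),
#' where `f_eff = f` unenriched and `min(f * enrichment_factor, 1)`
#' after enrichment for unmethylated DNA. Euploid samples have
#' `f_eff = 0` under both treatments.
#'
#' @param model The `trisomy_model` component of a [sim_config()].
#' @param seed Integer seed.
#' @return List with `counts` (long table: `sample_id`, `treatment`,
#'   `euploid_known`, `chrom`, `count`) and `truth` (per-sample ploidy
#'   and fetal fraction).
#' @export
simulate_trisomy_cohort <- function(model, seed = 1L) {
  if (model$enrichment_factor < 1)
    warning("enrichment_factor < 1: 'enriched' samples are depleted")
  local_seed(seed + 4L, {
    p0 <- model$chr21_share
    other <- paste0("chr", setdiff(1:22, 21))[seq_len(model$n_autosomes - 1L)]
    chroms <- c(other, "chr21")
    base <- c(rep((1 - p0) / length(other), length(other)), p0)
    samples <- data.table(
      sample_id = c(sprintf("eup_%03d", seq_len(model$n_euploid + model$n_euploid_test)),
                    sprintf("tri_%03d", seq_len(model$n_trisomy))),
      ploidy = rep(c("euploid", "trisomy21"),
                   c(model$n_euploid + model$n_euploid_test, model$n_trisomy)),
      euploid_known = rep(c(TRUE, FALSE, FALSE),
                          c(model$n_euploid, model$n_euploid_test, model$n_trisomy)),
      fetal_fraction = model$fetal_fraction
    )
    rows <- list()
    for (i in seq_len(nrow(samples))) {
      for (tr in c("unenriched", "enriched")) {
        f_eff <- if (samples$ploidy[i] == "trisomy21") {
          if (tr == "enriched") min(samples$fetal_fraction[i] * model$enrichment_factor, 1)
          else samples$fetal_fraction[i]
        } else 0
        p21 <- p0 * (1 + f_eff / 2) / (1 + p0 * f_eff / 2)
        probs <- c(base[-length(base)] * (1 - p21) / (1 - p0), p21)
        cnt <- as.vector(rmultinom(1, size = model$depth, prob = probs))
        rows[[length(rows) + 1L]] <- data.table(
          sample_id = samples$sample_id[i], treatment = tr,
          euploid_known = samples$euploid_known[i], chrom = chroms, count = cnt)
      }
    }
    list(counts = rbindlist(rows), truth = samples)
  })
}
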