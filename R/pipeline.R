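# End-to-end orchestration: run the synthetic-data, summary, DMR, PHD,
# fragment and trisomy stages in dependency order, with deterministic
# seeding, output caching and a machine-readable JSON run manifest.

PIPELINE_STAGES <- c("simulate", "summary", "dmr", "phd", "fragments", "zscore")

#' Default pipeline parameters
#'
#' Analysis-stage settings layered on top of a [sim_config()]: group
#' comparison for DMR calling, calling thresholds and cutoffs. All
#' bespoke thresholds of the procedure live here so that the manifest
#' records them.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    group_a = "non_pregnant_ccf", group_b = "placenta",
    min_coverage = 1L, min_samples = 2L,
    t_min = 5, max_gap = 300L, min_cpg = 9L,
    bin_size = 50000L, delta = 0.15, min_run = 10L, min_cpg_per_bin = 10L,
    length_cutoff = 200L, size_threshold = 300L, short_cutoff = 100L,
    histogram_groups = c("non_pregnant_ccf", "buffy_coat", "placenta")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop_("unknown pipeline parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && !is.data.frame(v))
      v <- lapply(v[order(names(v))], sort_rec)
    v
  }
  as.character(toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA, dataframe = "rows"))
}

config_hash <- function(config, params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(canonical_json(unclass(config)), canonical_json(params)), tmp)
  unname(md5sum(tmp))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order over a synthetic
#' study defined by `config`, writing each stage's outputs under
#' `out_dir` and a `manifest.json` recording the configuration hash,
#' seeds, parameters and per-output checksums. A stage is skipped when
#' its outputs already exist and the stored configuration hash is
#' unchanged; rerunning an unchanged configuration therefore yields an
#' identical manifest hash. All randomness derives from `config$seed`,
#' so two full runs from the same config are byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `simulate`, `summary`, `dmr`, `phd`,
#'   `fragments`, `zscore`.
#' @param params [pipeline_params()] overrides.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = PIPELINE_STAGES,
                         params = pipeline_params()) {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config, params)
  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE) else NULL
  reuse <- !is.null(old_manifest) && identical(old_manifest$config_hash, hash)

  manifest <- list(
    tool = "cfmethylome", version = as.character(utils::packageVersion("cfmethylome")),
    config_hash = hash, seed = config$seed, params = params,
    stages = if (reuse) old_manifest$stages else list())

  needed <- function(st) {
    outs <- unlist(manifest$stages[[st]]$outputs)
    !reuse || is.null(outs) || !all(file.exists(file.path(out_dir, outs)))
  }
  record <- function(st, outs) {
    manifest$stages[[st]] <<- list(
      outputs = as.list(outs),
      md5 = as.list(unname(md5sum(file.path(out_dir, outs)))),
      skipped = FALSE)
  }

  sim_cache <- NULL
  get_sim <- function() {
    if (is.null(sim_cache)) sim_cache <<- simulate_methylomes(config)
    sim_cache
  }
  stage_outputs <- list()

  if ("simulate" %in% stages && needed("simulate")) {
    sim <- get_sim()
    outs <- character()
    dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
    for (g in names(sim$methylomes)) for (m in sim$methylomes[[g]]) {
      f <- file.path("reports", paste0(m$sample_id, ".cx.tsv"))
      write_cytosine_report(m, file.path(out_dir, f))
      outs <- c(outs, f)
    }
    write_bed(region_set(sim$truth$dmrs[, .(chrom, start, end)], "true_dmrs"),
              file.path(out_dir, "truth_dmrs.bed"))
    write_bed(region_set(sim$truth$phds[, .(chrom, start, end)], "true_phds"),
              file.path(out_dir, "truth_phds.bed"))
    fr <- simulate_fragments(config, "wgbs_ccf")
    write_fragments(fr$fragments, file.path(out_dir, "fragments.tsv"))
    tri <- simulate_trisomy_cohort(config$trisomy_model, config$seed)
    fwrite(tri$counts, file.path(out_dir, "region_counts.tsv"), sep = "\t")
    outs <- c(outs, "truth_dmrs.bed", "truth_phds.bed", "fragments.tsv",
              "region_counts.tsv")
    record("simulate", outs)
  } else if ("simulate" %in% stages) manifest$stages$simulate$skipped <- TRUE

  collapsed <- NULL
  get_collapsed <- function() {
    if (is.null(collapsed)) {
      sim <- get_sim()
      collapsed <<- lapply(sim$methylomes, function(g) lapply(g, collapse_strands))
    }
    collapsed
  }

  if ("summary" %in% stages && needed("summary")) {
    cm <- get_collapsed()
    outs <- character()
    for (g in intersect(params$histogram_groups, names(cm))) {
      lv <- group_mean_levels(cm[[g]])
      h <- histogram_1pct(lv)
      f <- paste0("summary_histogram_", g, ".tsv")
      fwrite(data.table(bin_low_pct = 0:99, proportion = h$proportions),
             file.path(out_dir, f), sep = "\t")
      outs <- c(outs, f)
    }
    cls <- lapply(intersect(params$histogram_groups, names(cm)), function(g)
      c(list(group = g), as.list(classify_sites(group_mean_levels(cm[[g]])$level))))
    write_json(cls, file.path(out_dir, "summary_classes.json"),
               auto_unbox = TRUE, digits = NA)
    outs <- c(outs, "summary_classes.json")
    record("summary", outs)
  } else if ("summary" %in% stages) manifest$stages$summary$skipped <- TRUE

  if ("dmr" %in% stages && needed("dmr")) {
    cm <- get_collapsed()
    sa <- group_site_stats(cm[[params$group_a]], params$min_coverage, params$min_samples)
    sb <- group_site_stats(cm[[params$group_b]], params$min_coverage, params$min_samples)
    dmrs <- call_dmrs(filter_sites(site_t(sa, sb), params$t_min),
                      params$max_gap, params$min_cpg)
    write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    record("dmr", "dmrs.bed")
    stage_outputs$dmrs <- dmrs
  } else if ("dmr" %in% stages) manifest$stages$dmr$skipped <- TRUE

  if ("phd" %in% stages && needed("phd")) {
    cm <- get_collapsed()
    sim <- get_sim()
    gl <- list(group_mean_levels(cm[[params$group_b]]),
               group_mean_levels(cm[[params$group_a]]))
    names(gl) <- c(params$group_b, params$group_a)
    bins <- bin_genome(gl, sim$truth$cpg_positions,
                       config$genome[, .(chrom, length)],
                       bin_size = params$bin_size)
    phds <- call_phds(bins, params$group_b, params$group_a,
                      params$delta, params$min_run, params$min_cpg_per_bin)
    write_bed(region_set(as.data.table(phds)[, .(chrom, start, end)], "phds"),
              file.path(out_dir, "phds.bed"))
    outs <- "phds.bed"
    for (g in names(gl)) {
      f <- paste0("bins_", g, ".bedgraph")
      write_bedgraph(bins, g, file.path(out_dir, f))
      outs <- c(outs, f)
    }
    record("phd", outs)
  } else if ("phd" %in% stages) manifest$stages$phd$skipped <- TRUE

  if ("fragments" %in% stages && needed("fragments")) {
    fr <- simulate_fragments(config, "wgbs_ccf")
    mbl <- methylation_by_length(fr$fragments, params$length_cutoff)
    fwrite(mbl, file.path(out_dir, "fragment_meth_by_length.tsv"), sep = "\t")
    lh <- length_histogram(fr$fragments)
    fwrite(lh$hist, file.path(out_dir, "fragment_lengths.tsv"), sep = "\t")
    mc <- simulate_mcip(fr$fragments, config$mcip_model, config$seed)
    fsc <- fraction_size_comparison(mc$unmethylated, mc$methylated,
                                    params$size_threshold)
    write_json(list(modal_length = lh$modal_length,
                    size_fractions = fsc),
               file.path(out_dir, "fragment_summary.json"),
               auto_unbox = TRUE, digits = NA)
    record("fragments", c("fragment_meth_by_length.tsv", "fragment_lengths.tsv",
                          "fragment_summary.json"))
  } else if ("fragments" %in% stages) manifest$stages$fragments$skipped <- TRUE

  if ("zscore" %in% stages && needed("zscore")) {
    tri <- simulate_trisomy_cohort(config$trisomy_model, config$seed)
    zres <- robust_z(tri$counts)
    fwrite(zres, file.path(out_dir, "zscores.tsv"), sep = "\t")
    record("zscore", "zscores.tsv")
  } else if ("zscore" %in% stages) manifest$stages$zscore$skipped <- TRUE

  write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
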