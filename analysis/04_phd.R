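#!/usr/bin/env Rscript
# Stage 4: placenta hypomethylated domains. A 60 Mbp genome carries 10
# planted 2 Mbp domains (0.25 hypomethylation) plus 40 planted DMRs;
# the genome is tiled into 50 kbp bins, domains are called as maximal
# runs of >= 10 qualifying bins, and hypomethylated DMRs are
# intersected with the called domains. Differential methylation is
# also stratified by local CpG density.

suppressMessages({library(cfmethylome); library(data.table)})

cfg <- sim_config(
  seed = 14004L,
  genome = data.frame(chrom = c("chr1", "chr2"), length = c(3e7, 3e7)),
  n_samples = c(non_pregnant_ccf = 8L, placenta = 5L),
  n_phds = 10L, phd_bins = 40L, n_dmrs = 40L,
  placenta_intermediate_shift = 0, strand_split = FALSE)
sim <- simulate_methylomes(cfg)

gl <- list(placenta = group_mean_levels(sim$methylomes$placenta),
           non_pregnant_ccf = group_mean_levels(sim$methylomes$non_pregnant_ccf))
bins <- bin_genome(gl, sim$truth$cpg_positions, cfg$genome[, .(chrom, length)],
                   bin_size = cfg$bin_size)
phds <- call_phds(bins, "placenta", "non_pregnant_ccf")

cat(sprintf("%d domains called spanning %.1f Mbp (planted: %d x 2 Mbp)\n",
            nrow(phds), sum(phds$end - phds$start) / 1e6, nrow(sim$truth$phds)))
cat(sprintf("within domains: cfDNA mean %.1f%%, placenta mean %.1f%%\n",
            100 * mean(phds$mean_meth_reference),
            100 * mean(phds$mean_meth_target)))

sa <- group_site_stats(sim$methylomes$non_pregnant_ccf)
sb <- group_site_stats(sim$methylomes$placenta)
dmrs <- suppressMessages(call_dmrs(filter_sites(site_t(sa, sb))))
hypo <- dmrs[direction == "hyper_in_A"]   # hypomethylated in placenta
frac_in <- dmr_phd_overlap(hypo, phds)
cat(sprintf("%.1f%% of %d hypomethylated DMRs fall inside called domains\n",
            100 * frac_in, nrow(hypo)))
cat(sprintf("(domain footprint is %.1f%% of the genome)\n",
            100 * sum(phds$end - phds$start) / sum(cfg$genome$length)))

dens_br <- unique(c(0, unname(quantile(bins$cpg_count[bins$cpg_count > 0],
                                       c(0.25, 0.5, 0.75))), Inf))
ds <- density_stratified_diff(bins, "placenta", "non_pregnant_ccf",
                              breaks = dens_br)
cat("differential methylation (placenta - cfDNA) by CpG density stratum:\n")
print(ds$table)

dir.create("results", showWarnings = FALSE)
write_bed(region_set(as.data.table(phds)[, .(chrom, start, end)], "phds"),
          "results/04_phds.bed")
fwrite(as.data.table(phds), "results/04_phd_domains.tsv", sep = "\t")
fwrite(ds$table, "results/04_density_strata.tsv", sep = "\t")
fwrite(data.table(hypo_dmrs = nrow(hypo), fraction_in_domains = frac_in),
       "results/04_dmr_domain_overlap.tsv", sep = "\t")
cat("wrote results/04_phds.bed, 04_phd_domains.tsv, 04_density_strata.tsv, 04_dmr_domain_overlap.tsv\n")
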