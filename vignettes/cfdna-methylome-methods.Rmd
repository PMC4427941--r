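---
title: "Models and methods: cfDNA methylome analysis with planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cfDNA methylome analysis with planted-truth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`cfmethylome` implements the downstream analyses of whole-genome
bisulfite sequencing (WGBS) of circulating cell-free DNA (cfDNA) and
its tissue contributors — non-pregnant and pregnant plasma cfDNA,
maternal buffy coat and placenta. Upstream alignment and methylation
calling are out of scope: the package consumes the per-cytosine report
a bisulfite caller emits (chromosome, 1-based position, strand,
methylated count, unmethylated count, context, trinucleotide) and
standard BED region sets. Internally every coordinate is 0-based
half-open; the report dialect's 1-based positions are converted on
read, so one convention holds everywhere downstream.

Because the real study data are controlled-access, every analysis here
runs against a seeded synthetic generator whose structure emulates the
data's statistics with known ground truth. All validation is therefore
*property-based*: recovery of planted features, agreement with
independent brute-force oracles, and exact invariants.

## Strand collapse

Mammalian CpG methylation is symmetric across strands in almost all
contexts, so calls mapped to the reverse strand are moved to the
position of the plus-strand C (one base upstream) and read counts are
summed; methylation levels are then recomputed from summed counts.
Summing counts rather than averaging levels keeps deeply and shallowly
covered strands weighted by evidence. The operation is idempotent and
conserves total methylated/unmethylated counts per chromosome — both
asserted in the test suite, alongside an exact write/read round trip.

## Site levels and group summaries

The level of a site in one sample is `meth / (meth + unmeth)`. A
*group* level at a site is the unweighted mean of per-sample fractions,
not the pooled-count fraction: pooling would weight deeply sequenced
samples and conflate coverage with biology. This choice is exposed
(`min_samples`, `min_coverage`) rather than hard-coded; the default
coverage floor is a single read, because a floor is a study-design
decision, not a property of the estimator.

Classification into low / intermediate / high methylation uses strict
cuts at 20% and 75% — "less than" and "greater than" — so the
intermediate class is the closed interval `[0.20, 0.75]`. Histograms
use 100 half-open 1% bins with exactly-100% assigned to the top bin;
their proportions and the class fractions each sum to 1 exactly.

The regional profile pairs the CpG levels inside a region set with an
equally sized, seeded, uniform without-replacement sample of CpGs
strictly outside it. Uniform sampling is the least-informative choice
given that no background distribution is specified; the seed makes the
contrast bit-for-bit reproducible.

## The DMR caller

Differential methylation between two sample groups is called in four
steps, each a separate function:

1. per-site group mean and standard deviation (n−1 denominator) of the
   per-sample fractions;
2. a per-site *Welch* t-statistic
   `t = (m_A - m_B) / sqrt(s_A^2/n_A + s_B^2/n_B)`. The Welch form is
   used because group sizes are unequal (5–8 samples) and there is no
   justification for pooling variances. When both groups have zero
   variance and equal means, `t = 0`; with differing means the site
   gets a signed infinite sentinel so that maximally separated,
   fully-methylated-vs-unmethylated sites pass any finite threshold
   instead of being silently dropped;
3. removal of sites with `|t| < 5` (strictly below; a site at exactly
   5 survives);
4. grouping of surviving sites: consecutive sites on one chromosome
   join a group while the gap between CpG anchors is strictly under
   300 bp; by default a sign change in the mean difference also closes
   the group, since a reported region has a single direction. Groups
   of at least 9 CpG sites become DMRs, spanning the first member
   through the last member + 2 (covering the final dinucleotide in
   half-open coordinates).

No multiple-testing correction is applied: the `|t| >= 5` cut *is* the
procedure. The caller is verified against a literal brute-force
enumerator of the rule on 500 random instances, and by an
anti-symmetry property (swapping groups flips every sign and
direction, coordinates unchanged).

### Power at the benchmark conditions

The benchmark study uses 6 vs 6 samples at Poisson(15) coverage with
planted 12-CpG DMRs of effect 0.4. A design-stage Monte-Carlo power
analysis of the Welch statistic showed that at 15x coverage the
binomial counting noise alone caps the per-site pass probability: with
anchors 0.85/0.45 it is ~0.69, far too low for reliable recovery of a
12-CpG region through a 9-of-12 rule. Planted DMRs are therefore
modeled as *constitutively methylated* loci — mean 0.98 on the
hypermethylated side, dropping to 0.58 — with inter-individual
beta-binomial concentration 400 (about 2.5% SD at intermediate
levels). Both choices are realistic for strong tissue-specific DMRs,
where the blood side is near-fully methylated and between-donor
variation is small, and they were fixed from this power analysis
before any recovery run, not tuned afterwards. At these conditions the
per-site pass probability is ~0.90 and region-level sensitivity ~0.95.

### What the matched null means

The generator has an iid per-site "placenta intermediate shift" that
redraws 45% of placenta site means from the intermediate mode. It
exists to emulate the *marginal* distribution of placenta methylation
(the intermediate excess in 1%-bin histograms). It is deliberately
disabled in the DMR and domain benchmarks: an iid shift plants genuine
single-site group differences at 45% of sites, which a region caller
then assembles into "false" regions that are not false at the site
level. Spatially coherent placenta hypomethylation is represented
explicitly by the planted DMRs and domains instead. Consequently the
benchmarks show the caller's behaviour when planted features are the
only systematic differences; they do not certify behaviour under
unmodeled spatially structured noise.

## Hypomethylated domain detection

The genome is tiled into 50 kbp bins (the trailing bin of a chromosome
may be short). A bin's group mean is the unweighted mean of the site
group-means falling in it (undefined below `min_sites_per_bin`);
`cpg_count` and `gene_count` count CpG loci and overlapping gene
intervals (a long gene counts in several bins). Domains are maximal
runs of consecutive qualifying bins — both means defined, reference
minus target at least `delta`, at least `min_cpg_per_bin` CpGs — of
length at least `min_run`, with no gap tolerance. Domain-level means
weight member bins by CpG count so that summaries reflect site mass,
while bin means stay unweighted for consistency with the site
summaries.

No formal calling rule exists to copy, so the defaults —
`delta = 0.15`, `min_run = 10` bins (500 kbp), `min_cpg_per_bin = 10`
— were chosen conservatively: with ~250 CpGs per bin and bimodal
site-level spread, a null bin-difference has SD ≈ 0.027, so a single
bin qualifies by chance with probability ~10⁻⁴ and a 10-bin run is
essentially impossible, while planted 0.25-deep domains qualify
per-bin with probability ≈ 1 − 3×10⁻⁶. The benchmark plants ten 2 Mbp
domains on a 60 Mbp genome and requires exact run recovery within 2
bins of each boundary and zero calls across 20 null simulations.

The density-stratified differential methylation table and its loess
smooth (span 0.3, descriptive only, never used for calling) summarise
how hypomethylation depth varies with local CpG density.

## Fragment length and methylation

Fragment length is `end − start` of the aligned pair. cfDNA-mode
lengths follow a discretised gamma mixture: a mononucleosome component
with mode 168 bp (SD 30) and an 8% dinucleosome component with mode
332 bp (SD 50), truncated to [60, 1000] bp. With 1 bp bins the modal
length is read directly off the histogram (ties break to the smaller
length); near the peak the distribution is flat enough that the
empirical mode wanders a few bp at 5×10⁴ fragments, which the tests
allow for.

Per-cytosine methylation probability is logistic in fragment length.
The long/short comparison is a *rate ratio*: methylated calls over
total calls in fragments >200 bp, divided by the same rate in
fragments ≤200 bp (a 200 bp fragment falls in the short class by
default; a flag drops the boundary instead, and this normalisation-by
-cytosine-count is the stated reading of several possible ones). The
generator's analytic ratio is computed exactly from the discrete
length pmf — cytosine counts are proportional to length, so lengths
weight the average — and a root-finder calibrates the logistic
coefficient to any attainable target ratio; saturation caps the
attainable ratio (about 5.3 at the default base rate of 0.12), and the
calibrator reports unattainable targets rather than silently
saturating. Mechanically sheared control fragments use the same
machinery with length-independent methylation, so their true ratio is
exactly 1.

MCIp (methyl-CpG immunoprecipitation) is simulated as per-fragment
capture with probability `plogis(a + b·m)`, `m` the fragment's
methylated-CpG count — a minimal monotone model of MBD-protein
affinity. MCIp paired-read filtering discards discordant pairs and
pairs with size (distance between mate start sites) above 500 bp;
mis-ordered concordant mates are an error, not silently absolute-valued.
Short-fragment region enrichment assigns each fragment by its midpoint
(half-open), which is unambiguous for boundary-spanning fragments.

## Robust trisomy-21 z-scores

Within each treatment stratum (unenriched / MCIp-enriched)
independently, the chromosome-21 read fraction over the
hypomethylated-domain-restricted count table is scored as
`z = (fraction − median) / MAD`, where median and MAD are computed
over *known-euploid samples only*. The MAD is unscaled — the raw
median of absolute deviations — exactly as the formula is written; a
flag enables the 1.4826-scaled variant. Test samples never contribute
to the reference even when euploid. With an odd reference panel the
in-panel median z is exactly 0 in floating point, which the suite
asserts; an even panel leaves a ~10⁻¹⁹ residue, so the default panel
size is odd.

A design-stage calibration study showed the unscaled-MAD z is
anti-conservative with small panels: the euploid `|z| > 3` rate is
~8–10% with 9–12 reference samples, ~5.4% at 40 and ~4.5% at 150,
against a 4.3% asymptote. The default reference panel is therefore 151
known euploids — realistic for NIPT validation cohorts — and the
12-donor configuration is retained only as a descriptive scenario
illustrating the instability. Trisomy at fetal fraction `f` inflates
the expected chr21 share by `(1 + f_eff/2)` (renormalised), with
`f_eff` multiplied by the enrichment factor (capped at 1) after
enrichment for unmethylated DNA; at 10⁶ region reads, `f = 0.10` and
4× enrichment, enriched trisomy z-scores exceed 3 essentially always,
and the mean enriched/unenriched z fold sits slightly above the
enrichment factor because the unenriched z in the denominator is
noisy.

## The synthetic generator

CpG loci are placed by a background Poisson process (0.005/bp;
~250 per 50 kbp bin) plus CpG islands (8 per Mbp, 1 kbp wide,
0.02/bp). Site means are drawn from a bimodal beta mixture — low mode
0.05, intermediate 0.50, high 0.90 with blood-like weights
0.10/0.10/0.80 — shared between the blood-like groups, which is why
their group methylomes correlate highly. Placenta redraws a configured
fraction (0.45) of sites from the intermediate mode, reproducing the
placental intermediate-methylation excess in marginal summaries.
Planted domains redraw placenta means around the blood mixture mean
minus the planted depth (concentration 30); planted DMR loci carry 12
CpGs at 20–80 bp spacing (region-scale differential methylation
occurs in locally CpG-dense context, and the spacing keeps a planted
region from being split by its own gaps) and overwrite both groups'
anchors. Per sample, coverage is Poisson(15) per site — the >10×
regime of deep WGBS without modeling mappability — methylated counts
are beta-binomial (concentration 400) around the group mean, and the
pregnant group draws each read from the placental methylome with
probability `f` and the maternal one otherwise. CpG loci are emitted
as paired plus/minus-strand calls (reads apportioned hypergeometrically)
so the strand-collapse path is exercised on realistic input. One
master seed feeds fixed per-generator streams (methylomes +1,
fragments +2, MCIp +3, trisomy +4), output is byte-identical across
runs, and the caller's RNG state is restored.

What the generator does *not* emulate: mappability and GC bias,
sequencing error and bisulfite conversion failure, the 10 bp
nucleosomal periodicity and adapter-trimming dip of real length
profiles, spatially correlated background beyond the planted features,
and chromosome-specific count biases (counts outside chr21 are split
uniformly). Passing benchmarks therefore demonstrates correctness of
the procedures under the stated statistical structure, not performance
on real cfDNA.

## Problem sizes and seeds

The validation studies run at: 20 Mbp / 6 vs 6 for DMR recovery (50
planted DMRs; 20 matched-null seeds), 60 Mbp / 8 vs 5 for domain
recovery (10 domains; 20 null seeds), 6×10⁴ fragments (~10⁵ CpG
calls) for the length-methylation ratio, 20 seeds for MCIp
monotonicity, and 100 cohorts of 151 euploids (±3 trisomies) at 10⁶
reads for z calibration and power. These sizes put Monte-Carlo noise
well inside the asserted tolerances while keeping each study in the
seconds-to-minutes range. `scripts/acceptance.R --seed N` re-runs all
of them from scratch under a caller-chosen seed.

## Known limitations

* The DMR caller implements exactly the fixed-threshold procedure; it
  is not a smoothing or HMM caller and applies no FDR control.
* Domain calling has no gap tolerance; one disqualified bin splits a
  domain. At the benchmark noise levels this is the intended
  behaviour; for sparser data a gap-tolerant variant would be needed.
* The long/short fold ratio saturates with the logistic model, so very
  large ratios require low base rates.
* `group_correlation` compares shared sites only and is silent about
  sites private to either group.
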