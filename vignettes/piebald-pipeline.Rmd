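---
title: "Mapping piebald plumage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping piebald plumage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piebaldkit)
```

piebaldkit implements the computational arm of a genetic dissection of
piebald plumage patterning in the domestic pigeon: quantifying the
proportion of white plumage per body region, building F2 linkage maps,
scanning for quantitative trait loci (QTL), testing genome-wide
allele-frequency differentiation between piebald and non-piebald breed
panels, detecting conserved noncoding elements (CNEs) and
transcription-factor binding-site (TFBS) turnover, and calling a tandem
duplication from read depth with copy-specific expression analysis. Every
stage is paired with a synthetic-data generator that plants known truth, so
the whole pipeline can be exercised and validated at desk scale.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the underlying study left
the procedure open.

## Phenotype quantification

Each bird is divided into 15 canonical body regions (`plumage_regions()`).
For a region with `W` pixels in the whole-region mask and `P` pixels in the
pigmented-only mask, the white proportion is `(W - P) / W`. `score_table()`
validates region names against the canonical vocabulary, rejects duplicate
(individual, region) records, and leaves unscored regions missing —
bilaterally duplicated regions with missing feathers are simply missing
values, since no imputation rule is defensible from counts alone.

## F2 linkage maps

Map construction follows a staged, order-fixed pipeline
(`build_linkage_map()`):

1. **Segregation-distortion filter.** Autosomal markers are tested against
   the 1:2:1 F2 expectation by a chi-square goodness-of-fit test (df = 2),
   Bonferroni-corrected across the markers tested (drop when
   `p < alpha / M`, `alpha = 0.01`). Z-linked markers segregate differently
   in an intercross and are never tested here; they are mapped in a
   separate pass. The genotype-class 1:2:1 test (rather than an allele-level
   1:1 test) is the standard choice for codominant F2 markers.
2. **Duplicate collapse.** Markers with byte-identical call vectors
   (including the missingness pattern) are collapsed to one representative
   (lowest scaffold, then lowest bp). Strict identity is deliberate: a
   single differing missing cell is treated as independent information.
3. **Genotyping-rate filter.** Pass 1 removes markers typed in under 50% of
   birds; pass 2 applies only to scaffolds retaining more than 40 markers
   and removes markers typed in under 66%.
4. **Pairwise linkage.** `estimate_rf()` maximizes the phase-known F2
   two-locus likelihood over `r` in `[0, 0.5]` by 1-D numerical
   optimization (both parental meioses recombine independently), using
   pairwise-complete individuals; `lod_linkage = log10 L(r_hat) - log10 L(0.5)`.
   Pairs with fewer than 10 jointly typed individuals are flagged
   low-information.
5. **Grouping.** Markers are linked iff `r_hat <= 0.15` and `LOD >= 6`;
   linkage groups are connected components of that graph.
6. **Ordering and spacing.** Within a scaffold, bp order is trusted.
   Scaffolds within a group are chained greedily by terminal-marker
   recombination fractions, orienting each scaffold so its nearer end
   connects — an automation of what is usually a manual curation step; an
   explicit order can be substituted by calling `order_and_space()` on a
   pre-arranged marker set. Adjacent spacing is the Haldane transform
   `d = -50 ln(1 - 2r)`; unlinked adjacencies (`r ~ 0.5`) produce infinite
   distances and are capped (default 50 cM) and flagged.
7. **Genotype cleaning.** For each call on the map, `error_lod()` computes
   the log10 posterior odds that the true genotype differs from the
   observed call, with the posterior taken from the F2 genotype HMM
   conditioned on the flanking markers only (the call's own emission is
   left out, so the score is not self-confirming). Calls above threshold 5
   are set to missing. On sparse maps (~5 cM spacing) a single double
   recombinant cannot exceed LOD 5 at the default assumed error rate of
   0.01 — the dominant alternative explanation is that both flanks are
   miscalled — and this is correct behaviour, not a missed call; on dense
   (~1 cM) maps planted errors separate from correct calls with AUC > 0.99.
8. **Drop-one-marker refinement.** Each marker is dropped if (a) the
   multipoint HMM likelihood of the full data is higher with that marker
   treated as unlinked (its column scored under the stationary 1:2:1 prior
   with the same error model) than with it on the map — this makes the two
   hypotheses comparable on identical data — or (b) it is non-terminal and
   removing it shrinks the group by more than 10 cM without physical
   support. "Without physical support" is quantified as flanking markers on
   the same scaffold within 1 Mb (configurable); the rule never removes
   terminal markers. Iterates to a fixpoint.

The Haldane map function (no crossover interference) is used throughout —
in the gamete simulator, the spacing transform, and the HMM transitions —
so simulation and inference share one genetic model.

## QTL scanning

`calc_genoprob()` runs a three-state (AA/AB/BB) hidden Markov model along
each linkage group: stationary prior (1/4, 1/2, 1/4); transitions between
positions `d` cM apart from two independent meioses, each recombining with
`r = (1 - exp(-d/50))/2`; emissions from a symmetric miscall model (correct
with probability `1 - e`, each wrong class `e/2`; missing calls emit
uniformly). Pseudo-markers are inserted every `step_cM` (default 1 cM).
Posterior vectors sum to one within 1e-9 by construction and are checked in
the tests.

`hk_scan()` performs Haley–Knott regression: at each position the phenotype
is regressed on the expected additive dosage `P(BB) - P(AA)` and the
expected dominance indicator `P(AB)`, and
`LOD = (n/2) log10(RSS0/RSS1)` against the intercept-only model. White
proportions are scanned untransformed: they are bounded in `[0, 1]`, and a
Gaussian working model on proportions is a deliberate fidelity-over-purism
choice (a logit transform can be applied to the phenotype upstream by the
user; it is not applied by default). Perfect fits are capped at LOD 999.
Missing phenotypes are dropped listwise.

`perm_threshold()` permutes the phenotype against the intact genotype
structure (default 1000 permutations) and takes the empirical 95th
percentile of the genome-wide maximum LOD, with the quantile method fixed
to type-7 linear interpolation for bit-reproducibility. Calibration on null
crosses (no QTL) puts the empirical genome-wide type-I error close to the
nominal 0.05 (the package's acceptance run reports it at 200 permutations
x 100 replicates).

`lod_interval()` reports 2-LOD support intervals, expanded to the flanking
evaluated positions just beyond the drop boundary (so the interval is
conservative on a discrete grid); peak ties break to the left-most position
and are flagged. `pve()` converts a peak LOD to the proportion of variance
explained, `1 - 10^(-2 LOD / n)`. Z-linked groups are scanned with the
autosomal model and flagged; no Z-specific scan model is implemented.

## Population differentiation

`pfst_site()` tests allele-frequency differences between case (piebald) and
background panels while propagating genotype uncertainty. For a group with
alt-allele frequency `p`, each sample contributes
`L_i(p) = sum_g 10^(-PL_ig/10) HWE(g | p)` where `PL` are phred-scaled
genotype likelihoods and `HWE(g|p)` the Hardy–Weinberg genotype priors.
`p` is fitted by 1-D maximization per group (alternative) and pooled
(null); the statistic is `2 (lnL_case + lnL_bg - lnL_pooled)` with a
chi-square df = 1 p-value. This is this package's documented reading of a
"genotype-likelihood modified likelihood-ratio test"; the exact formula of
the original GPAT++ implementation is unpublished, so results may differ in
detail from that tool. With numerically certain likelihoods the statistic
reduces to the hard-call binomial LRT, and it agrees with a brute-force
frequency-grid oracle to 1e-6 in the tests. The statistic is discrete at
finite sample size, so null p-values are uniform only approximately;
empirical type-I error at 0.05 is calibrated within [0.03, 0.07] at desk
scale. Genome-wide significance uses Bonferroni: `0.05 / n_sites`.

`candidate_snp_filter()` implements the fixation rule used to shortlist
causal candidates: a site qualifies iff every non-missing case sample is
homozygous-alt (with case call rate at least 0.8, a guard the source
procedure left unstated) and no background sample is homozygous-alt at any
call rate. The filter is verified against an exhaustive truth-table oracle
over all genotype combinations of small panels.

`delineate_groups()` clusters case samples by Jaccard similarity of their
homozygous-alt site sets (average linkage, cut at similarity 0.5 by
default) and keeps clusters whose shared fixed set has at least 5 SNPs.
The corresponding step in the underlying study was at least partly manual
curation of a genotype heatmap; an automated rule can split or merge
borderline samples differently, which is why both the cut height and the
minimum defining-set size are exposed.

## Conserved noncoding elements and TFBS turnover

`species_conserved_regions()` slides a 100-bp reference-anchored window
(step 1) along the alignment; identity is matches over window length with
gaps and ambiguous bases counting as mismatches, and a base qualifies when
any covering window exceeds 70% identity. Because every base touched by a
passing window qualifies, raw runs bleed tens of bp into ~40%-identity
background (a window straddling the edge still clears 70%); each run is
therefore trimmed to its maximal-scoring subsegment under per-base scores
`match - 0.70`, which places boundaries within a few bp of the identity
change-point without eroding the conserved core. The trim is on by default
(`refine_boundaries`) and can be disabled to obtain the raw windowed rule.
Whether the 70% criterion applies per window or over the whole element was
ambiguous in the source; the per-window reading is implemented, with
window, identity, and length all configurable.

`detect_cnes()` counts, per reference base, the species whose conserved
regions cover it, masks exon bases first (so a masked fragment must itself
be at least 100 bp — the order of masking and length testing was unstated
upstream, and masking-first is the conservative choice), and reports
maximal runs of at least 100 bp supported by 10+ avian species or 3+
non-avian tetrapods. The two clade tracks are independent and may overlap.
Raising any threshold can only shrink elements (verified as a monotonicity
property).

`tfbs_scan()` scores position weight matrices with the classical
information-weighted matrix-similarity score
(`(current - min)/(max - min)` with per-position weights
`ci = sum_b f ln(4f)`), requiring both a core score over the 5 consecutive
highest-information positions (default cutoff 0.75) and a full-matrix score
(default 0.80), on both strands. `tfbs_gain_loss()` compares hits at
homologous offsets between reference and alternate alleles; swapping the
alleles swaps gained and lost exactly. Cutoffs are configurable per call
because the original profile set was not printed.

## Tandem duplication and copy-specific expression

`normalize_coverage()` scales per-window depth so the genome background
sits at copy number 2, using the median as the reference statistic (robust
to the duplication itself; the normalization constant used upstream was
unstated). `call_duplication()` takes maximal runs of at least 3
consecutive windows with copy number at least 2.5 and bins genotype by the
segment mean: `< 3.5` heterozygous, `>= 3.5` homozygous. All bins are
half-open, so no value lands in two bins; the 2.5/3.5 cutpoints are the
midpoints between the expected 2/3/4 copy-number bands and are
configurable, since the original call was made by inspection plus PCR.

`refine_breakpoints()` replaces window-level boundaries with modal
soft-clip positions when clip clusters near both edges remap to the partner
edge in tandem orientation (the signature of the novel junction), reporting
+/-1 bp uncertainty; tied modes leave the call unrefined with a warning,
and calls without usable evidence keep window-level uncertainty and a
depth-only flag. Insert-size discordance is corroborating evidence only —
depth is the primary caller. `screen_samples()` bins cohort samples by mean
regional copy number with the same half-open bins.

`normalized_expression()` is reads in the gene model over total sample
reads, scaled (per million by default). `classify_copy_specific()` labels a
SNP copy-specific when the pooled white-tissue minor-allele fraction is at
most 0.05 (mono-allelic: only the shared copy is expressed in white tissue)
and the pooled pigmented-tissue fraction is at least 0.20; samples below
depth 10 are ignored and SNPs lacking both tissues at depth are
uninformative. The 0.05/0.20/10 defaults are this package's stated rule —
the source gave no numeric thresholds — and the classification is symmetric
under ref/alt relabeling.

## The synthetic-data generators

The generators define the study conditions the tests and the acceptance
script run under; they are first-class, tested code.

- `sim_f2_cross()` forms F2 individuals from two independent F1 gametes
  simulated by a Markov recombination process with Haldane interval
  probabilities — the same no-interference model the HMM assumes. Observed
  copies add symmetric genotyping errors and missingness. Default study
  scale for QTL experiments: 5 chromosomes x 50 markers x 100 cM, n = 150,
  error rate 0.005, missingness 0.05 — GBS-like noise on a cross of the
  size the mapping populations actually had.
- `sim_phenotypes()` plants QTLs at the nearest marker to the requested cM
  (keeping truth genotypes exact without simulating an extra meiosis),
  builds the latent trait additively with Gaussian residuals, and clamps to
  `[0, 1]` because observed phenotypes are proportions; clamp events are
  reported, and effect sizes in the experiments are chosen (via
  `additive_effect_for_pve()`) so clamping is rare and the linear working
  model stays honest away from the boundaries. Both additive and dominant
  effects are exposed, since the true effect architecture at the mapped
  loci is unknown.
- `sim_population_sites()` draws shared allele frequencies
  `Uniform(0.05, 0.95)` under the null and plants fixed haplotypes
  (case-fixed hom-alt, background never hom-alt); likelihoods are
  GATK-style confident phred vectors with an optional miscall rate.
- `sim_alignment()` plants identity islands for the first `n` species of a
  clade against a uniform background; gaps are species-side deletions only,
  so reference coordinates are preserved exactly (no insertion columns —
  a deliberate simplification; gaps count as mismatches downstream either
  way).
- `sim_coverage()` plants a duplication (default geometry: 37 kb in a 1-Mb
  scaffold, 5-kb tiling windows, 30x depth) with Poisson,
  negative-binomial, or zero-variance window depths, plus soft-clip and
  discordant-pair evidence at the true breakpoints.
- `sim_allele_counts()` makes planted copy-specific SNPs mono-allelic in
  white tissue and balanced in pigmented tissue, binomial at the given
  depths.

A single integer seed is expanded into per-stage streams, so each stage is
independently reproducible; identical seed and spec give byte-identical
output.

What the generators do **not** emulate: read-level errors and mapping
artifacts, linkage disequilibrium and demography beyond the planted
haplotypes, segmental biases in coverage (GC, mappability), alignment
errors in the multi-species blocks, and selection. Passing tests therefore
demonstrate correctness of the algorithms under their stated models, not
robustness to every artifact of real sequencing data.

## Numerical choices

- 1-D likelihood maximizations (`estimate_rf`, `pfst_site`) use Brent
  optimization with tight tolerance and explicit boundary checks, verified
  against brute-force grids (1e-4 mesh) to 1e-3 / 1e-6 respectively.
- Permutation quantiles are type-7; permutation streams are seeded
  explicitly; the same seed gives the identical threshold.
- The error-LOD posterior caps at 1e-300 before the log to avoid -Inf on
  degenerate inputs; LOD scores cap at 999 on perfect fits.
- Interval conventions: VCF positions are 1-based inclusive; BED-style
  intervals (CNEs, coverage windows, duplications) are 0-based half-open.
  A SNP at a CNE's start is inside; at its end coordinate, outside.
- Experiment problem sizes (20 seeds for QTL and duplication recovery, 100
  null replicates x 200 permutations for calibration, 5000 null sites,
  50-kb alignments) were chosen as the smallest scales at which the
  binomial noise on each reported rate is well inside the band being
  checked.

## Known limitations

- The pF_ST statistic is an interpretation of an unpublished formula;
  agreement with the original tool is conceptual, not numerical.
- Marker ordering between scaffolds is greedy, not multipoint-optimal;
  pathological linkage structures can mis-chain scaffolds (an explicit
  order can be supplied instead).
- Error-LOD cleaning has limited power on sparse maps by the nature of the
  posterior (see above).
- At n = 200, the recombination-fraction estimator's sampling error at
  r = 0.35 sits at the Cramér–Rao floor (~0.025 mean absolute error); no
  estimator can beat it, and accuracy claims are made for the pooled error
  across the r grid.
- The haplotype-group clustering automates a partly manual step and may
  split borderline samples differently than curation by eye.
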