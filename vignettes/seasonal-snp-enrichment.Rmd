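---
title: "Methods: seasonal SNP enrichment and the synthetic caller benchmark"
author: "seasnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal SNP enrichment and the synthetic caller benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seasnp` implements two computational layers that together make a
strain-level seasonal SNP analysis of gut metagenomes fully testable without
any real sequencing data: a **variant-caller benchmark** built on mutated
reference genomes and simulated reads, and a **seasonal enrichment analysis**
exercised on a synthetic three-season cohort. This vignette records the
models, the tunable parameters and their defaults, the numerical
conventions, and the design decisions taken where the design was genuinely
open.

## 1. The caller benchmark layer

### Genomes and planted truth

`synthesize_genomes()` draws i.i.d. bases at a requested GC fraction
(default 0.5). Only genome *lengths* matter to every statistic downstream
(depth, density, coverage), so no attempt is made to model real base
composition, repeats or multi-replicon assemblies. The canonical benchmark
set is five prevalent human-gut species totalling 13,589,655 bp
(`benchmark_genome_sizes()`); a `scale` argument produces reduced sets that
preserve all per-base statistics.

`draw_snp_truth()` plants a list of unique substitution sites:

* allocation across genomes is proportional to length with largest-remainder
  rounding, so per-genome SNP density is uniform — consistent with a single
  SNP-coverage denominator over the summed genome sizes;
* the alternate base is uniform over the three non-reference bases;
* the canonical truth size is 10,786 sites over the five genomes
  (≈ 0.0794% of positions), and reduced genome sets use the same density.

Whether such a truth list should be uniform or drawn from real polymorphism
data is an open question; uniform placement was chosen because the
evaluation metrics are position-exchangeable.

`apply_snps()` substitutes the alternate base at every truth site and
errors on any reference mismatch, so an inconsistent truth list cannot
silently corrupt a benchmark.

### Read simulation

`simulate_reads()` generates paired 75 bp reads. Fragments
(`N(300, 30^2)` bp, clamped to the read length; not a sensitive choice —
fragment geometry does not alter per-column pileup statistics at fixed
depth) start uniformly on a genome chosen proportionally to length. Mate 1
reads the fragment start forward; mate 2 is the reverse complement of the
fragment end. The error model is per base: substitutions at rate 0.002,
insertions and deletions at 2×10⁻⁵ each. Indels edit the read *in place*,
shifting the remainder of the read relative to the reference, exactly as a
raw basecall stream would.

The canonical depth↔read-count mapping is

```
n_reads = round(depth × total_genome_size / read_length)
```

so 5x over the full five-genome set is 905,977 reads (conventionally
rounded to one million in benchmark folklore; the formula is authoritative
here because it makes depth semantics exact and reproducible).

**Quality model.** Correctly read bases draw Phred qualities from
`N(37, 2^2)`; miscalled and inserted bases draw from `N(7, 2^2)` (all
clamped to [2, 40]). The low miscall profile encodes the strong empirical
association between Illumina miscalls and very low quality scores, and it
is what makes the benchmark reproduce the zero-false-positive behaviour of
mpileup-based callers: the pileup's default base-quality floor (Q13, the
samtools default) removes ~99.7% of miscalled bases before calling. Both
profiles are parameters of `simulate_reads()`.

### Pileup and calling

Reads carry their true origin in their names, so `build_pileup()` stacks
bases without alignment. Two aligner behaviours are emulated rather than
skipped:

* **base-quality floor** — bases below Q13 never enter the pileup;
* **tail soft-clipping** — a read that suffered an indel carries a shifted
  tail that would otherwise stack as a run of high-quality mismatches.
  A gapped aligner absorbs or clips such tails; `build_pileup()` clips a
  read from the first position where ≥ 4 of the following 8 bases mismatch
  the reference. Windows shorter than 6 bases never trigger, so isolated
  mismatches (true SNPs, surviving miscalls) are unaffected: at a planted
  SNP density of ~10⁻³/bp, four true mismatches inside an 8 bp window have
  probability ~10⁻⁹ per window. `clip_tails = FALSE` restores naive
  stacking.

`call_snps()` emits a substitution call at a column iff

```
depth      >= min_coverage
alt_reads  >= min_reads2
alt_freq   >= min_var_freq          (alt_reads / depth)
mean alt base quality >= min_avg_qual
```

with the candidate alternate being the most frequent non-reference base,
ties broken by the fixed order A < C < G < T (deterministic output).
`min_var_freq` defaults to 0.2, the documented default of the wrapped-style
tool whose command line omits it; `min_avg_qual` applies to
alternate-supporting bases (the wrapped tool's semantics), switchable to
the whole column via `qual_scope`. Two canonical configurations are
provided: `benchmark_config()` (1/1/1/0.2, the permissive benchmark
setting) and the `caller_config()` default (10/2/15/0.2, the real-data
setting). Indels are never called. PCR-duplicate removal is a no-op on
i.i.d. simulated fragments and is therefore not implemented as a pipeline
stage.

### Evaluation metrics

`classify_calls()` compares calls with the truth list per position: correct
alternate at a truth site → *match*; wrong alternate at a truth site →
*mismatch*; call elsewhere → *false positive*; truth site without call →
*false negative*. The three headline metrics are

```
sensitivity  = 100 × match / all_true                      (one decimal)
selectivity  = 100 × (1 − (false_positive + mismatch) / all_true)
snp_coverage = 100 × all_identified / total_genome_size    (three decimals)
```

Note the selectivity denominator is the number of **true** SNPs, not the
number of identified SNPs. This is an unusual convention, kept deliberately
because the published benchmark table only reconciles under it
(e.g. 1 − 52/10,786 = 99.5%); it can exceed standard precision and can in
principle go negative when errors outnumber true sites.

### Benchmark problem sizes

The package's own replicate runs use the 1/10-scale genome set
(1,358,965 bp) with 1,079 truth sites — the same SNP density and the same
depths (10x and 20x) as the full-size benchmark. Depth and density, not
genome size, drive pileup statistics, so the scaled replicate is a faithful
check; the test suite and `scripts/acceptance.R` both use it.

## 2. The synthetic seasonal cohort

The real study design this layer emulates is a 40-sample fecal-metagenome
cohort spanning three seasons (8 samples from a first dry season, 19 from
the following wet season, 13 from the next dry season), analysed at the
level of per-sample SNP calls against reference genomes of 15 prevalent
species. No generative model exists in the source analysis (it works on
real data), so the generator here is this package's own minimal structure
that makes every analysis stage exercisable:

* **Per-sample, per-species SNP counts** are negative binomial with mean
  `genome_size × baseline_density` and variance `overdispersion × mean`
  (defaults: density 10⁻³/bp — the order observed for prevalent gut
  species, e.g. ~2,600 SNPs on a 2.6 Mb genome — and overdispersion 2).
  Wet-season samples of the eight planted species have the mean multiplied
  by `enrichment_factor` (default 1.5).
* **Species presence** is Bernoulli per sample (default 0.95), and species
  absent from a sample contribute *no* row to densities or profiles —
  absence of evidence is not an all-reference genotype.
* **Strain structure**: each species carries a wet-private and a
  dry-private haplotype of `strain_divergence` sites (default 100). A
  sample includes each site of its own season's haplotype with probability
  `haplotype_fidelity` (default 0.85) and each opposite-haplotype site with
  the complementary probability. Haplotype sites get allele frequencies
  from Beta(9, 1) (the mutated allele is the sample's dominant allele);
  background sites drawn from a shared pool get Beta(1, 5) frequencies
  (mostly minor alleles). This is what gives the AF > 0.5 profile matrices
  their two-cluster wet/dry geometry: strain-defining sites survive the
  threshold, background polymorphism largely does not.
* **The child outlier**: one second-dry-season sample draws from the wet
  haplotype (enabled by default), echoing the real cohort's single
  dry-season child sample that clustered among wet samples.
* **Gene layer**: 400 non-overlapping genes per species (6,000 total,
  echoing the scale of the ~6,000 genes the emulated analysis actually
  tested), normal lengths around 600 bp, geometric gaps. Three genes per
  enriched species are planted as *cyclic*: wet-season samples receive
  extra SNPs inside the gene at `gene_enrichment_factor` (default 6) times
  the baseline rate. The factor is deliberately strong so the planted genes
  are identifiable above the species-wide 1.5× enrichment that every gene
  of an enriched species inherits.
* **Reproducibility property**: the gene layer is drawn *after* the
  complete species-level cohort, so changing gene-model configuration never
  perturbs the species-level data of a given seed. The documented default
  cohort is `seed = 1`.

Sequencing depths per (sample, species) are log-normal around 20x; they
feed the depth filter only (the cohort is expressed at the call level — the
read-level path is covered by the benchmark layer).

### What the generator does not emulate

Real metagenomes have compositional abundance structure, shared
non-seasonal strain cores, reference bias, depth-dependent call quality,
and correlated presence/absence across species. None of these are modelled.
Passing recovery tests on this cohort therefore demonstrates that the
analysis code implements its selection and clustering rules correctly under
the stated statistical structure — not that the rules would have the same
power or error rates on real data.

## 3. The seasonal statistics

* `snp_density()` is the exact ratio SNPs / unit size (per bp, no scaling
  constant).
* `prevalence_filter()` keeps species present in ≥ `min_samples` samples of
  at least one season (default 8, per-season scope); `depth_filter()` keeps
  species with mean depth **strictly** above 10x in ≥ 3 samples (both
  boundary conventions are tested).
* `wilcoxon_rank_sum()` is self-implemented: the exact two-sided null is
  computed by a dynamic-programming count of rank subsets when
  n₁ + n₂ ≤ 20 and the data are tie-free; otherwise a normal approximation
  with tie correction and continuity correction is used. It is verified in
  the test suite against full subset enumeration (all n₁ + n₂ ≤ 12), the
  reference implementation, and a Monte-Carlo permutation oracle.
* `cyclic_pattern_select()` applies the cyclic rule per unit: selected iff
  the wet season differs from **each** dry season (both p < `alpha_wd`)
  while the two dry seasons are indistinguishable
  (p ≥ `alpha_dd`, default 0.05). Raw p-values drive selection, mirroring
  the two-tier raw-P convention of the emulated analysis (0.05 at species
  level, 0.01 at gene level); a Benjamini–Hochberg column over the binding
  wet-vs-dry p-value is reported for transparency but never drives
  selection. Units with fewer than two observations in any season group are
  reported with `NA` p-values and never selected.
* `profile_matrix()` uses a **strict** AF > 0.5 threshold (a site with AF
  exactly 0.5 is excluded). The threshold is a parameter: a 0.2 variant
  appears in the emulated study's supplementary material, and users can
  reproduce either choice.
* `manhattan_distances()` + `hierarchical_cluster()` implement the profile
  clustering; on binary rows the Manhattan distance is the Hamming count.
  Average linkage is the default — the linkage was unstated in the emulated
  analysis, and average linkage is a robust default for binary-profile
  distances — with complete and single available. Trees serialize to
  Newick (`ape`), replacing the maximum-likelihood trees of the original
  pipeline with distance trees; the Newick output keeps external ML tools
  usable downstream.
* `season_concordance()` formalizes the "one wet cluster, one dry cluster"
  reading as a k = 2 cut at the top merge: the wet cluster is the cluster
  holding the majority of wet samples (a tie is an error), the dry cluster
  is the other one, and each season's concordance is the percentage of its
  present samples falling in its cluster (two decimals). Whether the
  original two-cluster reading came from a formal cut or visual inspection
  is unstated; the top cut is one defensible formalization.

## 4. Numerical conventions

* Coordinates are 1-based and fully closed everywhere in memory (VCF
  convention); the gene-model file on disk is BED-like 0-based half-open
  and says so in its header.
* Sensitivity/selectivity round to one decimal, SNP coverage to three,
  concordance to two — the precisions of the published tables they mirror.
* Per-season mean SNP counts use `round(total/n)` (round-half-even).
* All generators are seeded and deterministic; FASTA/FASTQ/VCF/Newick and
  cohort directory round trips are lossless (allele frequencies stored at
  four decimals).
* Alt-base ties in the caller and leaf order in dendrograms are broken
  deterministically (base order, `hclust`'s canonical ordering).

## 5. Known limitations

* The caller is a single-alternate substitution caller: no indel calls, no
  genotype likelihoods, no multi-allelic records.
* True-origin placement sidesteps mapping ambiguity entirely; the
  soft-clipping rule emulates only the *local* effect of indel
  misplacement, not reference-scale repeat structure.
* The selectivity convention (true-SNP denominator) is not comparable to
  standard precision; both are easy to compute from `classify_calls()`
  output if needed.
* Cohort recovery rates (e.g. ~7.7/8 planted species recovered on average
  across seeds, with the occasional dry-vs-dry false rejection at
  `alpha_dd = 0.05`) are properties of the synthetic design, not estimates
  of power on real data.
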