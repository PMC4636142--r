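---
title: "Methods: multi-assay phenotyping of Drosophila mutants with broad expression shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-assay phenotyping of Drosophila mutants with broad expression shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flypheno)
```

# Scope

`flypheno` implements the quantitative analyses used to phenotype
Drosophila mutants of dosage-sensitive chromatin regulators -- the kind of
mutation (e.g. in the cohesin loader) that modestly shifts the expression
of *most* active genes at once, reduces body and wing growth, and disturbs
learning, memory, sleep and circadian rhythm. Four analysis surfaces share
a small statistics core, and a simulator family generates every input with
known ground truth:

* **Coverage-based RNA-seq quantification** with histone-anchored absolute
  normalization (`exon_union_coverage`, `strip_contaminants`,
  `histone_norm_factors`, `normalize_coverage`, `active_genes`,
  `per_gene_stats`, `fc_density`, `replicate_correlations`,
  `quantify_expression`).
* **Growth and wing morphometrics** (`cell_density`, `cell_area`,
  `cells_per_wing`, `genotype_ratio`, `count_hairs`, `weight_summary`,
  `timing_curves`, `apoptosis_compare`).
* **Sleep and circadian analysis** of per-minute beam-break data
  (`detect_sleep`, `sleep_metrics`, `activity_index`,
  `chi2_periodogram`, `fft_value`, `classify_rhythmicity`,
  `rhythm_analysis`, `actogram`).
* **Courtship conditioning** (`courtship_index`, `learning_test`,
  `memory_test`).

# Statistical conventions

All group comparisons use the **equal-variance (pooled) Student t test,
two-tailed**. The original analyses of this assay family were
spreadsheet-style t tests; Welch's correction is available behind
`welch = TRUE` but is not the default. Categorical outcomes
(normal/abnormal brain structure, rhythmic/arrhythmic) use **Fisher's
exact test** with the classical two-sided definition (sum of
hypergeometric probabilities no larger than the observed table's).
Multi-genotype behavioral contrasts use **one-way ANOVA with Tukey HSD**.
No multiple-testing correction is applied to per-gene p values: the
expression reports deliberately mirror the raw `p <= 0.05` convention of
the assay family, and readers should treat the DOWN/UP tabs as descriptive
enrichments, not FDR-controlled discovery lists.

Degenerate inputs follow fixed conventions rather than erroring, so batch
pipelines complete on pathological (e.g. all-zero) synthetic fixtures:
zero pooled variance gives p = 1 when means agree and p = 0 otherwise,
with a warning; an all-constant ANOVA returns p = 1 with a warning.

# Histone-anchored RNA-seq quantification

## Why not standard normalization

Standard RNA-seq normalization (total count, median-of-ratios) assumes
most genes do not change. When a regulator shifts the majority of active
genes in the same direction, that assumption fails *by construction*: the
global component of the shift is absorbed into the size factors and the
per-gene estimates are pulled toward zero. Replication-coupled histone
mRNA output is tightly coupled to DNA content rather than to global
transcription, so equalizing **total histone coverage** across samples
preserves global shifts.

The model, per sample $s$ and gene $g$ (coverage in summed nucleotides
over the gene's exon union):

$$f_s = \bar H / H_s, \qquad
  \tilde y_{gs} = (y_{gs} + 1)\, f_s,$$

where $H_s$ is sample $s$'s total raw histone coverage and $\bar H$ the
mean over **all samples of both genotypes**. The +1 offset is added
*before* scaling and guarantees positivity, so every log2 ratio is
finite. Factors are computed from **raw** totals (offset-free), the
literal reading of the procedure this package reimplements; with the
offset included the post-normalization histone totals would still agree
across samples to within `n_histone * max |f_s - f_t|`, an invariant the
test suite asserts both ways.

Stage order is fixed and enforced by `quantify_expression`:
rRNA/small-ncRNA stripping -> anchor factors -> offset normalization ->
active-gene filter -> per-gene statistics. Contaminants must be removed
first because rRNA carry-over is large (about half of a
ribo-depleted library) and sample-dependent.

## Quantification choices

* **Exon-union coverage.** Nucleotide coverage is summed over each gene's
  merged (non-redundant) exons, strand-matched, so each base counts once.
  This is more robust than read counting when read lengths vary.
  Coordinates: GFF3 is converted once, at the reader boundary, to the
  internal 0-based half-open convention; bedGraph is consumed natively.
* **Active genes** average more than 500 nucleotides of normalized
  coverage across *all* samples jointly (strict inequality). A single
  joint filter is used -- rather than per-genotype filters -- because the
  assay family reports one active-gene count; `active_genes` takes the
  threshold as a parameter.
* **Replicate correlations** are Pearson correlations of normalized
  values over all quantified genes (pre-filter), matching how
  reproducibility is conventionally reported for this assay.
* **Replicate exchangeability.** Samples are treated as exchangeable
  columns. If a "replicate" is in fact a resequenced library, the mild
  pseudo-replication is the caller's responsibility to weigh; the module
  does not model it.

## What the coverage simulator emulates

`gen_coverage` draws per-gene baselines from a log-normal
(`meanlog = log(2000)`, `sdlog = 1.3`, roughly the dynamic range of a
wing-disc library quantified in nucleotides), applies a global
fold-change (default 0.8, a modest global down-shift) times per-gene
log-normal jitter (SD 0.1 log2 units) to every non-histone gene in the
mutant, holds histone output constant, adds ~10% CV measurement noise,
scales each of the 4+4 replicate libraries by a random depth multiplier
(Unif(0.6, 1.4)), and makes rRNA half of each library. The anchor set
defaults to 100 histone gene copies: the Drosophila histone locus is a
tandem repeat with on the order of a hundred annotated copies, so the
per-sample anchor *total* has small relative noise -- with only a handful
of simulated copies the anchor itself would carry several percent noise
that real anchor totals do not have.

The simulator does **not** emulate: gene-length/GC biases, positional
coverage profiles, spliced-read ambiguity, or biological covariance
between genes. Passing the recovery tests therefore shows the
*normalization arithmetic* is right under a global shift with unequal
depths; it does not validate alignment or annotation choices upstream.

# Sleep and circadian analysis

## Sleep

Sleep is behavioral quiescence longer than five minutes. With 1-minute
bins this is implemented as a maximal run of **>= 5 consecutive
zero-count minutes** (the field-standard convention; `strict = TRUE`
gives the literal "longer than" reading). A bout that spans the light
transition keeps its identity; its minutes are attributed to day and
night phase-wise, so day + night sleep equals total sleep exactly --
conservation the tests assert. Totals are per 24 h, averaged over
recorded full days. The activity index (counts per waking minute)
separates hypo/hyperactivity from sleep-amount changes.

## Chi-square periodogram

For candidate periods 14-34 h in 0.1 h steps (30-min bins; both
configurable, mirroring common analysis-suite defaults), the data are
folded at each period into $K$ phase columns with means $M_h$ and
occupancies $n_h$:

$$Q_P = \frac{N \sum_h n_h (M_h - \bar M)^2}{\sum_i (x_i - \bar M)^2}
  \;\sim\; \chi^2_{K-1} \text{ under the null.}$$

The $n_h$-weighted form calibrates exactly to the chi-square reference
(the unweighted textbook shorthand assumes equal occupancy, which a
non-integer number of cycles violates). The per-period significance line
is the $\chi^2_{K-1}$ quantile at level $\alpha = 0.01$,
Bonferroni-divided by the number of candidate periods, so the whole
scan has family-wise level $\alpha$; on white-noise Poisson series the
peak crosses the line in well under 5% of simulations. The reported peak
maximizes $Q_P$ minus its line, which removes the monotone-in-$K$ trend
of the raw statistic.

## FFT value and classification

The FFT value is the relative power of rhythmicity: spectral power at
the strongest frequency in the 18-30 h band over total power at positive
frequencies, on mean-subtracted 30-min bins; it lies in [0, 1], is 0 for
a constant series, and rises monotonically with rhythm amplitude.
Classification combines both statistics: **arrhythmic** if the
periodogram peak is non-significant or the FFT value is below 0.01;
**rhythmic** if significant and FFT >= 0.03; **weak** otherwise. The two
FFT cutoffs are surrogates -- the proprietary suite this mirrors does not
publish its internal criterion -- so they are parameters, emitted with
every result, and group summaries (`rhythm_table`) compute FFT and
period averages over rhythmic + weak flies only, as such tables are
conventionally reported. Group rhythmicity contrasts
(`rhythmicity_test`) compare rhythmic-or-weak vs arrhythmic counts by
Fisher's exact test.

## What the activity simulator emulates

`gen_activity` alternates waking bouts (Poisson counts at a
thresholded-sinusoid rate, default 2 counts/min waking mean) and sleep
bouts (explicit zero runs) via a two-state Markov chain whose mean bout
lengths (sleep 40/15 min night/day, wake 12/60 min) interpolate with
amplitude between phase-free and fully phase-locked. Defaults: 16 flies,
14 DD days, 23.5 h period, amplitude 0.9. Bouts are embedded as explicit
zero runs so the 5-minute rule has exact truth. Not emulated: ultradian
structure, startle responses, monitor artifacts (dead channels, beam
noise), or light-driven masking; recovery of the generating period shows
the periodogram is right, not that real flies are this clean.

# Courtship conditioning

The courtship index (CI) is the fraction of a 10-minute observation
window -- truncated at successful copulation -- spent in active courtship.
CI is invariant to interval subdivision, and complement intervals give
1 - CI (both are property-tested). **Learning** is the within-fly
decrement CI_initial - CI_final over a training session with a
non-receptive female, tested as a paired t; genotypes are compared on
their decrements by ANOVA + Tukey. **Short-term memory** is the unpaired
contrast of trained males (CI_test) against separate naive males
(CI_sham); memory is called only when the difference is significant
*and* suppressive -- a significant increase is flagged, not called. CI is
kept on [0, 1] internally; percent belongs to report formatting.
Cohorts below 18 males trigger a warning, the conventional minimum for
this paradigm. `gen_courtship` draws per-male target CIs from truncated
normals per session and places non-overlapping intervals to hit the
target exactly; it does not emulate behavioral microstructure
(bout-pause texture within courting).

# Growth and morphometrics

Each wing epithelial cell bears one trichome, so a hair count over a
sampled region gives cells/mm^2; 10^6 over the density gives the mean
apical cell area (um^2); the density times the mean blade area gives
cells per wing. Internally everything is full precision -- the identity
`cell_area(d) * d == 1e6` holds exactly -- and rounding (areas 2 dp, cell
area 1 dp, cells integer, ratios 2 dp) happens only at report time.

`count_hairs` mirrors semi-automated colony-counter workflows: binarize
at a **percentile** intensity threshold (90th by default --
illumination-invariant, unlike an absolute cutoff), then a 3x3
morphological opening, then 8-connected labeling, dropping components
under 4 px. The opening matters: a percentile threshold marks a fixed
fraction of pixels no matter what, so on a sparse spot field some marked
pixels are always salt noise; opening removes them at negligible risk
(a false spot needs a 3x3 all-noise block) while preserving disks of
radius >= 2. Touching hairs merge into one component and are counted
once -- a documented limitation shared with the workflows this mirrors.

Body weights are measured in batches (default 20 flies/batch);
statistics are over batches, not flies. Developmental timing uses the
**median** day (first day cumulative counts reach half their final
value), robust to the long right tail of eclosion curves. Apoptotic
counts per disc are compared with boxplot summaries plus pairwise t
tests; the count per disc is the input -- image quantification of
stained discs is out of scope.

# Numerical and testing choices

* All simulators are deterministic given their seed and round-trip
  their outputs through the package's readers; truth tables list every
  generated entity exactly once.
* Oracle equivalence: exon-union coverage is checked against a per-base
  brute-force loop, sleep bouts against a run-length scanner, Fisher p
  against hypergeometric enumeration, t/Pearson against textbook
  formulas.
* Problem sizes in the test suite (2000-gene coverage tables, 8-16 fly
  cohorts at 14 days, 200-replicate power simulations) were chosen as
  the smallest sizes at which the recovery and power properties are
  stable, keeping the default suite under about a minute of compute.
* The total-coverage normalization used to demonstrate the anchoring
  rationale lives in the test helpers only; it is a control, not part of
  the package surface.

# Known limitations

* The anchor assumes histone mRNA output per cell is unchanged between
  genotypes; a mutation that alters S-phase fraction or histone
  regulation itself would bias all absolute levels.
* Rhythmicity classification thresholds are surrogates; borderline
  flies ("weak") are sensitive to them, which is why they are emitted
  with every result and why group tables pool rhythmic + weak.
* `count_hairs` undercounts dense fields where trichomes touch.
* The spreadsheet-style per-gene t tests have low power at n = 4 per
  group; the DOWN/UP tabs are descriptive, not FDR-controlled.
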