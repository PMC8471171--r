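---
title: "Integrating promoter methylation with transcriptional activation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating promoter methylation with transcriptional activation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethex)
```

# Background

Promoter CpG methylation is classically read as a silencing mark, yet a
subset of transcription factors binds methylated recognition sequences
preferentially, so that promoter *hyper*methylation can coincide with — and
drive — transcriptional *up*-regulation. promethex implements the desk side
of a study design built around that observation: integrate differential
promoter methylation with differential expression to find
"hypermethylated-and-up" genes; screen a protein microarray with methylated
versus unmethylated DNA fragments for methylation-preferring binders; locate
methylated binding sites in candidate promoters with a methylation-aware PWM
scan; use knockdown transcriptomics plus enrichment statistics to nominate
direct targets; and quantify the standard validation assays.

Because the patient-tissue and array data behind such a study are not
shippable, every stage is driven by a synthetic-data generator that plants
known ground truth. The generator is first-class, tested code: the package's
operating characteristics (sensitivity, false-discovery proportion, binder
recovery, type-I error) are measured on its output.

# Differential testing

## Promoter aggregation

Each gene's promoter window is the strand-oriented interval from 1500 bp
upstream to 500 bp downstream of the TSS, handled as 0-based half-open
coordinates (length exactly 2000 bp; a probe at the downstream boundary is
excluded). Per gene and sample, promoter methylation is the arithmetic mean
of the beta values of in-window CpG probes. Genes without any in-window
probe are dropped and reported in a `dropped` attribute rather than
failing the run — a QC report, not an error, because sparse annotations are
routine.

## The moderated t

Both layers use an empirical-Bayes moderated two-sample t. For feature $g$
with pooled within-group variance $s_g^2$ on $d = n_1 + n_2 - 2$ df, the
posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},
\qquad
\tilde t_g = \frac{\bar x_{g,\mathrm{case}} - \bar x_{g,\mathrm{ctrl}}}
{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with two-sided p-values on $d_0 + d$ df. The prior $(d_0, s_0^2)$ is fitted
by moment-matching the mean and variance of $\log s_g^2$ against their
digamma/trigamma expectations under a scaled-F sampling model; the trigamma
inversion is a Newton iteration. When the observed variances are *less*
dispersed than pure sampling noise the inversion has no solution and the
prior weight falls back to $d_0 = 0$, i.e. the ordinary pooled-variance t;
if every feature has zero variance the same fallback applies with a warning,
and zero-variance zero-effect features get $t = 0$, $p = 1$. Tests are
two-sided and pooled-variance throughout (no Welch correction), matching the
moderated-t model; the unit tests verify agreement with the limma
implementation to near machine precision on shared instances.

Significance combines an effect-size and an FDR condition:
methylation requires BH-adjusted $p \le 0.05$ and $|\Delta\beta| \ge 0.1$;
expression requires BH-adjusted $p \le 0.01$ and $|\log_2\mathrm{FC}| \ge 0.5$.
Both pairs are exposed as parameters (`p_cut`, `effect_cut`) with these
defaults.

A deliberate choice: methylation is tested on promoter-mean **beta values**,
not M-values, so the reported effect is directly the delta-beta that the
$\ge 0.1$ rule speaks about. Beta-scale tests are slightly conservative at
extreme methylation levels; at the intermediate levels the generator
produces (0.2–0.8), the difference is immaterial and the interpretability
gain is large. The exact regional test used by array-processing suites on
real 450k data is not re-implemented here; this package's choice is its own
and is documented as such.

# Quadrant integration and knockdown intersection

Genes present in both differential tables (inner join — only genes with both
measurements are classifiable) are assigned to `hyper_up`, `hyper_down`,
`hypo_up` or `hypo_down` exactly when both significance flags hold, by the
sign pattern of $(\Delta\beta, \log_2\mathrm{FC})$. A gene whose
delta-beta is exactly 0 yet flagged significant (possible only under
user-supplied thresholds) has no defined sign and is left unclassified.
Quadrant counts plus their total are reported alongside the per-gene
records; classification is a pure function of the two tables.

The knockdown arm intersects, across cell-line panels, the sets of genes
significantly down-regulated (negative log2FC) after knockdown; candidate
direct targets are the consistently-down genes whose promoters are also
significantly hypermethylated — the signature of genes activated through a
methylation-preferring factor.

# TF microarray screen

Replicate spots are collapsed by the median per channel (robust; replicate
handling is otherwise unspecified in this assay class). Positivity
thresholds are computed per channel from negative-control spots as
**mean + 4 sample SD**. The methylation-preference ratio divides the two
binding channels *after flooring each at its own threshold*: a
sub-background denominator would otherwise blow the ratio up, and flooring
keeps ratios finite and conservative. Classes:

* `not_expressed` — both terminal-tag stains below `expression_floor` ×
  their thresholds (default floor 1);
* `non_binder` — expressed, neither binding channel positive;
* `methyl_preferring` — methylated channel positive and ratio ≥
  `ratio_cutoff` (default 2; the assay literature reports rankings rather
  than a cutoff, so the value is an explicit parameter);
* `unmethyl_preferring` — the mirror image;
* `non_discriminating` — positive but below the cutoff either way.

Methyl-preferring candidates are ranked by descending ratio, ties by
descending methylated-channel MFI, then lexicographic id; the top 15 are
reported by default. The classification is invariant to spot order and to a
common rescaling of all channels and controls, and swapping the two binding
channels maps the two preferring classes onto each other exactly — both are
tested properties. Full-length expression QC requires *both* tag stains
above threshold (a missing C-terminal tag indicates truncation).

# Methylation-aware motif scanning

Sequences are encoded over the extended alphabet $\{A, C, G, T, M\}$, with
$M$ = 5-methylcytosine in CpG context. Methylation is recorded at the
cytosine; CpG methylation is treated as strand-symmetric, so the minus
strand encoding carries $M$ at the partner cytosine. Masks may name either
base of the CpG and are normalised to the C position; a masked position
outside CpG context is an error (hemimethylation is not modelled).

Windows on both strands are scored as $\sum_j \log_2 (p_j(x_j) / b(x_j))$
(PWM emission over background). P-values are exact tail probabilities of
the window score under the background model, computed by the standard
dynamic-programming construction: per-position scores are integerized at a
granularity of $10^{-3}$ bits and their distributions convolved across
positions. The scanner scores windows with the *same* integerized scores, so
reported scores and p-values are mutually consistent, and the DP tail equals
brute-force enumeration exactly on small motifs (verified at width 3 over
all $5^3$ words). The reported score differs from the un-integerized one by
at most width × granularity ÷ 2. Hits at $p \le 10^{-4}$ (the conventional
scanning default) are reported sorted by p, with BH q-values over all tested
windows. PWMs missing an M column get the C emission copied into M,
making the motif methylation-indifferent; a uniform extended-alphabet
background is the default and is user-replaceable.

# Enrichment statistics

Overrepresentation uses the one-sided Fisher exact test — the
hypergeometric upper tail of the 2×2 study/set table — BH-adjusted across
sets (significance at adjusted $p \le 0.05$).

GSEA uses the weighted Kolmogorov–Smirnov running sum: descending-score
ranking, hit increments proportional to $|s|^{w}$ (default $w = 1$)
normalised over the set, miss decrements $1/(N - N_h)$, ES = the running-sum
value of largest magnitude. On a near-tie between a positive and a negative
extremum (within $10^{-12}$) the earliest position wins, which keeps the
sign deterministic. The null is **gene-label permutation** (random sets of
the same size), not phenotype permutation: at desk scale with few samples,
label permutation is valid, fast, and exactly reproducible for a fixed seed;
this is a documented divergence from the phenotype-permuting default of the
original implementation. NES divides ES by the mean |null ES| of the same
sign, p carries a +1 correction (never 0, bounded below by
$1/(n_\mathrm{perm}+1)$), and FDR q is computed within the positive and
negative NES pools from the pooled null distribution. A set is significant
at NES > 1, $p \le 0.05$, $q \le 0.25$. The ranking metric for knockdown
panels is the moderated t from the differential module (the source study
does not state its metric; this is the package's choice).

# Validation assays

* **Bisulfite clones** — per-CpG and overall methylation are call means × 100.
  The conversion rate per clone is the percentage of non-CpG cytosines read
  as converted; clones below 95% (configurable) are flagged, with exclusion
  off by default since the assay convention is to report rather than drop.
* **ΔΔCt** — replicate Cts are combined by the arithmetic mean (median
  available by option), $\Delta C_t = C_t^\mathrm{target} -
  C_t^\mathrm{housekeeping}$ per condition, $\Delta\Delta C_t$ against the
  reference condition, fold $= 2^{-\Delta\Delta C_t}$. The fold is invariant
  to a global Ct shift and to shifting one gene's Cts equally in both
  conditions — both tested.
* **ChIP percent input** — the input Ct is adjusted for the chromatin
  fraction used, $C_t^\mathrm{adj} = C_t^\mathrm{input} - \log_2(1/f)$, and
  enrichment is $100 \times 2^{C_t^\mathrm{adj} - C_t^\mathrm{IP}}$; with
  $f = 1$ this reduces to $100 \times 2^{C_t^\mathrm{input} -
  C_t^\mathrm{IP}}$.
* **Dual luciferase** — per-well activity is firefly/renilla; the reported
  fold is mean promoter-construct activity over mean empty-control activity
  within each condition.

# The synthetic-data generator

The generator emulates the *structure* of the study's data, not its biology:

* **Methylome/transcriptome** — two groups, default 20 samples each (a
  typical tissue-cohort scale for this design), 200 genes with 5 promoter
  CpGs each; planted effects of $|\Delta\beta| = 0.3$ and
  $|\log_2\mathrm{FC}| = 1.5$ in configurable quadrant fractions (default
  10% hyper-up, 5% in each remaining quadrant). Beta noise is applied on
  the logit scale and back-transformed with clamping to
  $[10^{-4}, 1-10^{-4}]$, keeping values in the open unit interval with the
  mean-dependent variance real arrays show; logit-scale SD 0.5 and log2
  expression SD 0.5 are moderate-noise settings at which the planted
  effects are clearly but not trivially recoverable. Control-group promoter
  means are drawn uniformly with headroom for the planted shift
  (hypermethylated genes start at 0.2–0.5, hypomethylated at 0.5–0.8).
  One TSS per gene and all probes in-window: per-promoter aggregation is
  what is under test, multi-TSS handling would add nothing testable.
* **TF arrays** — normal background at MFI 100 (SD 10), tag stains at 3000
  for expressed spots, planted binders with methylated signal =
  `preference_fold` × an unmethylated base of 400–800, ~15% of the
  remaining TFs binding both fragments equally, multiplicative noise with
  CV 0.1–0.15, two replicate spots per TF.
* **Knockdown panels** — five samples per condition per line and log2 noise
  SD 0.25, cell-line-experiment scale; the consistent set is down-shifted
  in every line, private sets in one line each.
* **Validation data** — clone calls are Bernoulli draws from declared
  per-CpG fractions; Ct values are $\mathrm{base} - \log_2(\mathrm{abundance})
  + \mathrm{noise}$, so declared folds, percent-input values and activity
  ratios are recovered by the corresponding quantifiers.

Seeds are mandatory arguments; no generator touches global RNG state it did
not set, and identical configurations are byte-identical.

What the generator does **not** emulate: Illumina probe chemistry and probe
bias, batch and position effects, copy-number confounding, correlated
probes beyond the shared promoter mean, heavy-tailed expression noise, or
array spatial artefacts. Green tests therefore demonstrate correctness of
the statistics and plumbing under clean, planted-truth conditions — they do
not certify performance on real arrays.

# Numerical choices and degenerate inputs

* Beta clamping bounds ($10^{-4}$) keep logits finite; PWM pseudocount
  ($10^{-4}$) keeps log-odds finite; both are parameters.
* Score integerization granularity $10^{-3}$ bits bounds the p-value
  discretization error; enumeration tests pin the DP exactly at small width.
* Ratio flooring at channel thresholds (TF screen) bounds preference ratios
  by construction.
* BH adjustment delegates to the stock step-up implementation and is tested
  against a brute-force transcription of the formula.
* Degenerate inputs: all-zero variance falls back to the ordinary t with a
  warning; an empty differential join warns and returns zero rows; a motif
  wider than the sequence warns and returns zero hits; fractions outside
  $[0,1]$, missing housekeeping genes, missing negative controls and
  malformed matrices are errors.

# Pipeline and reproducibility

`run_pipeline()` orchestrates the stages (`simulate`, `diff`, `integrate`,
`screen`, `scan`, `enrich`, `validate`, `all`) over a validated config
(YAML or list; unknown keys are rejected; defaults reproduce the thresholds
above). Each stage writes its outputs under its own subdirectory plus a JSON
manifest with the package version, seed, parameters and input checksums; no
stage mutates its inputs, and runs are deterministic given the seed. A thin
Rscript wrapper ships in `inst/cli/`.

The test suite and the acceptance script use problem sizes of 30–200 genes,
4–20 samples per group, 40–100 TF spots, 1000 GSEA permutations and 20
replicate seeds for the recovery metrics — sizes at which every check runs
in seconds on one CPU while the planted effects remain statistically
comfortable.

# Known limitations

* Beta-scale testing, gene-label GSEA permutation and median replicate
  collapse are documented choices, not re-implementations of any specific
  upstream suite; results on real data will differ in detail.
* The motif scanner models symmetric CpG methylation only; hemimethylation
  and non-CpG methylation are out of scope.
* The TF screen assumes GenePix-level feature extraction upstream; no
  background subtraction or spatial correction is applied.
* Patient-tissue headline counts from the motivating study depend on
  cohort data not packaged here and are not reproduced; the package instead
  reports its operating characteristics on planted truth.
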