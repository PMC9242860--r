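---
title: "Methods: scoring pooled dropout screens and regulatory-element analyses"
author: "regscreen developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring pooled dropout screens and regulatory-element analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscreen)
```

# Scope

`regscreen` implements the statistical core of a functional-genomics workflow
built around pooled CRISPR/CRISPRi dropout screens in cancer models: scoring
gene- and enhancer-region-level depletion, permutation-based empirical
inference, linking regulatory peaks to genes by TSS proximity, motif-level
analyses of transcription-factor pairs and regulatory variants, and
allele-specific quantification. Primary sequencing analysis (alignment, peak
calling, differential-expression fitting) is out of scope: the package
consumes count tables, BED intervals, PWMs and DE result tables, and emits
TSV/BED/JSON.

# Screen scoring model

## Fold changes and control centring

Counts $c_{ij}$ (construct $i$, sample $j$) are library-size normalized with a
pseudocount $pc$ (default 0.5):

$$a_{ij} = 10^6 \cdot \frac{c_{ij} + pc}{\sum_k (c_{kj} + pc)}$$

Each endpoint sample $j$ has a designated reference $r(j)$ (the plasmid pool
or assay-start sample), giving per-construct fold changes
$\mathrm{FC}_{ij} = a_{ij} / a_{i,r(j)}$ and $\log_2$ fold changes. Because
pooled screens have no internal scale, fold changes are centred per endpoint
sample on the non-targeting controls: the centre (median by default; mean
available) of control $\log_2$ fold changes is subtracted from every
construct. The median is the default because a handful of outlying control
constructs — e.g. a control lost to an engraftment bottleneck — should not
shift the baseline.

## Gene sensitivity score

Per gene and replicate, the $k$ most depleted constructs (default $k = 3$)
are selected and the replicate score is the $\log_2$ of the mean of their
centred *linear* fold changes; the gene score is the mean over replicates.
The phrase "log2 of the mean of the top $k$ depleted guides" is ambiguous
between $\log_2(\overline{\mathrm{FC}})$ and $\overline{\log_2 \mathrm{FC}}$;
the default `fc_space = "linear_then_log"` takes the literal reading, and
`"mean_of_logs"` gives the other convention. When all selected guides agree
the two coincide exactly. Genes with fewer than $k$ constructs use all of
them, recorded in `n_constructs_used`. Ties in "most depleted" are broken by
construct id so results are deterministic.

## Region depletion score

In vivo enhancer screens read out tumours (units) grouped by transplantation
site (e.g. left/right flank). Constructs' centred $\log_2$ fold changes are
first averaged across each group's tumours — averaging before ranking keeps a
single bottleneck-distorted tumour from dominating the selection — then per
region the $m$ (default 2) lowest construct averages are averaged into the
group score, and group scores are averaged into the combined score. This
statistic is defined directly in $\log_2$ space (a mean of $\log_2$ values);
the `fc_space` switch deliberately does not apply here. Whether one should
average per tumour instead of per group first is not determined by the
design; the per-group default is fixed and the same machinery treats
technical replicates as groups.

# Permutation inference

## Region tests

Empirical p-values for region depletion come from reassigning
region-targeting constructs to region labels uniformly at random, preserving
each region's construct count, and recomputing every region's statistic per
permutation. This is the minimal exchangeable null: it holds the observed
fold-change distribution fixed and breaks only the grouping into regions.
Count shuffling or resampling would additionally perturb the noise structure
the screen actually has. All empirical p-values carry the add-one
(permutation-inclusive) correction

$$p = \frac{1 + \#\{S_{null} \le S_{obs}\}}{1 + N},$$

so $p = 0$ is impossible and the floor is $1/(N+1)$ — with $N = 1000$
permutations the strongest reportable result is $p < 0.001$. A
Benjamini–Hochberg q-value column is appended for convenience; thresholds
like "empirical $p < 0.01$" apply to the unadjusted p.

Note a consequence of counting ties (`null <= observed`): even a region whose
constructs are all extreme cannot be *guaranteed* the floor p, because a
permutation that happens to reassign enough of those constructs back to the
same label reproduces the observed statistic exactly.

## TSS-window enrichment

The observed statistic is the number of peaks intersecting the
$\pm w$ window (default $w$ = 500 kb, inclusive of the TSS base) around at
least one gene of a designated set, each peak counted once. The null redraws
equally sized gene sets uniformly from the TSS table, leaving peaks where
they are. Resampling genes rather than shuffling peaks avoids needing a
mappability/blacklist model for peak placement; a peak-shuffling null is
explicitly out of scope.

## Interval-set overlap

`interval_overlap_fisher()` tabulates universe intervals by membership in two
sets (by coordinate identity, or by $\ge$1 bp intersection) and reports the
sample odds ratio $ad/bc$, a Woolf logit 95% CI, and the one-sided Fisher
exact p. Zero cells get the Haldane–Anscombe 0.5 correction for the OR and CI
only (flagged in the output); the exact p needs no correction.

# Motif analyses

Scores are additive log2-odds in bits, $\sum_j \log_2(p_{j,b_j}/bg_{b_j})$,
computed on both strands (minus-strand windows are scored against the
reverse-complemented matrix). Windows containing N are skipped. The default
hit threshold is 80% of the PWM's maximal achievable score because no
absolute threshold is universal across motifs of different lengths and
information content; an absolute bits threshold is accepted wherever the
fraction is.

PWMs built from count matrices receive a fractional pseudocount: at a
position with total count $N$, each cell gains $w \cdot N \cdot 4 \cdot bg_b$
(default $w = 0.01$), keeping all probabilities positive while barely moving
well-supported positions.

`allele_delta_score()` rescopes one position of a hit:
$\Delta = \log_2(p_{j,ref}/bg) - \log_2(p_{j,alt}/bg)$, positive when the
reference base is the better match. For minus-strand hits the genomic bases
are complemented and the motif column mirrored, so callers always pass
plus-strand alleles. The statistic is antisymmetric by construction.

`pair_geometry()` classifies two-motif configurations motif-centrically —
tandem (same strand; `tandem_AB` when A precedes B in reading order),
`convergent` (facing each other), `divergent` (facing away) — with
edge-to-edge spacing (negative = overlap). Because no biologically "correct"
co-operative-binding distance is fixed a priori, the summary reports the full
(orientation, spacing) histogram, flags recurrent configurations above a
count threshold, and annotates a configurable close-spacing band (default
$\le$ 10 bp) instead of hard-coding a cutoff.

# Allelic quantification

Allele-specific assays (ChIP-qPCR vs input; RT-qPCR vs gDNA) are normalized
in odds form:

$$r = \frac{f_s/(1-f_s)}{f_r/(1-f_r)},$$

where $f$ is the allele-1 fraction. The odds form is the default because it
is exactly symmetric under allele relabelling ($r \to 1/r$) and invariant to
rescaling either measurement; plain fraction division is available for
comparison with simpler pipelines. Knockdown shifts are summarized as
per-allele fold changes (mean treated / mean control) and their ratio, the
allele-selectivity index. Replicates are summarized by mean with standard
errors; hypothesis testing is left to standard tools.

# Time-course target filter

"Early and sustained downregulation" is operationalized as
$\log_2\mathrm{FC} < 0$ and adjusted $p \le 0.05$ at **both** required
timepoints (default 32 h and 72 h). The thresholds are configuration, not
constants, because the source analyses do not print them in the main text;
the filter is monotone in both thresholds, which the tests assert.

# Synthetic data: what it emulates, and what a green test does not show

`simulate_screen()` generates the structure the scoring stack assumes:

* plasmid-pool abundance skew — log-normal, $\sigma = 1$ on the log2 scale,
  a typical spread for pooled lentiviral libraries;
* per-construct efficacy — Beta(5, 1): most constructs work, a tail does not;
* per-target fitness effects — 0 for neutral targets, a configurable negative
  value per doubling for true hits (acceptance runs use $-0.3$ over 10
  doublings), and $-0.5$/doubling for essential-gene controls, a strong
  ~32-fold dropout;
* engraftment bottleneck — one multinomial founder draw per tumour (default
  $10^5$ founders), the minimal mechanism that reproduces the inter-tumour
  variance motivating the top-$m$ statistic;
* sequencing noise — negative binomial with size 10 around expected
  proportions at the configured depth (default $10^6$).

Every generator is a pure function of (config, seed); the caller's RNG state
is untouched.

The generators deliberately do **not** model chromatin context, locus copy
number, guide off-targets, GC-dependent sequencing bias or realistic genomic
sequence composition. A green calibration or power test therefore
establishes that the estimators are correct and well calibrated *under the
stated noise model*, not that any particular biological screen meets these
assumptions.

One consequence measured during development: with negative-binomial size 10
and a 10-construct control set, the per-sample control centre carries
sampling error of roughly 0.1 log2 units, so the mean centred fold change of
neutral constructs in any single simulated screen fluctuates at that scale.
Unbiasedness holds in expectation (asserted over 24 seeds); per-screen
deviations of ~0.1 are a property of median-of-few-controls centring, not an
estimator defect.

# Numerical and interface choices

* Intervals use `GenomicRanges` internally (1-based closed, the Bioconductor
  convention); all text I/O is BED 0-based half-open via `rtracklayer`, and
  round-trips are coordinate-exact. Constructors taking raw coordinates
  (`intervals_bed0()`) use the BED convention.
* Empirical p-values are never 0 and never exceed 1; seeded runs are exactly
  reproducible, and changing only the seed changes null draws, never observed
  statistics.
* Tie-breaks in top-$k$ selection use construct id order.
* Degenerate inputs fail loudly: all-zero samples with zero pseudocount,
  endpoint samples without references, single-region permutation tests,
  empty peak set A in co-binding fractions, references with allele fraction
  0 or 1.
* The CLI (`run_cli()`, launcher in `inst/cli/regscreen.R`) merges a YAML
  config under explicit flags (flags win), writes the resolved configuration
  next to every output, and uses exit codes 0/1/2 for success, validation
  failure and usage errors.

# Known limitations

* The region permutation null assumes constructs are exchangeable across
  regions; strong region-specific construct biases (e.g. copy-number
  differences at target loci) would violate it.
* The TSS-enrichment null resamples genes, not peak positions; it answers
  "are peaks closer to *these* genes than to random genes", not "are there
  more peaks here than expected from genome-wide placement".
* No multiple-screen batch modelling; each screen is scored independently.
* The background-FPR calibration of motif scanning assumes i.i.d. background
  composition.
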