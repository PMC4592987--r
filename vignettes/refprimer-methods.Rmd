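---
title: "Methods: stability scoring, consensus ranking and primer design in refprimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability scoring, consensus ranking and primer design in refprimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refprimer)
```

# Overview

`refprimer` addresses two recurring needs in qPCR experiment design for
organisms with rich expression resources (the motivating case is the
filamentous fungus *Neurospora crassa*, whose circadian biology makes most
classical "housekeeping" genes unreliable as references):

1. **Reference-gene selection.** Given expression time courses (log10 FPKM),
   find genes whose expression is flat in time and low in variance, across a
   range of absolute expression levels, and robust across several
   experimental conditions.
2. **Primer cataloguing.** Given a genome and its annotation, design five
   ranked RT-PCR primer pairs per transcript under intron-aware placement
   rules, so any gene can be assayed without ad hoc primer design.

This vignette records the statistical model behind each stage, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and what the seeded simulators do and do not emulate.

# Reference-gene selection

## The ENCAS filter chain

A gene enters the stability ranking only if it is **E**xpressing,
**N**on**C**ircadian, and **A**NOVA **S**elected:

* *Expression*: mean log10 FPKM across all samples must exceed a cutoff,
  default **−2** (strict `>`). The cutoff statistic is the dataset-level
  mean; a per-sample variant was considered and rejected because a single
  dropout sample should not disqualify an otherwise well-expressed gene.
* *Rhythmicity*: genes confidently called rhythmic are removed, at
  Benjamini–Hochberg **q < 0.05** (strict). Calls can be imported from a
  prior screen (`read_rhythm_calls()`) — the workflow used on the original
  data — or recomputed with the package's own permutation JTK test
  (`jtk_screen()`), so the pipeline is self-contained.
* *Time-effect ANOVA*: a per-gene one-way fixed-effects ANOVA with time
  point as the factor; genes with **P < 0.05** are removed. Deliberately
  **no** multiple-testing adjustment is applied across genes: the screen is
  built to err toward rejection, and adjusting would trade type II for
  type I errors in the wrong direction for a screen.

For induction-style series without replicates, the rhythmicity and ANOVA
stages are skipped (within-time-point variance is undefined) and recorded as
skipped in the report attributes and provenance.

## The prediction-interval ranking score (PIRS)

For each gene, ordinary least squares of log10 FPKM on time over all
replicate observations gives fitted values $\hat y_i$ at each distinct time
point $t_i$ and a residual standard deviation $s$. The 95% prediction
interval for a new observation at $t_i$ is

$$\hat y_i \pm t_{0.975,\,n-2}\; s \sqrt{1 + \tfrac1n +
\frac{(t_i - \bar t)^2}{S_{tt}}}.$$

With $m$ the gene's overall mean expression and $(L_i, U_i)$ the interval
bounds, the score is

$$\mathrm{PIRS} = \sum_i \big(|U_i - m| + |L_i - m|\big),$$

summed over distinct time points. A gene that is flat (slope ≈ 0, so the
bounds hug the mean) and quiet (small $s$, so the bounds are tight) scores
near zero; lower is more stable. PIRS is exactly invariant under adding a
constant to a gene (both bounds and the mean shift together) and strictly
increasing in the residual noise scale — both properties are tested.

Three readings of the verbal definition were open:

* *Prediction vs confidence interval.* The score is named after prediction
  intervals, and that is the default object; the confidence-interval
  variant is available via `fit_regression_pi(interval = "confidence")`.
* *Both-bounds-vs-mean or interval width.* The default sums both bounds'
  deviations from the mean, which the definition enumerates; the width
  reading $\sum_i |U_i - L_i|$ is available via
  `pirs_score(formula = "width")`. The two differ only when the fitted line
  drifts away from the mean (trending genes), where the deviation reading
  penalizes drift more — appropriate for a flatness score.
* *Evaluation points.* Intervals are evaluated at each distinct time point,
  not at each replicate sample, so replication density does not inflate the
  score.

Courses can be scored separately (the default: each dataset contributes its
own PIRS to the consensus) or pooled; pooling conflates course-to-course
level shifts with instability, so separate fits are the default.

## Complementary SD/RSD ranking

As an independent check, `sd_rsd()` ranks genes by the standard deviation
of their log values, flagging genes whose SD is at most **0.5%** of the
absolute mean log10 FPKM, and `cross_course_candidates()` intersects the
flags from a replicate-averaged course with those from at least one
individual course. `jaccard_topk()` quantifies agreement between rankings;
on planted data the PIRS-vs-SD agreement is far above the agreement between
a ranking and its own random shuffle, which is the testable core of the
observation that the two rankings correspond well.

## Quintile reporting and consensus

Reference genes should exist at every expression level, so
`quintile_report()` splits genes into five equal-frequency bins of mean
expression and reports the `per_quintile = 2` lowest-PIRS genes per bin
(ties broken by gene ID for determinism). Relative-scale datasets
(normalized to the first time point) have no absolute expression, so
quintiles are refused and the workflow reports the top-n overall instead.

Across datasets, `consensus_ranking()`:

1. restricts to genes scored (ENCAS) in **every** dataset — dominance is
   undefined on missing coordinates, so genes filtered in any dataset are
   excluded and reported separately;
2. computes the **pareto front** under minimization: a gene is nondominated
   iff no other gene scores ≤ in every dataset and < in at least one (weak
   dominance, matching the usual reading of "superior under every metric");
3. min–max normalizes each dataset's scores to [0, 1] and sums them (an
   equal-weight scalarization; a z-score variant exists for sensitivity
   checks); and
4. intersects the pareto front with the top `top_n = 10` summed scores.

The front is invariant under any strictly monotone per-dataset transform
(tested with cubing), which is why the choice of normalization affects the
summed ranking but never the front.

# The rhythmicity test

The test compares a gene's series against cosine reference waveforms
$\cos\!\big(2\pi (t - \phi)/P\big)$ for each candidate period $P$ (default
22 h, the *Neurospora* circadian regime; the original screen's scanned
range is not recorded, so the period set is exposed as configuration) and
each phase $\phi$ on the sampling grid. Replicates at a time point share
the reference value, giving tied reference ranks — the standard
replicate-aware treatment. The statistic per reference is $|S|$, the
Kendall concordance sum; its null distribution under permutation of the
observed values is enumerated exactly for $n \le 8$ (40 320 arrangements;
the next factorial is 9! = 362 880 per tie pattern, past the point of
diminishing returns for a test routinely run on thousands of genes) and
estimated by 10 000 seeded Monte-Carlo permutations otherwise.

Scanning many phases inflates the maximum $|S|$ under the null, so a
within-gene correction is required. Two are provided:

* `correction = "maxstat"` (default): the permutation distribution of
  $\max_j |S_j|$ across all references. Because the correction is built
  from the same permutation null as the statistic, the test is calibrated
  by construction; on 1 000 simulated null genes the empirical type-I error
  at α = 0.05 is within binomial bounds of 0.05 (this is asserted in the
  acceptance suite).
* `correction = "bonferroni"`: the smallest per-reference tail probability
  times the number of references. Phased cosines are strongly correlated,
  so this is conservative — measured at ≈ 0.033 empirical type-I at
  nominal 0.05 on the same design. It is kept because it is the correction
  conventionally described with JTK-style tests.

Screening a matrix (`jtk_screen()`) caches the permutation null per tie
pattern of the observed values; for continuous data every gene shares one
pattern, so screening 1 000 genes costs little more than one test.
BH adjustment across genes then yields q-values; `q < alpha` (strict) flags
rhythmic genes.

# Primer catalog

## Region rules

`select_region()` implements three placement modes on the spliced
transcript (all coordinates 0-based half-open internally; GFF3 I/O converts
from/to 1-based inclusive):

* **Mono-exonic genes** — primers fall in the 3′ tail window
  `[len − 500, len − 100)`. The narrower of the two plausible readings of
  the window ("between 500 and 100 bp from the end" vs "the last 500 bp")
  was adopted because it is the more precise statement; genes shorter than
  the window use the whole sequence minus the 100 bp margin and are flagged
  `short_gene` rather than dropped — consistent with a genome-wide design
  success rate approaching 100%.
* **One intron** — the amplicon must span the single exon–exon junction.
* **Two or more introns** — the amplicon must span the **last** junction;
  earlier introns are ignored.

Spanning is implemented as a mandatory internal target: the left primer
starts strictly before the junction and the right primer ends strictly
after it, so genomic DNA yields a larger (or no) product and signal can be
attributed to spliced mRNA. The search region in span modes is the
junction ± 250 bp (one maximal amplicon each side); a flank shorter than
25 bp (a minimal primer plus margin) raises a structured
degenerate-region error that `build_catalog()` records as that gene's
design failure — failures are data, not exceptions.

## The built-in search engine

No Primer3 binding is assumed: the package ships a deterministic
thermodynamic engine. Melting temperatures come from nearest-neighbor
duplex thermodynamics (unified oligonucleotide parameter set), with the
entropic salt correction $0.368\,(N{-}1)\ln[\mathrm{Na}^+]$ at 50 mM
monovalent cation and two-state kinetics at $C_T/4 = 12.5$ nM. The
implementation is verified against an independent nearest-neighbor
implementation to within 0.5 °C on fixed 18–24-mers.

Single-primer penalty is a weighted deviation from the optimum,

$$w_{tm}\,|T_m - 60| + w_{size}\,|\ell - 20| + w_{gc}\,|GC - 0.5|,$$

with all weights 1 by default; a pair adds both primer penalties plus
$|T_{m,L} - T_{m,R}|$. Hard constraints: primer length 18–27 nt, amplicon
100–250 bp on the spliced transcript, pair $T_m$ difference ≤ 3 °C, GC in
[0.2, 0.8], and rejection of any primer containing two mutually
reverse-complementary 8-mers (a self-dimer/hairpin-stem proxy; the
region-wide k-mer screen is proven equivalent to a per-window
longest-common-substring computation in the tests). The $T_m$ acceptance
window is 60 ± 6 °C: on this engine's temperature scale a 50% GC 20-mer
sits near 54 °C, so a tighter window would exclude well-formed primers of
ordinary composition while the penalty still pulls selections toward 60.

Candidate windows are scored vectorially via cumulative dinucleotide sums;
the pair search examines the best K candidates per side and escalates K
until the best five pairs are provably optimal (every unexamined pair
contains a candidate whose penalty already exceeds the bound) or the pools
are exhausted. Pairs are "non-identical" when their
`(left_start, right_start)` tuples differ — the checkable reading of the
uniqueness requirement. Ranks 1–5 follow ascending pair penalty with
coordinate tie-breaks, so catalogs are byte-identical across runs.

The `primer3_engine()` binding exists for systems with `primer3_core` on
the PATH and errors informatively otherwise; the built-in engine is the
default everywhere, including all tests.

# Ct-table analysis

Relative expression across three biological replicates is filtered by the
three-fold rule: a single replicate differing by more than three-fold from
**both** others (ratio > 3 or < 1/3, on the linear scale) is dropped;
otherwise all three are kept. At most one value is ever removed, and when
two or more values each differ three-fold from both others the situation is
ambiguous and everything is retained — the "exactly one" reading is the
only one under which the rule is well defined. A helper converts Ct to
relative level as $2^{-\Delta C_t}$ for this purpose.

Per gene, the mean Ct is taken over all readable wells, the SD is reported
only with ≥ 3 readable wells, and a gene counts as *detected* when any
readable well is strictly below 30 cycles (the threshold is a parameter;
28 is a useful stricter stratum for medium-to-high expressors).
"Unreadable" is an explicit missing flag, never a sentinel cycle number —
instrument conventions for non-amplification vary too much for a numeric
stand-in. `penalty_detection_summary()` compares the mean engine penalty of
tested pairs between detected and undetected genes, the diagnostic linking
primer quality to RT-PCR success.

# Simulators: what they emulate, and what they do not

`simulate_expression()` emulates the structure of replicated circadian
RNA-Seq courses: a 0–44 h grid every 2 h, two replicates, three courses
sharing gene parameters with independent Gaussian noise on the log10 scale
(the scale on which the ANOVA and regression operate), and gene classes —
flat, 22-h cosine cyclers, linear trenders, and low-expressed genes below
the detection cutoff. Defaults: noise SD 0.2 (cyclers' amplitude 1),
base expression spanning roughly 0.1–3.2 log10 units, matching the
reported reference-gene expression range. What it does **not** emulate:
count noise and its mean–variance relation, heavy-tailed outliers,
batch/replicate correlation, or non-sinusoidal waveforms. Passing the
planted-recovery tests therefore shows the chain is correct and selective
under its own assumptions, not that real libraries are this well behaved.

Two optional class constructions exist solely to make planted-truth
recovery deterministic rather than seed-lucky: `centered_noise` draws
within-time-point mean-centered noise, making a flat gene's between-time
variance exactly zero (its time-effect ANOVA is null by construction —
without this, 5% of genuinely flat genes fail an α = 0.05 screen by
definition); `opposed_gradient` reverses the class's noise-magnitude
ordering between courses 1 and 2 (factors of 2 between adjacent genes), so
every pair of planted genes trades places across datasets and the class is
mutually nondominated — otherwise roughly half the planted genes would be
dominated by their own siblings by chance and no deterministic consensus
assertion would be possible.

`simulate_genome()` plants mono-, two- and three-exon genes on both strands
of one contig, GC ≈ 50%, no homopolymer beyond 6 bp, exons ≥ 250 bp —
composition under which every gene is designable by the built-in engine
(asserted as a post-generation audit in the tests). It does not emulate
repeats, paralogy, or GC skew, so off-target behavior is untestable here by
design (specificity screening is out of scope). `simulate_ct()` uses the
dilution relation $C_t = 35 - \log_2\!10 \cdot \log_{10}(\mathrm{expr})$
with Gaussian cycle noise (SD 0.15) and a dropout probability
$1 - e^{-(0.6\,\mathrm{penalty} + 0.35\,\max(0,\,C_t - 30))}$, increasing
in primer penalty and in cycles above a soft ceiling — enough structure to
make the penalty-vs-detection and SD-vs-detection patterns emerge from the
generator rather than being wired in.

# Numerical choices and degenerate inputs

* log10(0) is represented by a configurable floor, default **−4** — below
  the −2 expression cutoff, so zero-FPKM genes can never pass the filter.
* Zero-variance series: ANOVA returns p = 1; a zero-residual regression
  yields degenerate intervals equal to the fitted line and PIRS counts only
  the drift term.
* A dataset with zero score spread min–max-normalizes to all-zeros with a
  warning rather than dividing by zero.
* RSD with mean 0 is undefined; such genes are flagged non-candidates with
  a recorded reason.
* All ties (quintile boundaries, equal PIRS, equal pair penalties) break by
  gene ID or coordinates, never by hash or address, so every output is
  reproducible byte-for-byte.
* Problem sizes used throughout the test and acceptance suites — 200-gene
  recovery datasets, 1 000-gene calibration, 25–50-gene genomes, 10 000
  permutations — were chosen as the smallest sizes at which the asserted
  properties are statistically meaningful.

# Known limitations

* The JTK variant scans a configured period set against cosines only; no
  harmonic regression, amplitude estimation, or asymmetric waveforms.
* PIRS assumes a linear drift model within a course; strongly nonlinear
  but non-rhythmic trends inflate $s$ and are penalized as instability,
  which is usually — but not always — the desired behavior.
* The consensus requires a gene to be scored in every dataset; a gene
  filtered in one condition can never be a candidate, even if exemplary
  elsewhere.
* The built-in engine checks self-complementarity within a primer but not
  cross-dimers between the two primers of a pair, and performs no
  genome-wide specificity screening.
* Catalog numbers reported on real genomes (for example, near-total design
  success over ten thousand ORFs) are scale demonstrations requiring the
  real genome; here they are replaced by structural assertions on
  constructed fixtures.
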