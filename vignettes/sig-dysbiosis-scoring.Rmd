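---
title: "Scoring gut dysbiosis with species interacting groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gut dysbiosis with species interacting groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscore)
```

## The classifier

The gut microbiome of cancer patients is systematically re-structured
relative to healthy subjects, and the direction of that re-structuring can be
summarized by two antagonistic constellations of co-abundant species
("species interacting groups"). SIG1 collects 37 species repeatedly
associated with resistance to immune checkpoint inhibition and worse
survival; it splits into an oral-cavity sub-cluster (aerotolerant genera such
as *Veillonella* and *Streptococcus*, plus *Bifidobacterium dentium*) and a
gut-resident obligate-anaerobe sub-cluster (*Enterocloster* spp.,
*Clostridium* spp., *Hungatella hathewayi*, *Erysipelatoclostridium
ramosum*). SIG2 collects 45 gut-resident butyrate producers associated with
better prognosis (*Faecalibacterium* spp., *Eubacterium rectale*,
*Coprococcus comes*, *Roseburia inulinivorans*, *Oscillibacter* sp. ER4, and
others).

A sample is summarized by how many unique members of each group are
*detectable* in its species-level taxonomic profile. With $N_{SIG1}$ and
$N_{SIG2}$ those counts, the score is the unweighted balance

$$S = \frac{1}{2}\left(\frac{N_{SIG2}}{45} - \frac{N_{SIG1}}{37} + 1\right) \in [0, 1].$$

Samples with $S \le 0.535$ are classified dysbiotic (SIG1+), samples with
$S \ge 0.791$ eubiotic (SIG2+). Scores strictly between the thresholds fall
in a gray zone that is arbitrated by *Akkermansia muciniphila* (the SGB9226
bin), whose relation to outcome is trichotomic rather than monotone: gray
samples that lack it, or carry it above 4.799% relative abundance, resolve to
SIG1+; gray samples with "normal" levels resolve to SIG2+. All three boundary
inequalities are implemented exactly as printed (inclusive `<=`/`>=` on the
score, strict `>` on the abundance cutoff); `classify_sample()` and the
sweeps in `tests/testthat/test-acceptance.R` pin them down to grid
resolution 0.001.

Note one consequence of the inclusive lower threshold that is easy to
misread: a sample in which *nothing* is detected has $S = 0.5$, which is
*below* 0.535, so it is dysbiotic by the primary rule — the Akkermansia
arbiter is never consulted for it.

## The catalog and its placeholders

The published 37 + 45 species lists are maintained in an external
repository; this package must remain self-contained, so the shipped default
catalog (`inst/extdata/sig_catalog.json`) contains every species named in
the narrative description of the groups and pads each list with entries
flagged `"placeholder": true` up to the exact reference sizes. The padding
preserves every structural property the code and tests rely on (sizes 37/45,
disjointness, the oral/gut partition of SIG1, Akkermansia held outside both
groups) while making the provenance of each entry explicit. Substituting a
published list is a pure data edit: replace the placeholder entries in the
JSON and reload with `load_sig_catalog()` — validation re-checks every
invariant and no code changes.

Two open choices were resolved as follows. *A. muciniphila* is kept outside
both SIG sets and used only as the gray-zone arbiter; including it in SIG2
would let the same organism move the score *and* resolve the zone that score
lands in, a double-counting we prefer to avoid (a custom catalog may include
it if desired — validation only insists the arbiter entry itself is not a
group member). The distilled 21-taxon variant of the classifier is not
implemented: its membership is unpublished and its printed arithmetic
(5 + 17) is internally inconsistent.

Name matching between catalog and table is by canonical species token
(lower-cased, separators collapsed, clade prefixes stripped), with an SGB
code fallback when both sides carry one — MetaPhlAn 4 output mixes both
naming styles across versions.

## Detection, thresholds, and the CLR transform

"Detectable" is operationalized as relative abundance strictly greater than
a configurable `detection_threshold`, default 0: any nonzero MetaPhlAn call
counts, which matches how such profilers report absence as exact zero.
"Lack" of Akkermansia in the gray-zone rule uses the same threshold, for
symmetry. Counts are monotonically non-increasing in the threshold, a
property the unit tests check directly.

Heatmap-style and differential analyses work on centered log-ratios,
$\mathrm{clr}(x)_j = \ln\!\big((x_j + pc)/g(x + pc)\big)$ with $g$ the
geometric mean. Zero replacement is a fixed additive pseudocount, default
$10^{-5}$ percent — the simplest reproducible choice, exposed as a parameter
since no single convention dominates. Per-sample CLR values sum to zero to
within $10^{-9}$ by construction. Abundances are treated as percentages
(0–100), consistent with the 4.799% cutoff; tables whose per-sample totals
look like proportions in $[0,1]$ are auto-rescaled with a warning.

## Co-abundance network and Ward partition

The network stage uses Spearman rank correlation of CLR-transformed
abundances between all pairs of taxa passing a prevalence filter (default:
detected in at least 10% of samples), with two-sided p-values from the
large-sample t approximation, Benjamini–Hochberg adjustment across all
tested pairs, and edges retained at adjusted $p \le 0.05$. Rank correlation
on CLR is a standard, reproducible co-abundance choice that is robust to the
compositional scale; the estimator is deliberately simple and documented so
it can be swapped. One caveat worth knowing: on *small* taxon panels the CLR
itself induces a spurious correlation of order $-1/p$ between independent
taxa; with realistic panel widths (dozens to hundreds of species) this is
negligible, and the test suite works at $p \ge 40$ where it is.

Clustering is agglomerative with Ward's minimum-variance linkage
(`hclust(method = "ward.D2")`) on the distance $d = 1 - \rho$ — the
conventional correlation-to-distance proxy, noted as approximate since Ward
formally expects squared Euclidean geometry. The default cut requests 10
clusters, mirroring the ten major clusters of the reference co-abundance
network, and is a plain parameter. Agglomeration order in `hclust` is
deterministic for a fixed input, which supplies the reproducibility the
tie-break rule exists for. Hierarchy nesting (a lower cut never merges
clusters separated at a higher cut) is asserted as a property test.

## Cohort statistics

The retrospective stage mirrors a fixed analysis sequence: a 2×3
classification table (group × SIG1+/GRAY/SIG2+) collapsed to SIG2+-vs-not
and tested with Fisher's exact test (conditional-MLE odds ratio, with a
Haldane–Anscombe 0.5 fallback for degenerate cells; a 2×3 exact variant is
available); the per-sample SIG balance $N_{SIG1} - N_{SIG2}$ (positive =
SIG1 dominance) binned for mirror histograms; Spearman correlation of SIG1
(and SIG2) counts with overall-survival months; a Kaplan–Meier median-split
on the SIG1 count with the log-rank test, for overall and progression-free
survival; and per-taxon Wilcoxon rank-sum tests on CLR values between
SIG1-high and SIG1-low samples with BH adjustment (the volcano table).

The survival correlation is computed over all samples with a recorded
follow-up time regardless of event status, mirroring the printed analysis;
`events_only = TRUE` restricts to observed deaths, the statistically safer
variant under censoring, and is the recommended option when censoring is
heavy and informative.

Compositional dysbiosis subtypes operationalize a qualitative description:
among finally-SIG1+ samples, Type 1 is a modest loss of SIG2 with oral
spillover (SIG2 retention $\ge 0.15$ and oral fraction of detected SIG1
$\ge 0.5$), Type 2 a near-complete SIG2 collapse with gut-anaerobe dominance
(retention $< 0.15$, oral fraction $< 0.5$); mixed configurations and all
eubiotic samples are `unclassified`. The cutoffs (0.15 collapse, 0.4
"modest" annotation boundary, 0.5 oral fraction) are invented
operationalizations of descriptive text and are prominently configurable —
they should be re-examined on any real cohort.

## What the synthetic generator emulates — and what it does not

No patient metagenomes are distributed with this package, so every
downstream stage is validated on synthetic cohorts whose *statistical
structure* matches the study conditions the analysis assumes:

* **Label mixtures.** Healthy subjects are predominantly eubiotic (~68%
  SIG2+, ~4% SIG1+ three-way labels) and cancer patients predominantly
  dysbiotic (34% SIG1+, ~23% SIG2+). A single per-group detection
  probability cannot produce both a 68% mass above the eubiotic threshold
  and a 4% mass below the dysbiotic one — the binomial score distribution is
  far too concentrated — so each sample is first assigned to one of three
  ecology strata (eubiotic: per-taxon detection 0.10/0.80 for SIG1/SIG2;
  intermediate: 0.26/0.47; dysbiotic: 0.55/0.15). The label probability of
  each stratum follows exactly from the convolution of two binomials
  (`label_probabilities()`), and the stratum weights are then solved
  analytically against the target fractions (`calibrate_ecology_mix()`).
  The targets are the three-way (pre-gray-resolution) fractions.
* **Akkermansia trichotomy.** Per group, a mixture over absent / normal
  (uniform on (0, 4.799]) / overabundant (uniform on (4.799, 15]); the 15%
  upper bound is arbitrary and documented, only the 4.799 boundary is fixed.
  Group mixtures (healthy 0.20/0.70/0.10, cancer 0.40/0.45/0.15) are chosen
  once as plausible contrasts; no published proportions exist.
* **Abundances.** Detected taxa draw log-normal abundances (meanlog
  $\ln 0.2$, sdlog 1, percent scale); 150 non-catalog filler taxa make rank
  and prevalence filtering non-trivial. When a sample's total would exceed
  100%, only the non-Akkermansia portion is scaled down, so the drawn
  Akkermansia stratum is never crossed by renormalization.
* **Survival.** Exponential times with hazard
  $h = h_0 \exp(\beta \cdot N_{SIG1})$, $h_0 = 0.02$/month, $\beta = 0.15$
  per detected SIG1 taxon (positive $\beta$ = shorter survival with higher
  SIG1 burden — the sign convention is explicit to prevent silent
  inversion), administrative censoring at 60 months plus 20% random early
  censoring. Progression-free times use a 1.6-fold hazard and are capped at
  the survival time.

Everything flows from one integer seed; the same configuration and seed
reproduce the cohort bit for bit. Under the defaults the cancer-group median
SIG1 count lands around 9–10, close to the reference median split at 9.

The generator deliberately omits several features of real metagenomes:
taxon-specific prevalence and abundance profiles (all members of a group are
exchangeable), inter-taxon correlation within a sample beyond the stratum
effect, over-dispersion and zero-inflation beyond Bernoulli detection,
strain-level variation, and any direct biological coupling between
Akkermansia and the rest of the community. Passing tests therefore
demonstrate that the *pipeline* recovers effects it was designed to detect
under a faithful null/effect structure — not that real cohorts will show
effects of these magnitudes. In particular the synthetic SIG1–survival
correlation (around −0.6 at the default $\beta$) is intentionally stronger
than what heterogeneous patient data yield.

A separate fixture generator, `planted_block_table()`, draws taxa from a
Gaussian copula with planted correlation blocks mapped to log-normal
margins; monotone margins preserve rank correlations, so the planted
structure is exactly what the Spearman network should recover. Its samples
are kept sub-compositional (totals well below 100%) so compositional closure
does not distort the planted blocks.

## Numerical choices and problem sizes

Boundary grids use exact rational points (`(0:1000)/1000`) so that 0.535,
0.791 and 4.799 are represented by the same double as the catalog constants.
The score formula is checked exhaustively over all 38 × 46 count pairs
against an independent evaluation. Fisher's exact p-values are compared with
a hand-coded hypergeometric tail sum over every non-degenerate 2×2 table
with total $N \le 30$; BH q-values against a hand-coded step-up; the
log-rank test against its nominal 5% rejection rate in 1,000 null
replicates at $n = 100$. Network recovery uses ten planted blocks of five
taxa (within-block $\rho = 0.9$) at $n = 500$ across ten seeds, requiring
adjusted Rand index $\ge 0.9$. End-to-end parameter recovery uses 100 seeds
at 400 samples per group, requiring a negative SIG1–survival correlation in
at least 95 and median-split log-rank $p < 0.01$ in at least 90, with both
signals at nominal false-positive rates when $\beta = 0$. Calibration is
checked as the mean over 20 seeds at 2,000 samples per group, within ±5
percentage points of each target fraction. These sizes were chosen to make
the stochastic checks decisive while keeping a full test run comfortably
interactive.

## Known limitations

* The default catalog's placeholder entries mean scores computed on *real*
  MetaPhlAn profiles with the shipped catalog reflect only the named
  species; supply the published lists for faithful scoring.
* The co-abundance estimator is a documented stand-in for the original
  network workflow, whose exact estimator, prevalence filter and edge rule
  are not restated here; conclusions about specific edges should not be
  read across.
* The Spearman-vs-survival correlation treats censored follow-up as
  observed time (as printed); prefer `events_only = TRUE` or proper
  survival models for inference on real cohorts.
* Subtype cutoffs are heuristic operationalizations, and the 2×2 collapse
  choice for the Fisher contrast (SIG2+ vs not) is one of two defensible
  readings — the 2×3 variant is provided.
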