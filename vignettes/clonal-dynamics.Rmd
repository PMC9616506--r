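---
title: "Models and methods behind clonepulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonepulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepulse)
```

clonepulse quantifies how the subclonal architecture of a tumor shifts under
chemotherapy, using the data types produced by a preclinical
patient-derived-xenograft (PDX) study: allele-specific copy-number segments
from SNP arrays, single-cell low-pass copy-number profiles, bulk expression
with patient survival cohorts, and caliper tumor-volume series. This
vignette explains each model, its assumptions, the parameters that matter,
and what the synthetic-data generators do and do not emulate.

## Bulk clonality: MSF, TCF and MCF

A copy-number aberration carried by a fraction $m$ of the cells in a sample
(tumor plus stroma) shifts the observed median probe intensity away from
the background. If aberrant cells carry $N_t$ copies where non-aberrant
cells carry $N_p$ (usually 2), the expected intensity ratio is the cell
mixture

$$2^{\log_2 R} = \frac{m N_t + (1 - m) N_p}{N_p},$$

which inverts to the *mutated sample fraction*

$$\mathrm{MSF} = \frac{N_p \cdot 2^{\log_2 R} - N_p}{N_t - N_p}.$$

Copy-neutral imbalances ($N_t = N_p$) are invisible to the intensity ratio;
their MSF comes from the mirrored B-allele frequency. With $N_A \le N_B$
minor/major allele copies in aberrant cells on a diploid heterozygous
background, the allele mixture
$\mathrm{mBAF} = \frac{m N_B + (1 - m)}{m (N_A + N_B) + 2 (1 - m)}$
inverts to

$$\mathrm{MSF} = \frac{1 - 2\,\mathrm{mBAF}}
{\mathrm{mBAF}\,(N_A + N_B - 2) - N_B + 1}.$$

The orientation convention matters: $N_B$ names the *major* allele, so
mBAF lives in $[0.5, 1]$ and the printed formula is the exact inverse of
the forward mixture (the test suite asserts the round trip to $10^{-9}$
over a full grid of unbalanced genotypes). Inputs violating $N_A \le N_B$
are swapped with a warning rather than rejected. Balanced genotypes
($N_A = N_B$) pin mBAF at 0.5 and raise a non-identifiability error, as
does $N_t = N_p$ on the intensity route.

Estimated fractions within 0.05 of $[0, 1]$ are clamped into the unit
interval; anything further out is *returned unclamped and flagged*. The
tolerance separates measurement noise, which should be absorbed, from a
mis-specified allelic composition, which should be surfaced. High-grade
amplifications are always flagged low-confidence: their total ploidy is
poorly determined by either signal.

Purity (tumor cell fraction, TCF) is the mean MSF of aberrations designated
clonal, with the *interval of clonal events* $\mathrm{TCF} \pm 2\,
\mathrm{SD}_{\mathrm{MSF}}$. An aberration whose MSF falls inside the
interval (boundaries inclusive) is clonal and its mutated clone fraction is
set to 1 exactly; otherwise $\mathrm{MCF} = \mathrm{MSF}/\mathrm{TCF}$,
clamped to $[0, 1]$. The interval can equivalently be read on the MCF scale
(divide both bounds by TCF) — the two readings classify identically, so we
classify on the MSF scale and note the equivalence.

Clonal designation was a manual, plot-inspection step in the source
workflow. The default path therefore expects an explicit `is_clonal`
column. The automated proxy (`clonal_mode = "auto"`) takes the densest
cluster of MSF values within a 0.1-wide window containing the maximum MSF;
since any such window is maximised by anchoring its upper edge at the
maximum, this reduces to $\{\mathrm{MSF} \ge \max(\mathrm{MSF}) - 0.1\}$.

Only segments of at least 50 kb supported by at least 50 array probes enter
the analysis; both bounds are inclusive, and coordinates are 1-based
inclusive (length $= \mathrm{end} - \mathrm{start} + 1$).

## Single-cell event calling and clone grouping

Single-cell profiles are integer copy states on ~1-Mb bins (BED-style
0-based half-open bins). An event is a maximal run of consecutive
same-chromosome bins at a constant non-baseline state:

* ordinary imbalances need **five** consecutive bins;
* high-grade amplifications (state at least `baseline + 3`, i.e. five
  copies on a diploid background — the threshold is configurable since no
  canonical value exists) need only **two** consecutive bins;
* a run qualifying for both grades is emitted once, as an amplification;
* runs never cross chromosome boundaries, and by default a single
  dissenting bin breaks a run.

Cells with identical event sets (same chromosome, bin span, direction and
copy state) form clones, labelled deterministically by decreasing size with
ties broken by the smallest member cell identifier; event-free cells form
the designated `baseline` clone and single-cell clones are flagged. The
event matrix over clones carries cell counts as column weights, so weights
always sum to the number of cells.

Strict run-breaking and exact set equality are the reproducible defaults,
but they are brittle under per-bin noise: a single flipped bin inside a
planted run splits or reshapes its span, and with a realistic 1% flip rate
most cells then disagree with their clone's canonical event set. Two
documented options recover robustness for noisy data, and the noisy
recovery tests use both: `max_gap_bins = 1` absorbs single-bin
interruptions between same-state runs, and `match_mode = "overlap"` groups
cells whose event sets pair one-to-one by chromosome, direction and state
with at least 50% reciprocal span overlap (grouping by connected
components, since tolerant matching is not transitive). With these, the
planted partition is recovered at adjusted Rand index above 0.9 in
essentially every replicate of the simulation study (20 cells, 3 clones,
events of 8+ bins, flip rate 0.01).

## Maximum-parsimony clone trees

Events are binary characters; the tree is rooted at the unaberrated
all-zero ancestor, and gains and losses both count one change (unordered
Fitch counting — the minimal model when no character model is given). The
per-event Fitch pass runs in C++; an extra change is charged whenever the
root's state set excludes the ancestral zero.

Up to seven leaves, every rooted binary topology is enumerated (the
$(2n-3)!!$ trees are cached per leaf count) and scored — the optimum is
guaranteed. Beyond that, seeded stepwise addition builds a starting tree,
and steepest-descent hill climbing over subtree-prune-regraft
rearrangements refines it, with a bounded number of sideways moves across
equal-score plateaus (parsimony landscapes are plateau-rich; pure descent
stalls on them) and a handful of random restarts. Among co-optimal trees
the lexicographically smallest canonical (sorted) newick is returned, so
output is reproducible for a fixed seed. The test suite checks the
heuristic against the exhaustive optimum on hundreds of random matrices and
both against an independent parsimony implementation.

The *stem* of a model is the intersection of all sample event sets. An
event whose Fitch count on the fixed tree is two or more cannot be
explained by a single origin and is flagged as parallel evolution;
convergence across independently analysed models is tabulated by matching
events with the same chromosome and direction at 50% reciprocal overlap.
Maximum-likelihood reconstruction is deliberately out of scope: the trees
are interpreted topologically, not parameterized.

## Heterogeneity indices and fish plots

For a tumor with clone frequencies $f$ summing to 1:

* $\mathrm{CNAB} = \sum_{\text{clones}} f \cdot \sum_{\text{non-stem
  events}} |\Delta \text{copies vs diploid}|$. Stem events are excluded so
  the burden compares what each tumor acquired within the model; a
  configuration flag compares against the sample's modal ploidy instead of
  diploid for whole-genome-duplicated samples.
* Simpson's index of diversity $D_s = 1 - \sum f^2$: 0 for a monoclonal
  tumor, at most $1 - 1/k$ for $k$ clones, maximised at uniformity.
* The private-aberration fraction counts, per tumor, the non-stem units
  seen in no other tumor of the model — clones by default (exact event-set
  equality), events optionally (overlap matching) for sensitivity analysis.

Fish-plot preparation validates that children's frequencies never exceed
their parent's at any observed time (within $10^{-6}$), fills absent clones
with zero, interpolates linearly onto a regular grid, and pins a newly
emerging clone to zero at the midpoint before its first observation — the
standard fish-plot convention. Violating tables are rejected with the time
point and clones named, not silently repaired.

## Signature scoring and survival integration

Expression is assumed variance-stabilized. A signature score is the
per-sample mean of gene-wise z-scores over the signature genes present;
constant genes are dropped with a warning. Variable-gene selection ranks by
sample variance (the estimator is unstated upstream; sample variance is
used) with lexicographic tie-breaks at the boundary. Signature merging
unions gene lists with per-gene provenance; genes claimed by both of two
opposing signature families are assigned by majority of supporting sources,
with ties dropped from both sides and reported.

The integrated-signature filter tests each gene by a median-cut log-rank
test — ties go to the low arm, arms smaller than two patients raise a
degenerate-split error — followed by Benjamini–Hochberg adjustment across
the signature and retention at FDR < 0.05. The log-rank statistic is
implemented from its standard hypergeometric observed-minus-expected form
so the pipeline is self-contained; the test suite cross-checks it against
the survival package and verifies null p-value uniformity. Whether the
original analysis also filtered on the *direction* of the association is
unknowable from the text; direction filtering is on by default whenever a
signature declares an expected prognosis (`"favorable"` keeps genes whose
high-expression arm fares better), and is switchable off. An FDR threshold
of 1 disables the filter entirely, returning every testable gene.

## Treatment response

Caliper measurements convert by $V = \pi l s^2 / 6$ (swapping sides with a
warning when the "long" side is shorter). Relative volume is tracked
against the first observation at or after randomization. The default
classes follow the Pediatric Preclinical Testing Program conventions —
complete response below a measurable minimum of 100 mm³ (maintained CR if
still below it at the final in-window observation), partial response at
min relative volume ≤ 0.5, progressive disease at max ≥ 1.25, stable
disease otherwise, relapse on regrowth past 200 mm³ after a CR or after
surgical resection. The framework's exact parameterization (evaluation
window, minimum SD duration) is not recoverable from the source text, so
these are package defaults, exposed as configuration keys and echoed into
the output metadata — not claimed as the original study's values.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of `(seed, config)`; regeneration is
bit-identical, and each dataset travels with its truth record
(JSON-serializable, lossless round trip).

* **Clone trees** grow by uniform random attachment; branch events are
  drawn without within-lineage overlap on a 22-autosome, 1-Mb-bin genome
  (real chromosome lengths, no sex chromosomes). Optional stem
  whole-genome duplication doubles the baseline ploidy.
* **Bulk segments** apply the forward mixture models exactly, then add
  Gaussian noise: $\sigma_{\log_2 R} = 0.02$ and $\sigma_{\mathrm{mBAF}} =
  0.01$ by default — visibly non-trivial yet recoverable, matching
  well-behaved array data. A stated fraction of segments is planted below
  the 50 kb / 50 marker curation filter to exercise it.
* **Cell matrices** draw cells independently from the clone mixture and
  flip single bins by ±1 copy at rate 0.01 by default.
* **Expression cohorts** give signature genes a shared latent state
  (70% of variance by default) — the structure of lineage-state signatures,
  whose member genes rise and fall together, and the reason per-gene
  survival filtering can recover a score-level hazard. Survival is
  exponential with hazard $h_0 e^{\beta \cdot \mathrm{score}}$ on the
  standardized score and independent exponential censoring calibrated to a
  30% default rate.
* **Volume series** are piecewise-exponential archetype trajectories
  (progression, stability, partial and complete regression, relapse after
  CR or after mid-window surgical resection) with multiplicative
  log-normal noise, default 5%. The archetype-to-expected-call contract is
  part of the generator: `CR` re-emerges above the measurable minimum
  before the window ends (so the call is CR rather than maintained CR),
  while the surgery archetypes end the window below it (MCR), with and
  without late regrowth.

What the simulators do *not* emulate: probe-level array artifacts and wave
noise, doublets and quality gradients in single-cell libraries, clone
trees with polytomies or frequency drift between sampling times, batch
effects or heavy-tailed expression, and informative censoring. Passing the
recovery tests therefore demonstrates correctness of the inference given
the stated generative models, not robustness to every artifact of real
data.

## Numerical choices and problem sizes

Tolerances: MSF/MCF clamping 0.05 absolute; frequency-sum and nesting
checks $10^{-6}$; round-trip identities asserted at $10^{-9}$. Tie-breaks
are lexicographic throughout (clone labels, co-optimal trees, variance
ties) so every result is deterministic for a fixed seed. Degenerate inputs
fail loudly: empty clonal sets, zero-column matrices, balanced genotypes,
sub-minimum survival arms and nesting violations all raise typed errors
rather than producing silent defaults.

The test suite's simulation studies use deliberately compact designs —
200 purity-recovery replicates, 100 noisy clone-partition replicates at 20
cells each, 200 random parsimony matrices with at most 7 leaves, 1,000
log-rank null replicates, 50-seed power studies at 300 patients, 350
response-archetype classifications — sizes at which every Monte-Carlo
criterion is stable across seeds while the whole suite runs in a few
minutes on a laptop.
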