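---
title: "From chemical-genetic screens to ranked mechanisms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chemical-genetic screens to ranked mechanisms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemnet)
```

# Scope

`chemnet` implements the computational arc of a humanized-yeast
chemical-genetic study of MTAP inhibition: growth screens of gene-deletion
libraries under drug treatment (or in a *meu1*Δ genetic mimic) are scored
and thresholded into interaction calls; high-content microscopy tables are
scored for protein abundance and localization changes; the combined hit list
seeds a network analysis on a confidence-filtered interactome (minimum
connector network, betweenness ranking, community detection, community
significance); and communities are annotated by gene-set
over-representation. A synthetic-data generator with machine-readable
planted truth stands in for the raw laboratory screens, so every stage is
testable end to end without any external download.

The package consumes quantified tables only. Image segmentation (colony
grids, per-cell fluorescence) and database retrieval (interactome releases,
pathway collections) are upstream of its scope.

# Growth and endpoint statistics

**Residual growth.** Liquid growth is summarized as percent residual growth,
$(\mathrm{OD}_{600}^{\text{treated}} / \mathrm{OD}_{600}^{\text{vehicle}})
\times 100$, evaluated at the first measured time point at which the vehicle
control lies in the mid-log window $[0.3, 0.5]$ OD units. We use the
earliest in-window index with no interpolation: readings are hourly and the
window is wide relative to the sampling interval, so interpolation would add
model assumptions without changing calls. The window is a configurable
parameter. When treated and control replicate counts match, replicates are
paired by index and per-pair percentages averaged; otherwise the mean over
all pairs is used (the pairing scheme is a design choice; replicate pairing
is rarely meaningful in pinned screens but preserves paired structure when
it exists).

**Epistasis score.** For a double mutant the score is
$((g_{\text{double}}/g_{\text{query}})/(g_{\text{array}}/g_{\text{wt}}))
\times 100$, i.e. deviation from the multiplicative expectation of the two
single mutants, rescaled so that a phenotypically neutral reference double
(the *his3*-partial analogue of the query deletion) scores exactly 100. The
reference correction is a single multiplicative factor applied per plate:
plate effects dominate batch structure in pinned screens, so a per-plate
reference is preferred over a global one.

**Dose–response.** IC50 is estimated by least squares on the
four-parameter log-logistic inhibition model
$y = b + (t - b) / (1 + (d/\mathrm{IC50})^{h})$, fitted on the
$\log_{10}$ dose scale with the Levenberg–Marquardt algorithm. To stabilize
small-$n$ fits on the percent scale, the bottom asymptote is constrained to
$\ge 0$ and the top to $\le 120$. Responses spanning less than 10 percentage
points are rejected as "no dose dependence" rather than fitted. An IC50
outside the tested dose range is returned but flagged `extrapolated`.

**Synergy.** The drug–drug synergy ratio is
$((g_{AB}/g_{A})/(g_{B}/g_{\text{vehicle}})) \times 100$; 100 is exact
multiplicative (Bliss-like) non-interaction, values below 100 indicate the
combination underperforms the expectation. The pairing of numerator and
denominator is notationally ambiguous in shorthand forms such as
"(RPM+MTA/MTDIA)/(RPM/DMSO)"; we resolve it as combination-over-single-agent
divided by second-agent-over-vehicle, which reduces to the Bliss null at
independence and is symmetric in the two agents.

**Viability and sterols.** Dead-cell-stain viability is
$\text{unlabeled}/(\text{labeled}+\text{unlabeled}) \times 100$; sterol
composition is each of squalene, lanosterol and ergosterol as a percentage
of their three-way total. Group comparisons use the classical equal-variance
two-tailed Student's *t*-test (Welch's form available by flag); degenerate
inputs (fewer than two values, zero pooled variance) raise an error rather
than produce an artificial p-value.

# Screen scoring and hit calling

**Plate normalization.** Colony sizes are divided by the plate median; row
and column effects, estimated as medians over interior positions, are then
polished out iteratively; border rows/columns — systematically larger in
pinned formats because of reduced nutrient competition — are corrected by
the border/interior median ratio; finally the interior median is anchored at
exactly 1. Row/column effects are removed from interior rows and columns
(each correction applies to the whole row or column of cells), while border
rows and columns are corrected solely by the border ratio; this separation
makes the full map idempotent to numerical precision, so re-normalizing
normalized data is a no-op. Missing colonies stay missing and are never
imputed as zero.

**Two-stage calls.** Hit calling mirrors a screen-then-validate design. At
the screen stage a strain is a putative interaction if its mean score
crosses the stage threshold with a per-screen two-tailed one-sample
*t*-test $p < \alpha$ (replicate scores against the neutral value 100) in at
least 2 of 3 independent screens. At the validation stage, calls come from a
single replicated growth assay with stricter thresholds: sensitive below
75%, resistant above 130%, $\alpha = 0.05$. The screen-stage default
thresholds are (40, 140): primary-screen wording of cutoffs is often
internally inconsistent in this literature (a "growth improvement > 40%"
reads as a typo for a symmetric upper cutoff), so both stages' thresholds
are plain configuration with the discrepancy surfaced rather than silently
resolved. No multiple-testing correction is applied by default — raw
$p < 0.05$ combined with effect-size and replication filters is the
screening convention — but Benjamini–Hochberg adjustment is available by
flag. A strain whose vehicle-condition growth falls below 10% of the plate
median (configurable floor) is reported as inviable and excluded from
interaction calls rather than miscalled as sensitive.

# Microscopy scoring

Per cell, the GFP intensity of the tagged protein is normalized to the RFP
reference channel; a strain–condition pair is summarized by the median
ratio, and the abundance change is the percent change of treated versus
control medians. The median (not the mean) is used because per-cell
intensity distributions are heavy-tailed — a handful of extremely bright
cells would otherwise dominate; the tests plant 10× outliers in 5% of cells
to demonstrate the difference. A change is flagged when it exceeds 20% in
either direction — the threshold at which changes are reliably confirmed by
visual inspection — with at least 50 cells per condition (a floor well below
the ~200 cells per replicate typical of automated imaging).

Localization is called by the modal-compartment rule: a shift requires the
modal compartment to differ between conditions *and* the treated fraction of
the new modal compartment to exceed its control fraction by at least 20
percentage points. Visual confirmation cannot be encoded; the modal rule is
the codified proxy and both thresholds are configurable. Compartment labels
come from a fixed vocabulary (cytosol, nucleus, vacuole, ER, plasma
membrane, endosome, cytoplasmic foci, other); unknown labels are an error,
not a silent extra category.

# Network analysis

**Filtering.** Interactome edges are kept when the combined confidence
score is at least 900 (of 1000) and, by default, the experimental evidence
channel is positive. Duplicate undirected edges are stored once and
self-loops dropped; identifiers are case-normalized opaque strings
(alias/ortholog mapping is the caller's responsibility).

**Seed networks.** The first-order network is the subgraph induced by the
seeds and their direct neighbors. The minimum network trims this to the
nodes needed to connect the seeds: per connected component we approximate
the Steiner tree with the Takahashi–Matsuyama incremental shortest-path
heuristic on unit edge lengths — starting from the lexicographically
smallest seed, the nearest unconnected seed is repeatedly attached along a
shortest path. The heuristic carries a 2-approximation guarantee, and ties
(equal-distance seeds, equal-length paths) are broken lexicographically so
the output is deterministic. Non-seed leaves are pruned, guaranteeing every
retained connector lies on a seed-to-seed path. Seeds in different
components yield one tree per component and are reported, never dropped.
Unit lengths are used because confidence scores are calibrated
probabilities, not distances; a monotone transform into lengths would be an
additional modeling assumption.

**Centrality.** Betweenness is Brandes' algorithm on the unweighted
undirected subnetwork, unnormalized, endpoints excluded, with shortest-path
multiplicity shared fractionally — the convention under which published
per-gene values are large fractional numbers. The tests verify exact
agreement with brute-force shortest-path enumeration on all graphs up to 8
nodes.

**Communities.** Community detection minimizes the two-level map equation —
the description length of a random walk under a modular code — with node
visit rates proportional to degree and no teleportation. The optimizer is a
greedy descent: starting from singleton modules, node-moving passes (each
node may join the best-improving neighboring module) alternate with
module-merge steps until no move lowers the code length. Only improving
moves are accepted, so the objective is non-increasing by construction; the
per-pass trajectory is returned for inspection. The node visit order of
each pass is drawn from the supplied seed, making results reproducible.
Two-level (flat) partitions only: hierarchical variants are out of scope.

**Significance.** A community's internal edge count is compared with its
distribution over degree-preserving edge rewirings of the whole graph
($10 \times |E|$ swap attempts per sample), with
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{null}} + 1)$. This
estimator never returns 0 and is valid (conservative) by construction;
with small communities the integer statistic ties with null draws often,
making the p-value noticeably conservative — calibration should be judged
on communities large enough that the statistic is effectively continuous.
Fewer than 19 null samples is an error (the p-value could then never fall
below 0.05). Each null sample draws from its own RNG substream, so
significance is reproducible and independent of evaluation order.

# Enrichment

Over-representation uses the exact hypergeometric upper tail, evaluated in
log space. Reported per set: overlap $k$, fold enrichment $(k/n)/(K/N)$, the
standardized deviation $z = (k - nK/N)/\mathrm{sd}$, the BH-adjusted
p-value, and the combined ranking score $z \times (-\ln p)$. The verbal
definition of the z-score as a "ratio of expected and observed" conflicts
with its use in a product-type combined score; we implement $z$ as the
standardized hypergeometric deviation and additionally report the literal
observed/expected ratio as fold enrichment, so both readings are available.
The combined score uses the unadjusted p-value (the Enrichr convention),
with a flag to use the adjusted one. The default universe is the screened
library, not the whole genome — enrichment is universe-sensitive by design
and the universe is always an explicit argument. Communities smaller than 3
genes are skipped (and noted), since no set can be meaningfully enriched in
them.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Growth screens** — logistic control curves
  ($r = 0.35\,\mathrm{h^{-1}}$, $K = 1.2$ OD, $\mathrm{OD}_0 = 0.01$,
  hourly sampling over 14 h) with multiplicative log-normal noise
  (relative s.d. 0.05, three replicates). These place mid-log at ~10–11 h
  and are typical of plate-reader yeast cultures; no noise magnitudes are
  standard in the literature, so the defaults are calibration choices
  validated by the null false-positive rate (5% ± 2%). Planted strains
  carry an effect multiplier applied either to the growth rate or to the
  whole OD trajectory; the latter makes the multiplier equal the noise-free
  percent growth, which is the configuration used for recovery benchmarks
  (50 strains, 5 sensitive at 50%, 5 resistant at 150%, 3 screens).
* **Interactomes** — Erdős–Rényi, preferential-attachment or
  planted-partition graphs with STRING-like integer scores: combined
  scores are drawn in 150–1000 with a configurable fraction at ≥ 900, and a
  configurable fraction of edges carries experimental evidence, so the
  confidence filter is genuinely exercised. Community benchmarks use 4
  blocks of 25 nodes with $p_{\text{in}} = 0.3$, $p_{\text{out}} = 0.02$.
* **Gene sets** — collections of 100 sets of 50 genes over a universe of
  1000, with 3 planted sets drawing 80% of their members from the query;
  decoys are uniform draws. Under these conditions a decoy occasionally
  reaches an overlap that survives FDR control, so "exactly and only the
  planted sets" recovery sits near (not at) 1.
* **Microscopy tables** — per-cell GFP/RFP intensities log-normal around
  strain means (log-scale s.d. 0.1, 200 cells per condition), compartment
  labels drawn from a predominantly cytosolic distribution, with planted
  abundance shifts scaling the treated GFP mean and planted localization
  movers re-weighting the treated compartment distribution.

Noise is multiplicative log-normal throughout because the emulated
measurements are positive and heteroscedastic. Every generator is a pure
function of its parameters and a master seed: each entity draws from an RNG
substream keyed by (stage, entity id), so enlarging a library never
reshuffles existing entities, and identical seeds give byte-identical
output. Every planted signal is recorded in a truth object consumed by the
tests.

What the generator does *not* emulate: spatial autocorrelation and
batch/edge artefacts beyond smooth row/column gradients, the degree
distribution of real interactomes beyond optional preferential attachment,
correlated gene-set overlap (real pathway collections are nested), or
cell-cycle structure in intensity distributions. Passing the planted-truth
benchmarks therefore demonstrates correctness of the algorithms under the
stated statistical model, not robustness to every artefact of real screens.

# Determinism and the pipeline

`runPipeline()` executes simulate → screen scoring → microscopy scoring →
seed merging → network → enrichment, writing each stage's TSV/JSON outputs
plus a manifest containing the full effective configuration (no hidden
defaults), the master seed, package version and MD5 checksums of every
output. All randomness derives from the master seed through named
substreams; rerunning a configuration reproduces every output byte for
byte. Stage outputs are plain text and are never mutated by later stages.

# Problem sizes

The validation suite runs at deliberately compact scales chosen so each
property is measured with adequate precision: betweenness and Steiner
oracles on hundreds of graphs of ≤ 8–10 nodes (where exhaustive enumeration
is exact), hypergeometric checks over thousands of parameter tuples with
$N \le 30$, FDR calibration over hundreds of 10,000-test null lists, screen
calibration over 150–200 simulated null screens, community recovery over 20
planted-partition instances of 100 nodes, and community significance with
999 degree-preserving nulls. These sizes give standard errors comfortably
inside the tolerances asserted.

# Known limitations

* The minimum network is a heuristic approximation; on adversarial graphs
  it may use up to twice the optimal number of connectors (never more, on
  the instances verified exhaustively).
* The map-equation optimizer is a local descent; very weak community
  structure can leave it at a local optimum, which the planted-partition
  recovery rate quantifies.
* Hit calling treats replicates as exchangeable and the per-strain t-test
  assumes approximate normality of replicate percent-growth values; with
  2–3 replicates the test is underpowered and the effect thresholds do most
  of the work, as in the screening convention it follows.
* Identifier harmonization (aliases, orthologs) is out of scope; callers
  must supply a consistent identifier space.
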