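---
title: "Methods: comparative circuit quantification with circuitdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative circuit quantification with circuitdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitdiff)
```

# The problem

When a neuron type is experimentally displaced or silenced during
development, does it still connect to the right partners, and with the
right numbers of synapses? Answering this requires comparing synaptic-
resolution reconstructions of a wild-type and a perturbed nervous system,
plus functional (calcium) and behavioral readouts of the same circuit.
`circuitdiff` implements the quantification layer of such a comparison
for hemisegmentally organized circuits like the larval *Drosophila*
mechanosensory network: connectivity statistics on skeletonized
reconstructions with polyadic chemical synapses, mediolateral density
profiles, stimulus-locked ΔF/F₀ response scoring, and windowed behavior
probabilities — together with seeded synthetic-data generators so that
every estimator can be validated against known ground truth without any
external dataset.

# Circuit model

A `circuit()` bundles four tables: treenodes (rooted trees, coordinates
in nm — the convention of CATMAID-style reconstructions), synaptic links
(one row per pre→post pairing of a polyadic connector; each pairing
counts as one chemical synapse), per-neuron annotations (cell type,
segment, side, homolog pairing, identification status), and volume
geometry (midline position and neuropil width in nm). User-facing
lengths are reported in µm and densities per mm.

Design choices that the data model fixes:

* **Edge attribution.** A parent–child edge belongs to the *child*
  node's compartment. This makes per-compartment cable lengths partition
  the total exactly, which is tested as an invariant.
* **Compartments are annotations.** Axon/dendrite labels arrive with the
  data (SWC type column: 2 = axon, 3 = dendrite, other = unlabeled). No
  splitting algorithm is computed; upstream reconstructions label
  compartments manually.
* **Axes.** Mediolateral = x, anteroposterior = y, dorsoventral = z. The
  volume's `midline_x` and `neuropil_width` configure the only geometry
  the analyses use.
* **Subvolume restriction and forests.** `restrict_to_subvolume()` is
  the coverage correction used when a partial volume is compared with a
  whole-nervous-system reference: nodes outside a closed box are
  removed, and a link survives only if both its endpoints do. Children
  of removed nodes become roots, so a restricted skeleton may be a
  forest; `validate_circuit(forest_ok = TRUE)` accepts these derived
  circuits, while primary inputs must be single trees.

# Connectivity statistics

All quantifications group individual neurons of one cell type in one
hemisegment (e.g. 8 mechanosensory axons, 4 Basins, 6 bilateral Ladder
interneurons, 1 Griddle, 1 Drunken, 3 nociceptive axons). Bilateral cell
types are included on both sides; a connection's hemisegment is
attributed from the *unilateral* partner's side annotation, because a
bilateral interneuron's left/right connectivity difference resides in
its connections with unilateral neurons.

* **Input fraction** — synapses from a presynaptic group divided by the
  target's total input count. Three modes: whole-neuron; dendritic (both
  numerator and denominator restricted to links onto dendrites, for cell
  types that receive seed input mostly there); and subvolume (both
  counts computed after restriction, for arbors that leave a partial
  volume). A target with zero inputs raises an error rather than
  returning 0 — an undefined fraction must not silently enter a
  comparison.
* **Partner ranking** — per-candidate sums of links from all seed
  members, with an inclusion threshold of 3 synapses and a strong/weak
  boundary at 15, both inclusive (a partner with exactly 15 seed
  synapses is strong). Ties in the ranking are broken by skeleton id so
  output is deterministic.
* **Homolog conservation** — for partners with ≥ t seed synapses on one
  side (t ∈ {1, 5, 10, 15} by default), the probability that the
  bilateral homolog receives ≥ 1 synapse from the opposite seed group.
  Eligibility requires a homolog annotation, identified status
  (optional), and ≥ 500 reconstructed nodes by default — the size filter
  that guards against spuriously "unconnected" fragments. Left and right
  estimates are averaged. `binned = TRUE` evaluates half-open strength
  bins instead of cumulative thresholds; that is the resolution at which
  the synthetic generator designs conservation, so it is what parameter
  recovery checks.
* **Cross-volume comparison** — fractions (never absolute counts, which
  grow with development) are compared with a chi-square test on the 2×2
  table `[[from-seed, other-input]]` per volume. Yates correction is off
  by default and configurable; with identical counts the statistic is
  exactly 0.
* **Retention** — given the wild-type ranking and the seed-synapse
  counts of matched candidates in the perturbed volume, the failure
  percentage per strength class is rounded to the nearest integer
  percent (9/37 → 24%, 1/23 → 4%). "Failure" defaults to *zero* seed
  synapses in the perturbed volume; counting `< 3` instead is available
  via `failure_rule = "below_min"` since published wording does not
  distinguish the two. New partners must receive ≥ 3 seed synapses in
  *both* hemisegments (left–right reproducibility) and be absent from
  the wild-type ranking.

# Spatial profiles

`density_profile()` slides a 2.5 µm window (closed interval, ±1.25 µm)
along the mediolateral axis on a grid spaced at 1% of the neuropil
width. Positions are normalized to the neuropil width and centered at
the midline; densities are optionally normalized to the cell type's
maximum. The window size is standard; the grid step is this package's
choice — dense enough for span-0.1 smoothing and cheap to compute.
Normalization order is count → max-normalize → smooth.

`loess_smooth()` is locally weighted quadratic regression with tricube
weights over the span-nearest neighbors (span 0.1 by default), computed
by `stats::loess` with `surface = "direct"` so results are reproducible
bit-for-bit and match an independent tricube implementation to 10⁻⁶
(the test suite carries one). Constants are reproduced exactly and exact
quadratics are reproduced whenever the span covers all points.

`exploration_ratio()` expresses the cumulative developmental coverage of
an arbor (union of binary masks over time) as a percentage of its mature
area; it is ≥ 100 whenever the mature arbor is contained in the union
and monotone as frames are appended. `membrane_profile()` binarizes a
3-D stack at an explicit threshold (≥ threshold counts; thresholds are
chosen manually upstream, so no automatic thresholding is offered), sums
over Z and averages over rows to give one value per mediolateral column.

# Calcium scoring

ΔF/F₀ = (Fₜ − F₀)/F₀ with F₀ the median of the whole trace, making the
series invariant under any positive rescaling of the raw signal. The
peak response is the maximum ΔF/F₀ in the 4.5 s window immediately after
stimulation *offset* minus the recent baseline (mean ΔF/F₀ of the 3 s
preceding onset). Two conventions are fixed here: the response window of
the rejection rule also follows the offset (the phrase "following
stimulation" is read to match the peak window; `window_from = "onset"`
is available), and window endpoints are half-open — `(offset,
offset + 4.5]`, `[onset − 3, onset)` — so no frame at ≈ 6.6 frames/s is
double-counted. A trial fails when the window mean lies within ± k
sample standard deviations (n − 1, over the 3 s baseline frames) of the
recent baseline — k = 1.5 for mechanosensory, 0.5 for nociceptive
stimulation. A zero-variance baseline with a deviating window responds;
with no deviation it does not. Failed trials are discarded and the
responding-trial peaks are averaged per animal; groups are compared with
a single-sided Wilcoxon rank-sum test.

# Behavior scoring

An animal enters the analysis only if it was tracked for ≥ 95% of the
analysis window (15 s for optogenetic/vibration stimuli, 40 s for
thermogenetic ramps, measured from stimulus onset or from the moment the
plate reaches temperature) and had *no* collision intersecting the
window — any overlap excludes. The behavior probability is the fraction
of valid animals with at least one bout intersecting the window (a bout
straddling the onset counts); durations are per-animal total bout time
clipped to the window, summarized as mean ± SE across animals.
Probabilities carry Wilson 95% intervals by default (Wald available);
the published analyses state only "95% confidence interval", and the
Wilson interval behaves correctly at the extreme probabilities rolling
assays produce. Probabilities are compared with the chi-square test on
responder counts, durations with a two-sided Welch t test (pooled
variance available). Whether durations should be per-bout rather than
per-animal totals is not determinable from the published wording;
per-animal totals are the default because they make the SE an
across-animal quantity like the probability.

# Statistical tests

The test layer wraps the standard implementations (`stats::chisq.test`,
`stats::wilcox.test`, `stats::t.test`) behind a uniform result type that
records the method and options used, so every comparison is reproducible
from its output metadata. Fixed conventions: Yates correction off by
default for the proportion test; rank-sum p exact by enumeration when
m + n ≤ 12 without ties, otherwise normal approximation with tie and
continuity correction (the one-sided approximation is within 0.01 of
enumeration at m = n = 6; at smaller sizes the exact branch applies);
Welch (unpooled) variances by default; degenerate zero-variance t tests
return p = 1 for a zero effect and p = 0, flagged in the method string,
otherwise. The Wilson interval is computed in closed form.

# Synthetic data and what it does (not) show

The generators are pure functions of a configuration and a seed.

**Circuits.** `generate_circuit()` realizes a bilaterally mirrored
hemisegmental roster with homolog annotations. Skeletons are
deliberately schematic — short random-walk trees (30 nodes by default,
configurable) around cell-type placement centroids — because no analysis
here uses geometry beyond positions and cable length; realistic
arborization would add nothing testable. Interneuron nodes are 60%
dendrite / 35% axon / root, sensory nodes all axon. Input links onto
each postsynaptic neuron are drawn multinomially at a fixed total
(e.g. 400 for a Basin) from the designed fraction matrix
(e.g. mechanosensory → Basin 0.20), the unassigned remainder coming from
a background pool; bilateral targets draw half their inputs from each
side. Polyadic connectors are formed by grouping links that share a
presynaptic node and are placed at that node (a single release site has
one position but several postsynaptic partners, so a per-link midpoint
is not well defined for a polyadic site).

**Conservation.** Each homolog partner pair draws a strength bin
([1,5), [5,10), [10,15), [15,∞) with design probabilities 0.75, 0.89,
0.97, 1.00); each side's seed connection then exists *independently*
with the bin's probability, with a synapse count uniform in the bin.
Under this bilateral-independence model the conditional probability the
analysis estimates — homolog connected given a connection in bin b —
equals the design probability on both sides, which is what makes the
design value recoverable without bias. Parameter-recovery runs disable
the 500-node filter (`min_nodes = 0`): synthetic skeletons are schematic
and reconstruction completeness is not part of the generated-data model.

**Perturbations.** A lateral shift translates the target type's nodes
and presynaptic sites away from the midline by per-axon offsets drawn
from N(shift, jitter) — individual axons are affected with different
magnitudes, as in the real manipulation. Silencing is emulated at the
level of its measured consequence: input links of affected targets are
resampled under gain-multiplied fractions (excitatory gains above 1,
inhibitory below), clipped to [0, 1] with the remainder reassigned to
the background pool. No biophysics is simulated.

**Calcium.** F(t) = F₀ + noise + A·exp(−(t − t₁)/τ) with the transient
aligned to the first acquired frame t₁ after stimulus offset, so the
noise-free ground-truth peak is exactly A/F₀ rather than carrying a
sampling-lag bias of up to one frame. Defaults: 6.61 frames/s, 30 s
rest, 100 ms stimulus, F₀ = 100, σ = 5, A = 80, τ = 2 s.

**Behavior.** Each animal responds with its group's design probability;
responders receive one bout inside the window (gamma-distributed
duration, shape 2, scale 1 s). Tracking gaps (2 s, rate 0.1) and
collisions (rate 0.05) are injected independently of the response so the
filters cannot bias the recovered probability.

A single seeded RNG stream drives each generator call; the determinism
contract is that identical (config, seed) yield identical output.
Sub-entities are not separately reproducible under this scheme — a
limitation accepted for simplicity.

What passing these tests shows: the estimators are exact on their count
definitions, unbiased on the generative models above, and correctly
calibrated as statistical procedures. What they cannot show: robustness
to reconstruction errors, to mis-identification of homologs, to
non-multinomial synapse placement, or to tracker artifacts beyond gaps
and collisions — real data contain all of these.

# Numerical choices and problem sizes

Tolerances used in the validation suite: loess fidelity 10⁻⁶ against the
independent implementation (10⁻⁹ for constants); noise-free calcium peak
10⁻³; count-based operations exact. Parameter-recovery runs use 1800
homolog pairs (≈ 340–450 eligible pairs per strength bin, putting the
±0.05 recovery band at ≈ 3 standard errors for the least favorable bin),
10,000 null tables at group size 300 for chi-square calibration, 2,000
null trials for the rejection-band comparison, and cohorts of 1,000
animals for behavior recovery — sizes chosen so each sampling interval
is decisively narrower than the band it is checked against.

# Known limitations

* Homology across volumes is annotation-driven; no morphological
  matching is implemented, so mis-annotated homologs propagate directly
  into conservation and retention estimates.
* The published eligible-partner counts for wild-type conservation (160
  and 149) depend on the identification status of the original
  reconstruction and cannot be reproduced without that dataset; the
  `identified_only` flag exposes the filter itself.
* Graph-theoretic analyses (paths, motifs), neurotransmitter inference,
  ROI extraction, tracking and behavior detection are out of scope;
  this package consumes their outputs.
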