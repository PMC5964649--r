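---
title: "Methods: lineage analysis of pre-implantation embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage analysis of pre-implantation embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastotrace)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

The input is a curated lineage table: one row per detected nucleus per
timestep with a unique `node_id`, a `predecessor_id` linking it to the
same cell one frame earlier, the frame index and the time in hours post
fertilization (wild types) or post activation (clones), the position in
micrometres, a validation flag, an optional inner/outer annotation and a
death flag. Frames are 15 minutes apart by default. Nodes are grouped
into **tracks** — maximal chains between divisions — so that a track is a
cell's life from birth (or the start of observation) to its division,
death or censoring at the end of the sequence. Only validated nuclei
enter any statistic: curation of real recordings is limited to a trusted
window, and everything downstream inherits that restriction.

Two conventions avoid silent corruption. A predecessor pointing to the
same or a later timestep is a *format* error and the file is rejected; a
predecessor two or more frames back passes the reader but is flagged by
`validate_lineage()` as a gap, because it is repairable curation damage
rather than a malformed file. `time_hp` and `timestep` are redundant;
when they disagree beyond tolerance the validator reports it rather than
preferring one silently.

## Inner/outer classification and propagation

At a single frame, a nucleus is **outer** when it is a vertex of the 3D
convex hull of all validated nuclei, or when its perpendicular distance
to the nearest hull facet plane is at most `shell_tolerance` times the
frame's mean nearest-neighbour distance. The default tolerance of 0.5
says: a cell within half a typical cell spacing of the enveloping surface
belongs to the epithelium. Distances exactly at the tolerance classify as
outer — the conservative direction for trophectoderm continuity — and the
tie rule is documented here precisely because it is arbitrary. We use the
perpendicular distance to the facet *plane* rather than to the facet
polygon: for interior points of a convex body the two differ only near
edges, and the plane distance is a lower bound, again erring toward
"outer". The hull itself (volume, vertices, facet planes) is computed by
the package's own incremental-hull implementation in C++, since no
installed R package provides a 3D hull; it is cross-checked in the test
suite against a brute-force plane-enumeration oracle and a Monte-Carlo
volume oracle.

Identity is a **per-track attribute**: a cell keeps one identity between
divisions, so the "identity prior to the next mitosis" of a daughter is
simply her track's identity, and daughters that never divide contribute
their identity at their last observed frame. Leaf tracks take the curated
annotation when present, else the geometric call at their last frame.
Propagation is leaves-to-roots: a mother whose daughters agree inherits
their identity (this is exact whenever the forward process is one of
inheritance with occasional single-daughter flips); a mother whose
daughters disagree — an asymmetric division — has no logically forced
identity, and is resolved by her curated annotation when present,
otherwise by the geometric rule at her own last position. The resolution
source is recorded per track (`identity_source`), since the geometric
fallback is this package's rule, not a fact of the data. A division is
**asymmetric** iff its daughters' identities differ; division times are
the mother's last frame, the last moment the dividing cell exists.

Deaths are input data (curation or the generator), never inferred from
geometry — death is identified morphologically in recordings, and a
geometry-based death call would confound the death/position analysis the
ratio below is meant to expose.

## Temporal rescaling

The embryo volume series is the convex-hull volume of all validated
nuclei per frame. The first **blastocoel collapse** is the earliest pair
of consecutive frames with `V(t+1) < 0.9 V(t)`; the threshold is strict
("more than 10%"), and the collapse is reported at the *later* frame —
the first frame exhibiting the reduced volume — a choice the data leave
open (the alternative, the last pre-collapse frame, shifts every anchor
by one frame interval). No smoothing is applied before detection; none is
needed when the 10% one-step rule holds, and smoothing would blur the
anchor it defines.

Normalized age is `na(t) = t / t_collapse`, anchoring 0 at
fertilization/activation and 1 at the collapse. Cross-embryo comparisons
are restricted to the intersection of the embryos' observed windows in
n.a., and when cohorts are pooled onto a grid the densest embryo's grid
(restricted to the common window) is used, preserving the finest temporal
resolution; series are interpolated linearly, and count series are
evaluated as step functions (the count at `t` is the count at the latest
frame at or before `t`) since cell numbers are piecewise constant.

## Population statistics

* **PIC** = inner/(inner+outer) per frame; group curves average
  per-embryo proportions unweighted, so a large embryo does not dominate.
* **OAD/IAD**: per half-open n.a. bin `[lo, hi)` of width 0.05 (about
  4.3 h), asymmetric divisions over all divisions of mothers of the given
  type. Bins are aligned at the common-window lower bound; empty bins are
  flagged, never zero-filled, because "no divisions" and "no asymmetric
  divisions" are different observations. A division exactly on an edge
  joins the right-hand bin (enforced with an epsilon against float
  representation of bin edges).
* **Normalized death ratio** `r_T = (D_T/D) / (N_T/N)` with `D_T` deaths
  of type `T` in the window and `N_T` distinct validated tracks of type
  `T` alive at any point in the window. Exposure is counted as distinct
  tracks, not cell-time: it is the simplest reading under which `r_T = 1`
  exactly when deaths are allocated proportionally to abundance, and the
  weighted identity `sum_T (N_T/N) r_T = 1` holds per embryo (both are
  tested). An exposure-weighted variant would change the numbers when
  track lifetimes differ systematically between types; the definition
  used is recorded in the run manifest. Embryos with no deaths in the
  window are excluded with a warning, and both the across-embryo standard
  deviation and the standard error are reported.
* **CV** across embryos = sample standard deviation (n−1) over mean, per
  grid point and type; undefined (flagged) where the mean is zero, and
  refused outright for a single embryo.
* **Neighbourhood composition**: for each division, the fraction of the
  mother's k = 8 nearest validated neighbours (Euclidean, at her last
  frame) of the other type. k-nearest is robust to embryo growth where a
  fixed radius is not. Summaries are emitted both pooled by division type
  and stratified by mother identity, since either convention is
  defensible.
* **Founder clones**: every validated cell present at the first frame
  heads a clone; we report its subtree's mitoses and final composition.
  For a binary tree, mitoses = final cells + deaths − 1, which doubles as
  an internal consistency check.
* **Relative developmental speed** of a clone is
  `t_collapse(clone) / mean(t_collapse(wild types)) − 1`, in percent. The
  quantity compared is the single common anchor; with the printed anchors
  of the source recordings this definition gives values that round to the
  reported slowdowns, which is why it was adopted among the several
  "percent slower" definitions possible.

## The in silico experiment

The transformation asks: what would the inner/outer populations have
looked like if outer (or inner) mothers had divided symmetrically?
A lineage's **division program** stores, per division, whether it was
asymmetric and which daughter was off-type, plus the root identities.
Replaying the program forward reproduces the observed identities exactly
(tested). Under transformation with target type `T`, divisions are
replayed root-to-leaf and a division is treated as symmetric when *the
mother's current replayed identity* is `T` and the division was flagged
asymmetric. Evaluating the mother under the transformed dynamics — rather
than on her original annotation — is the only reading with a clean fixed
point: afterwards no asymmetric division with a `T` mother remains, and
under `T = outer` every inner cell's ancestry is inner back to an inner
root (both tested as invariants, along with idempotence and conservation
of total counts). Selection on original annotations is available
(`selection = "original"`) for sensitivity analysis. Only identities
change; positions, times and topology are untouched, so every count
difference between conditions is attributable to division symmetry.

## The synthetic embryo generator

The generator produces the statistical structure the analysis consumes,
with ground truth, so that correctness can be tested exactly and
calibration can be tested against independent Monte-Carlo oracles.

It is a discrete-time branching process at frame resolution (15 min).
Each cell draws a log-normal cycle length (mean 14 h, CV 0.2 — chosen so
a wild-type-like embryo grows from 32 to roughly 120 cells over a
28-hour window, the scale of the recordings) and an exponential death
waiting time; the earlier event wins. At a division, asymmetry is
Bernoulli with a type- and time-dependent probability: for outer mothers
a Gaussian bump in normalized age (default peak 0.25 at 0.82 n.a., width
0.08 n.a.), emulating a wave of outer-cell asymmetric divisions around
the 32- to 64-cell stages; for inner mothers either a constant (wild-type
preset, 0.08), a late-onset step (clone preset: none before 0.95 n.a.),
or a feedback controller. Death hazards are per cell-hour with bias
`beta = h_inner/h_outer`: 1 in the wild-type preset (0.004/0.004) and 4
in the clone preset (0.012/0.003), the clone preset also starting with 3
rather than 9 inner cells. Presets place wild-type windows at 62–90 h
with collapse near 81 h and clone windows at 72–101 h with collapse near
94 h, so the two groups overlap on a common normalized window of roughly
0.77–1.06 n.a. and clones run some 16% slower — the regime of the study
this emulates. Per-embryo collapse times are jittered (sd 2 h) so cohort
members develop at different paces.

On the **feedback mode**: an inner-cell asymmetric division replaces one
inner mother by one inner and one outer daughter — it leaves the inner
count unchanged and grows the outer pool, so it can only *lower* the
proportion of inner cells. A controller that raises inner asymmetry when
PIC is *below* target would therefore push PIC further down; regulation
toward a target requires the opposite sign. The implemented control
raises the inner asymmetric probability (to `p_inner_hi`) when PIC
exceeds the target and lowers it (to `p_inner_lo`) otherwise, which is
also the direction consistent with the observation that embryos starting
with few inner cells show scarce inner asymmetric divisions. The
regulation test asserts a cohort-mean final PIC within ±0.05 of the
target.

Geometry is phenomenological: outer cells sit on a sphere of radius
`R(t)` (55 µm at window start, growing 0.6 µm/h, scaled by
`(1 − 0.15)^(1/3)` at the scripted collapse so the hull volume drops 15%,
comfortably above the 10% detection threshold), inner cells at 0.45 R;
asymmetric divisions relocate the off-type daughter to the other
compartment. Positional noise is a persistent per-track offset (sd
1.5 µm) plus a small per-frame jitter (sd 0.4 µm): cells keep their place
in the epithelium between frames, and fully independent per-frame noise
would make the hull volume of small embryos fluctuate beyond the collapse
threshold, which curated volume series do not. There is no mechanics, no
cell-cell exclusion beyond jitter, no cavity model: sufficient for hull
volumes, shell classification and k-NN composition, and nothing else is
claimed. What passing tests on synthetic data do **not** show: robustness
to real detection noise (false/missed nuclei), to curation gaps, to
non-spherical embryo shapes, or to the imaging-axis anisotropy of real
microscopes.

Cohorts derive per-embryo seeds deterministically from the master seed,
so any table is reproducible from the run manifest.

## Numerical choices and degenerate inputs

Hull construction requires at least 4 non-coplanar points (5 for
classification); degenerate frames abort with the offending timestep
named. Facet-plane distances use unit normals with an epsilon of 1e-9
times the coordinate scale; sliver facets with undefined normals are
excluded from distance queries. Cycle lengths are floored at 2 frames and
death waits at 1 frame so events never precede births. Interpolation
refuses extrapolation rather than padding. The division-program replay
processes mothers in birth order, which is a topological order of the
tree, so every mother's identity is set before her daughters'.

## Problem sizes in the test suite

The suite runs the full pipeline on cohorts of 20 synthetic embryos for
exact ground-truth recovery, 50 random parameterizations for collapse
detection (plus 50 sub-threshold controls), 50-embryo clone cohorts
against a 500-replicate independent branching oracle for death-ratio
calibration, 50-embryo cohorts for recovery of a scripted
asymmetric-division bump, and 100 random lineages for the in silico
invariants — sizes chosen to keep Monte-Carlo standard errors small
relative to the tolerances tested while the whole suite completes in a
couple of minutes.

## Known limitations

* The import path expects the documented CSV dialect; externally
  deposited recordings may need a column-mapping adapter.
* The geometric inner/outer rule has one tunable (`shell_tolerance`);
  the published annotations were curated by hand, and the geometric
  fallback for mothers of asymmetric divisions is this package's rule.
* The normalized death ratio uses track-count exposure; an
  exposure-time-weighted variant would be the natural next step if track
  lifetimes differ strongly between types.
* The generator's asymmetric-division time profiles are free parameters
  emulating qualitative descriptions, not estimates fitted to data.
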