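---
title: "Models and methods behind woodyroot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind woodyroot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodyroot)
```

`woodyroot` implements a field-to-parameter pipeline for the root system
architecture (RSA) of woody perennials, built around grapevine rootstocks:
in-situ 3D-digitized point records are turned into topological root
systems and RSML, architectural traits and growth-model parameters are
extracted, genotype-specific root growth is simulated from a static
initial root system, and a water-flow model yields each root segment's
standard uptake fraction (SUF) and the whole-system conductance (Krs).
This vignette explains the models, the conventions and the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## Digitizer files, the ID dialect and the soil frame

A digitized root system arrives as plain text, one point per line:
`<dot-ID> <organ> <x> <y> <z>` in cm. The hierarchical dot IDs encode
topology: an axis's ID prefix is the full ID of the point on the parent
where it branches, and its own points append a 1-based running index
(axis `2.1.3` branches at point 3 of axis `2.1`). Every branch point is
digitized twice — once as a point of the parent, once as the first point
of the lateral — and the Euclidean distance between the two recordings is
itself a useful quantity: it measures operator error. `build_root_system()`
records these deviations, then snaps the lateral onto the parent. A
deviation above `merge_tolerance` (default 1 cm, comfortably above
observed operator error) warns but still merges, since large deviations
are data to inspect, not necessarily data to reject.

Because published descriptions of such digitizer exports do not pin down
a complete file grammar, the dialect above is normative for this package:
in particular it can encode at most one lateral per parent point, so the
fixture generator never places siblings on one node. Root types follow
hierarchy depth — stem 0, woody adventitious roots 1, first-order
laterals 2, everything deeper 3 ("fine roots") — capped at 3.

The digitizer's x axis points vertically downward (the transmitter hangs
above the pit), so coordinates are mapped to a right-handed soil frame
by `x_dig -> -z, y_dig -> x, z_dig -> y`, and the stem point recorded at
the soil horizon (ID "1" by default, overridable with a
`# soil_ref=<id>` header) is placed at the origin: z = 0 is the soil
surface and depth is `-z`.

## RSML

RSML encodes branch attachment by element nesting, so nesting depth
equals root type; the shared branch node is repeated as the child's
first polyline point. RSML has no stem concept, so the stem is written
as a top-level root carrying a `type=0` property — readers that ignore
the property still see a valid root system, while this package's reader
uses it to rebuild the full plant. Diameters are written per root (they
were measured per root with a caliper in the field protocol, not per
node), and per-node ages, when present, travel as an RSML `age`
function. Write-then-read is the identity on geometry, topology,
diameters and ages to floating-point tolerance, and the node set — hence
total root length — is preserved exactly.

## Traits

`compute_traits()` reports the standard field trait set. Choices worth
stating:

* Surface and volume use the per-axis radius (`2*pi*a*l`, `pi*a^2*l`),
  not frustums — matching how diameters are actually measured.
* Root system *width* is the maximum pairwise distance between
  horizontal projections of root nodes (the in-situ "lateral spread"
  sense); bounding-box extents are reported alongside for transparency.
* *Height* is max depth minus min depth of root nodes, clipped at the
  soil surface.
* The 3D convex hull volume is computed by an in-package incremental
  hull (validated against analytic solids and an independent
  implementation) and reported in m^3; planar hulls of the XY and XZ
  projections are in cm^2.
* The depth profile apportions each segment to depth bins by linear
  clipping at bin boundaries, so bin sums conserve total length exactly
  for any layer thickness. A point exactly on a boundary belongs to the
  deeper bin (half-open bins in depth).
* Insertion angles are reported in degrees. The angle is measured
  between the parent's local direction at the branch node (central
  difference, one-sided at the ends) and the lateral's first segment.

`estimate_lmax_r()` inverts the growth law (below): `lmax` defaults to
the observed per-type maximum (a quantile is available, since the
estimator is not uniquely determined by field practice), and `r` solves
"mean observed length = expected length at the observation age" by
bisection.

## The growth model

Roots elongate by the negative-exponential law

$$ l(t) = l_{max}\,(1 - e^{-r t / l_{max}}), $$

with genotype- and type-specific maximal length `lmax` (cm) and initial
elongation rate `r` (cm/d); both are treated as deterministic (no SDs
are attached to them in the presets). All other per-axis parameters —
insertion angle theta, radius a, and for type-2 roots the basal zone lb,
apical zone la and interlateral distances ln — are sampled once per axis
at emergence from normal distributions truncated to positive values
(resample-until-positive), which reproduces natural branch-to-branch
variability while avoiding negative lengths.

Simulation starts from a *static initial root system*: the stem and the
1-year-old woody adventitious roots (type 1) are copied verbatim and
never grow (they are persistent, effectively infinite-lifetime
structures), and every point where a type-2 root was present in the
source data becomes a lateral emergence point. All type-2 laterals
emerge at t = 0 with probability 1 by default — field observations show
their number does not increase between 3 and 6 months, so emergence is
an initial-phase event. Type-3 laterals follow the interlateral
schedule: positions `s_1 = lb`, `s_{k+1} = s_k + ln_k`, truncated at
`lmax - la`; lateral k activates when the parent's length first reaches
`s_k + la`. Type-3 roots carry no laterals themselves (no branching
parameters exist for them) and are fixed gravitropic.

Because the growth law has a closed-form inverse, each axis's polyline
is generated by exact arc-length stepping: segments of length `dx`
(default 0.5 cm; the final partial segment is kept), with per-node ages
from the inverse law. This makes the result independent of the
bookkeeping time step `dt` — a lateral activating "mid-step" simply gets
its exact activation time — and the emitted arc length matches the
growth law to 1e-6 cm by construction.

### Probabilistic tropism

From one segment to the next a root's heading changes by a random
angle `alpha ~ |N(0, sigma_eff)|` about a uniformly random azimuth,
with `sigma_eff = sigma * sqrt(dx)` (a length-scaled random walk, so
trajectories are resolution-independent). Tropism enters as random
optimization: `N` candidate headings are drawn and the one optimizing
the objective wins — gravitropism minimizes the heading's z component
(z negative is down, so the most downward candidate wins),
plagiotropism minimizes |z|, keeping growth near the horizontal plane.
`N` is the *tropism strength*; with `N = 1` there is no choice and with
`sigma = 0` every candidate equals the old heading, so roots grow
straight — two degenerate cases the tests pin down.

Field data show type-2 roots mixing both behaviours, so their objective
is chosen probabilistically. Two granularities are implemented:

* `per_segment` (default): before each segment a uniform draw decides
  the objective — gravitropic below the genotype threshold `p_gravi`
  (0.85 for "101-14"), plagiotropic otherwise. This is the literal
  segment-level mechanism; its long-run draw fraction converges to
  `p_gravi`.
* `per_root`: the draw happens once per root at emergence. This matches
  the way the probability is *estimated* from data — the fraction of
  long (> 40 cm) type-2 root tips remaining in the topsoil
  (depth < 50 cm) — because whole-root assignment produces the bimodal
  tip-depth distribution that estimator assumes. Under `per_segment`
  mixing, nearly every root eventually dives, and the tip-depth
  estimator is not a consistent estimator of `p_gravi`.

Both modes are exposed and tested; the closure (parameter-recovery)
test uses `per_root` for exactly this reason, while the draw-fraction
check runs in `per_segment` mode. A lateral's *first* segment always
uses the sampled insertion angle unchanged — tropism acts from the
second segment on — which keeps the insertion-angle estimator unbiased.

## Hydraulics

Theoretical axial conductivity of a cross-section follows the
Hagen-Poiseuille law adapted to elliptical conduits,

$$ K_h = \frac{\pi}{64\,\eta} \sum_i \frac{a_i^3 b_i^3}{a_i^2+b_i^2}, $$

with minor/major vessel diameters in metres and
`eta = 1.002e-9` MPa s (water at 20 °C); the circular limit reduces to
the classical `pi d^4 / (128 eta)`, which the tests assert for every
diameter. A power law `Kh = alpha * d^beta` links conductivity to root
diameter, fitted by Levenberg-Marquardt least squares initialized from
the log-log OLS line; the power-law form is the package's choice (it is
the standard allometry and fits the synthetic vessel data well), and the
solver interface only needs *some* monotone kx(d).

Water flow is solved on the segment network in the Doussan fashion: one
xylem-potential unknown per node; each segment contributes an axial
conductance `kx(d)/l` between its end nodes and a radial conductance
`kr(type, age) * 2 pi a l` from the soil, lumped half to each end node.
The symmetric lumping makes the discretization second-order accurate,
which is what lets a 2000-segment single root match the closed-form
conductance `sqrt(kx kr') tanh(L sqrt(kr'/kx))` (with `kr' = kr 2 pi a`)
to 1e-6 relative. Potentials are expressed as cm of head, so Krs emerges
in cm^3 cm^-1 d^-1; under the hydrostatic-equilibrium assumption the
soil total potential is uniform and gravity terms cancel. SUF is each
segment's share of total radial inflow and, by linearity, independent of
the imposed potentials; the depth aggregation reuses the trait module's
clipping rule, so refining the layer thickness never changes horizon
aggregates.

The shipped radial-conductivity table is a clearly-labelled synthetic
placeholder — three classes (unsuberized < 30 d, suberized, woody
type-1), orders of magnitude consistent with published grapevine
fine-root Lpr near 1e-7 m s^-1 MPa^-1 — because genotype-specific
measured values are not available; every value is overridable via
`hydraulic_params()` or its YAML config. Absolute Krs numbers from the
defaults are therefore order-of-magnitude context, not predictions.

## Accuracy metrics

Digitization accuracy uses a standard object with 5 cm and 10 cm
segments digitized at random poses: RMSE of digitized vs true lengths,
bias, and accuracy `1 - RMSE/L` per known length, optionally banded by
transmitter distance (< 100, 100-150, > 150 cm). Two bias definitions
circulate for this kind of calibration — the mean difference and a
difference of mean squares; the mean difference is the default here and
the squared variant is available via `as_typeset = TRUE`. Operator error
is summarized from the double-digitized branch points: mean Euclidean
deviation, band means, and the OLS trend of deviation on transmitter
distance with its R^2. `RMSE >= |bias|` always, with equality only for
constant error — a property the tests exercise.

## The synthetic-data generator

`synth_root_system()` closes the pipeline on itself: simulate a genotype
from a static template, down-sample each polyline to digitization-like
vertex density (vertices where the heading changes by more than 10
degrees, plus all branch points and endpoints — mimicking the field
protocol's point-placement rule), and emit the digitizer dialect with
double points, optionally degraded by a noise model (per-point jitter,
extra double-point jitter, and fine-root length loss emulating
excavation damage, which shortens type-3 roots but preserves their
count). The default static template has 8 adventitious roots of about
13 cm radiating from a basal node 20 cm below the surface — the planting
depth of the rooted cuttings — with type-2 emergence stubs marking where
laterals were observed.

What the closure tests show: parsing, topology reconstruction, RSML
round-trips, trait extraction and the parameter estimators are mutually
consistent, and the estimators recover the generating parameter means on
several hundred branches. What they cannot show: fidelity to real field
digitization (soil occlusion, electromagnetic distortion, operator
habits are not modelled), or the realism of the shipped kr table.

Two estimator expectations deserve a note, because they are properties
of the generative process, not bugs. First, resample-until-positive
sampling means the realized parameter means are those of the
positive-truncated normal, slightly above the nominal means — the
recovery tests compare against the truncated means. Second, the apical
zone estimator (tip to last branch) exceeds `la` by about `E[ln]/2` on
average, because a lateral is only visible once the parent has grown
past its position plus the apical zone; the recovery test includes this
censoring offset. The recovery run uses a long horizon (2000 d) so that
type-2 roots approach `lmax` and this censoring affects at most the last
interlateral gap.

## Problem sizes and numerical choices

Defaults and test scales, chosen once: `dx = 0.5` cm segment
resolution; `dt = 1` d (inert, see above); recovery tests use 40 type-2
roots yielding roughly 650 type-3 branches; the simulator-fidelity
checks average over 104 type-2 roots; the draw-fraction check uses 1e5
draws; the single-root conductance check uses 2000 segments, where the
second-order discretization error is below 1e-8 relative. Double-point
merging snaps to the parent's coordinates (the parent's recording is
taken as truth); hull degeneracy (< 4 non-coplanar points) yields volume
0 with a flag; bisection for `r` brackets (0, 10] cm/d with 1e-12
tolerance.

## Known limitations

No root mortality or turnover, no secondary thickening, no hydrotropism
or soil feedback, no shoot coupling; single-plant scenes only;
per-axis (not per-node) diameters; the tip-depth tropism estimator
assumes whole-root behavioural assignment; and absolute hydraulic
outputs depend on a placeholder kr table until measured conductivities
are supplied.
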