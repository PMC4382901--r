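---
title: "The BDML 0.2 data model in bdmlr: conventions, validation, and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The BDML 0.2 data model in bdmlr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmlr)
```

## The model

BDML (Biological Dynamics Markup Language, version 0.2) represents
quantitative spatiotemporal dynamics of biological objects — from single
molecules to cells to whole organisms — in one self-contained XML file with
six top-level elements in fixed order: `info` (a UUID identifier and
license), `ontology` (optional term mappings), `summary` (what was
measured, in which organism, whether by experiment or simulation),
`contact`, `methods` (URIs to the original sources and the processing
procedure) and a body that is exactly one of `data`, `series` or `set`.

The data body holds four kinds of declarations:

* **scaleUnit** — per-axis scale factors and unit names. Stored
  coordinates are raw values (typically pixels and frame indices); physical
  position is `stored * scale` in the named unit. `z_scale = 0` marks
  two-dimensional data. Units come from closed vocabularies (34 spatial /
  feature names including the imaging additions `micrometer`, `a.u.`
  (arbitrary unit) and `p.d.u.` (procedure-defined unit); 9 time units from
  nanosecond to year).
* **object** / **feature** — named object types and named scalar features
  (each feature with its own scale factor and unit), referenced by name
  from measurements.
* **component** — everything observed at one time point. Components must
  be *separated in time* (pairwise distinct time values) and may carry
  `prevID` backward links to components at strictly earlier times.
* **measurement** — one object's spatial record: an object reference, one
  geometric entity (point, polyline, circle, sphere, or triangular face),
  and optional feature values.

Two structural consequences drive the package design. First, because links
must point strictly backwards in time, the graph they induce is acyclic by
construction; `build_lineage()` only has to verify what the constructors
already guarantee. Tracks are maximal unbranched chains, a node with two or
more outgoing links is a division, two or more incoming links a fusion.
Track identity deliberately follows *neither* daughter across a division —
both daughters start fresh tracks — because any parent-assignment
convention (larger cell, anterior cell, first-listed) would be arbitrary at
this level of the format. Second, because every component owns a unique
time, "several objects at the same instant" must either share one component
(identity through object type names) or live in separate documents; both
layouts appear below.

## Constructors enforce invariants; the validator diagnoses breaches

Documents assembled through `new_document()`, `add_component()`,
`add_measurement()` etc. cannot violate the model invariants — duplicate
times, dangling references and malformed entities are rejected at
construction. Files arriving from elsewhere need diagnosis instead:
`read_bdml()` checks well-formedness and the shipped XML Schema
(structure: required elements, ordering, cardinality), and
`validate_bdml()` reports value-level breaches under 13 closed codes
(UUID-FORMAT, CONTACT-REQUIRED, UNIT-ENUM, SCALE-NEGATIVE, TIME-DUPLICATE,
PREV-UNKNOWN, PREV-FORWARD, OBJECT-UNKNOWN, FEATURE-UNKNOWN,
ONTOREF-UNKNOWN, ENTITY-MALFORMED, COMPONENT-EMPTY, BASEDON-ENUM). The
split of labour is deliberate: rules with dedicated codes are excluded from
the XSD (e.g. a component with no measurement passes the schema) so that a
single fault produces a single, named diagnostic rather than an opaque
schema message. All breaches are collected in one pass — no fail-fast — so
reports are stable objects.

Severity policy: every code is an error except `ONTOREF-UNKNOWN`, reported
as a warning. The ontology section is optional in BDML 0.2 and ontology
annotations are typically attached late, at database-registration time, so
a dangling term reference should not block data exchange. Similarly, in a
document known to be one part of a time-windowed series
(`validate_bdml(doc, series_part = TRUE)`), unresolved backward links
downgrade to warnings: a track may legitimately continue from the previous
file.

The validator's completeness is not asserted, it is *tested*:
`inject_violation(doc, code, seed)` mutates a valid document with exactly
one breach of the named kind (deterministically, given the seed) and the
test suite sweeps all 13 codes over a corpus of randomized documents,
requiring a 100% catch rate with the correct code. One subtlety: the
TIME-DUPLICATE mutation also clears the mutated component's own backward
links, since moving its time backwards could otherwise incidentally create
a forward link and break the one-fault contract.

## The XML dialect

The paper-level description of BDML leaves several serialization details
unprinted; this package fixes them and documents them as its own
conventions (they are also stated in the header of
`inst/extdata/bdml-0.2.xsd`):

* a point's coordinates are one whitespace-separated `(x, y, z)` triple in
  an `xyz` element; polylines and faces are flat `3n`-number lists in
  `xyzSequence`; circles and spheres use `center` + `radius` children;
* element casing follows the printed names (`bdmlID`, `scaleUnit`,
  `objectRef`, `prevID`, `componentID`, `featureVal`, …);
* encoding is UTF-8, indentation two spaces, and the element order is
  fixed, so writing the same document twice yields byte-identical output;
* every numeric value is rendered as the *shortest* decimal string that
  parses back to the identical double (try 1–17 significant digits, keep
  the first that round-trips). XML's decimal-ASCII representation is known
  to threaten precision; shortest-exact formatting removes that risk
  entirely, and the round-trip property `read(write(d)) == d` is tested at
  tolerance zero over hundreds of randomized documents;
* BDBase-style opaque annotations are supported as foreign-namespace
  elements after the body; they are preserved verbatim on read
  (`doc$annotations`) and re-emitted on write. Same-namespace unknown
  elements are rejected by the schema — within the 0.2 vocabulary the
  schema is strict, and forward compatibility is provided through the
  foreign-namespace channel.

## Geometry conventions

* **Radii under anisotropic scaling.** The format never says how a circle
  or sphere interacts with anisotropic voxel scales (common for confocal
  stacks, where the z-step exceeds the xy pixel size). A sphere scaled by
  `(0.105, 0.105, 0.5)` is an ellipsoid, which the entity vocabulary cannot
  express. `bdmlr` scales radii by `x_scale` and emits an
  `anisotropic-radius` warning whenever `x_scale != y_scale` (or
  `!= z_scale` for spheres). The alternative — a geometric-mean scale —
  would silently fabricate a volume no axis actually has.
* **Circles lie in the plane `z = center_z`**; the format stores no
  orientation for them.
* **Centroid** of a component is the unweighted mean of entity
  representative points (point → itself, line/face → vertex mean,
  circle/sphere → centre). This is a package convention, not part of the
  format; it is cross-checked against brute-force means in the tests.
* Degenerate inputs behave continuously: points have size 0, a collinear
  face has area 0, `measure_size()` is never negative, and
  `polyline_length()` is invariant under vertex-order reversal.
* `to_physical()` sets all scale factors to 1 after applying them, making
  it idempotent; feature values scale by their own `feature_scale`,
  mirroring coordinate handling (stored values are treated as raw).

## What the synthetic generators emulate — and what they do not

Each generator reproduces the *data shape* of one canonical use case, with
defaults chosen once as realistic study conditions; none of them is a
physically faithful simulation of the underlying biology.

* `gen_molecule_points()` — Brownian point molecules in a spherocylinder
  (cylinder 2 µm long, radius 0.5 µm — an *E. coli*-sized rod), reflective
  boundaries, per-axis step SD 10 nm/frame, coordinates stored directly in
  meters. 50 molecules × 20 frames by default. The planted law
  MSD = 3σ²t holds to within sampling error while steps are small relative
  to the cell; it says nothing about real membrane interactions, crowding
  or anomalous diffusion.
* `gen_dividing_nuclei()` — contours as closed polygonal chains
  (36 vertices) inscribed in circles that shrink 40% over each cell's
  life, radius ×0.75 per generation from 30 px, under the
  0.105 × 0.105 × 0.5 µm calibration. Real nuclear contours are neither
  circular nor flat in z.
* `gen_expression_spheres()` — nuclei as spheres under the 0.9 × 0.9 × 1.0
  µm calibration with a "GFP" feature in `a.u.`, planted as
  `10 + slope·t` plus Gaussian noise. Real GFP–histone dynamics are
  nonlinear and cell-cycle gated; the linear ramp exists so that
  least-squares recovery of the slope is a meaningful test with known
  sampling theory.
* `gen_pronucleus_microtubules()` — a sphere (radius 5 µm) on a planted
  linear drift path with line segments radiating from its surface, in
  meters. The `separate_components` layout emits *two documents bundled in
  a set* rather than two simultaneous components in one file: two
  components cannot share a time value, so a set is the only encoding of
  "separate components" consistent with the format's temporal rule. The
  forces that actually move a pronucleus are not modelled.
* `gen_worm_track2d()` — an open centerline of 50 vertices with constant
  5 px segment length (≈1 mm body at 4.1 µm/px), tangent angle undulating
  sinusoidally around a random-walk heading, phase advancing each frame.
  Arc length is constant *by construction* (every segment has fixed
  length), `z_scale = 0` and all z coordinates are 0. Real worms bend with
  variable local curvature and their tracked length fluctuates with
  segmentation noise.

**Division-tree encoding.** In the two division generators every
cell-frame is its own component, with time `frame + b/2^G` for branch `b`
of a `G`-generation tree: the sub-frame offsets keep all component times
unique (as the format requires) while letting the prevID links carry the
planted binary tree — a mother's last component links forward to both
daughters' first components. Putting all simultaneous nuclei into one
shared component per frame would respect the time rule too, but would
collapse every lineage to a single chain and make division recovery
impossible; the offsets are the one encoding that supports both.

Randomness: each generator call runs under its own seeded stream (R's
default Mersenne–Twister, saved and restored around the call), and the
document UUID is minted from the same stream — so identical parameters and
seed reproduce the serialized file byte for byte, and the generator
algorithm is documented well enough to reproduce the statistics (not the
bits) in another language.

What passing these tests shows — and does not show — about real data: the
suite demonstrates that the *format machinery* (serialization, validation,
conversion, lineage) is exact on data with known structure. It does not
validate any biological conclusion, and real files may exercise
combinations the generators do not (multi-entity measurements of mixed
kinds in one object, pathological unicode metadata, files larger than
memory).

## Problem sizes and numerical tolerances

The test suite and the acceptance script use desk-scale corpora, chosen so
a full run completes in well under a minute while keeping every statistical
check comfortably powered: 200 randomized documents for the round-trip
property (tolerance 0, byte-determinism on a 20-document subsample), 8 × 13
one-fault injections, 1000 random geometry oracles at relative tolerance
1e-9, 1000 molecules for the MSD law at 10% tolerance, and a 50-frame track
for slope recovery judged at three standard errors. Closed forms
(4π/3 for the unit sphere volume, perimeter 4 for the unit square, area 0.5
for the unit right triangle) are asserted at floating-point precision.

## Known limitations

* No binary/HDF5 payload support — BDML 0.2 is text-only; very large
  datasets should be split with `split_series()`.
* Ontology references are checked for resolvability inside the document,
  never against live ontology services.
* PDPML procedure descriptions are carried as opaque URIs.
* No perturbation metadata (mutants, RNAi, drugs) — outside the 0.2 schema.
* `lineage_newick()` refuses graphs with fusions (not trees); use
  `lineage_edges()` there.
* Whether `componentName` must be unique is unspecified; uniqueness is not
  enforced.
* Streaming parsing is out of scope; documents are read whole.
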