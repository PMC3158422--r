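---
title: "Steric shape quadrupole filters: model, construction and guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steric shape quadrupole filters: model, construction and guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapequad)
```

## The problem

Shape-based 3-D similarity search scores a pair of rigid conformers by the
shape Tanimoto,

$$ST = \frac{V_{AB}}{V_{AA} + V_{BB} - V_{AB}},$$

where $V_{AA}$ and $V_{BB}$ are the self-overlap volumes of the two shapes
and $V_{AB}$ is their common overlap volume *after superposition
optimization*. The superposition step — maximizing $V_{AB}$ over all rigid
motions — dominates the cost of large similarity searches. Most candidate
pairs, however, cannot possibly reach a useful threshold such as
$ST \ge 0.8$: their sizes or proportions are simply too different. This
package implements cheap, sound prefilters that remove such pairs using
only per-conformer descriptors, so the expensive optimization runs only on
pairs that might qualify.

## The shape model

Every heavy atom is a spherical Gaussian
$g_i(r) = p\,e^{-\alpha_i |r-c_i|^2}$ calibrated so its amplitude-weighted
integral equals the hard-sphere atomic volume,
$p(\pi/\alpha_i)^{3/2} = \tfrac{4}{3}\pi r_i^3$, with the conventional
amplitude $p = 2\sqrt{2}$ under which a single atom's self-overlap equals
its monopole volume exactly. Radii default to the Bondi van der Waals set
(carbon's 1.70 Å as the fallback for unlisted elements; fully
user-overridable), and hydrogens are excluded by default — the usual
heavy-atom convention for shape overlays; both choices are config flags
because the reference descriptor sets in public databases do not document
their exact radii or hydrogen policy.

From the summed density $\rho = \sum_i g_i$ the package computes three
volumes:

* **monopole volume** $V_{mp} = \int\rho\,dr = \sum_i \tfrac43\pi r_i^3$ —
  the zeroth moment of the shape expansion, conformation-independent;
* **self-overlap volume** $V_{so} = \int\rho^2 dr$ — the quantity used in
  the $ST$ denominator; it counts overlap regions multiply and typically
  exceeds the physical volume by a factor of 2–3 for bonded systems (the
  synthetic corpus averages $V_{so}/V_{an} \approx 2.7$);
* **analytic volume** $V_{an}$ — an inclusion–exclusion approximation to
  the hard-sphere union volume over Gaussian product integrals, truncated
  at third order with distance pruning at 1.2× the radius sum (validated
  against a 10⁷-point Monte-Carlo union-of-spheres oracle to within 3%).

The **steric quadrupoles** $(Q_x, Q_y, Q_z)$ are the eigenvalues of the
monopole-normalized second-moment tensor of $\rho$ about its centroid,
sorted $Q_x \ge Q_y \ge Q_z$; they behave as squared length, width and
height, and satisfy the exact identity $Q_x + Q_y + Q_z = R_g^2$ with
$R_g$ the radius of gyration of the shape density. Normalizing by the
monopole makes that identity exact and gives units of Å²; the
volume-scaled variant (×$V_{mp}$, units Å⁵, the scale used in the
public descriptor tables this design follows) is available via
`quad_scale = "volume"`. The per-atom second moment has the closed form
$V_i(c_ic_i^T + I/2\alpha_i)$, so no numerical integration is involved.
Degenerate eigenvalue ties are resolved deterministically: eigenvalues
sorted descending, the first two axes sign-fixed so their
largest-magnitude component is non-negative, the third axis their cross
product (det +1).

## Superposition

`optimize_superposition()` maximizes the closed-form Gaussian cross
overlap over a quaternion + translation parameterization by BFGS ascent
with analytic gradients, starting from the four proper principal-axes
alignments (centroids superposed; identity plus π flips about each
principal axis) — the standard shape-overlay start set. Convergence uses a
relative tolerance of $10^{-12}$ on the overlap volume with a 200-iteration
cap per start; hitting the cap is flagged, never raised. Optimization
quality is checked against an exhaustive 15°-step Euler-angle rotation
grid: the optimizer must reach at least 98% of the grid optimum on small
random pairs, and recovers $ST = 1$ for rigid copies to $10^{-6}$.

Because the cross overlap of Gaussian densities is an inner product,
Cauchy–Schwarz gives $V_{AB} \le \sqrt{V_{AA}V_{BB}}$ for *any* pose, so

$$ST \le \frac{s}{V_{AA}+V_{BB}-s}, \qquad s = \sqrt{V_{AA}V_{BB}}$$

is a provable upper bound from volumes alone (`st_volume_bound()`), used
as the first, zero-false-negative stage of the screening pipeline. (The
min/max-volume bound familiar from hard-sphere arguments is *not* sound
for this model; the Cauchy–Schwarz form is.)

## Quadrupole filters

The filters encode an empirical observation: two conformers that are
shape-neighbors ($ST \ge t$) can only differ so much in each quadrupole
component, and the tolerable difference depends on the two volumes.
Construction from a labeled neighbor-pair corpus:

1. **Binning.** Volumes and quadrupoles are integer-binned by truncation,
   `floor(value/binsize)`, with bin sizes 5.0 (volume; all of
   $V_{mp}/V_{so}/V_{an}$ can serve as the key, monopole by default) and
   2.5 / 0.5 / 0.1 for $Q_x/Q_y/Q_z$ — the components' spreads differ by
   roughly these ratios.
2. **Canonical ordering.** In each pair, molecule 1 is the one with the
   smaller volume bin; ties fall through smaller $Q_x$, then $Q_y$, then
   $Q_z$ bins, then input order. All differences are signed
   $\Delta Q = Q^{(2)} - Q^{(1)}$ after this ordering, and the same
   ordering is applied at lookup time, so filters are symmetric in their
   inputs while still capturing the asymmetry of the $\Delta Q$
   distribution.
3. **Accumulation.** Each neighbor pair contributes its
   $(V^{bin}_1, V^{bin}_2) \to \Delta Q^{bin}$ observation to a sparse
   map, per component.
4. **Fringe fill.** A finite corpus leaves ragged fringes: volume-bin keys
   between the populated extremes of a row or column that simply lack an
   example yet. Processing the unique $\Delta Q$ levels from the extreme
   toward zero (positive and negative branches separately, each level's
   region cumulative over all more extreme levels), the populated region
   is closed row-wise and column-wise. The filter stores, per key, the
   inclusive range $[\Delta Q_{min}, \Delta Q_{max}]$ of levels at which
   the key is present.

A pair passes a filter if its key's range contains its $\Delta Q$; keys
never seen in training follow the *unknown-key policy* — pass by default
(the filter only rejects pairs it has evidence against), or reject in the
strict mode used for efficiency experiments. The three filters are applied
as a cascade in x → y → z order ($Q_x$ is consistently the most
discriminating), short-circuiting at the first rejection; the cascade's
rejection set is exactly the union of the members'.

Two implementation choices deserve a note:

* The row/column closure is iterated to a fixed point at each level
  rather than applied once. A single row-then-column pass can leave a
  set that a second pass would still grow, so one-pass filling is not
  idempotent; iterating to closure preserves soundness (it only ever adds
  allowed territory), makes `fill_map()` idempotent, and makes the stored
  region genuinely closed in both directions.
* A key observed in only one signed branch takes its other endpoint from
  the branch level nearest zero. Since a zero difference is observed in
  any non-degenerate corpus, every built filter's range contains 0 — an
  identical-descriptor pair is never rejected.

### Guarantees and their limits

*Soundness on the training corpus is exact*: by construction every
observed $(key, \Delta Q)$ is allowed, so a filter never rejects a pair of
the corpus it was built from — the package asserts FN = 0 at every
threshold, and this is the property that makes the method safe to deploy
over a precomputed neighbor set.

*Generalization* to unseen pairs, by contrast, is an empirical matter that
depends on how densely the training corpus covers the key space. The
production-scale corpora this method was designed for contain billions of
neighbor pairs (~10⁷ observations per volume key); the synthetic study
corpus used here has 2,000 training pairs over ~270 keys. At that density,
held-out false negatives concentrate at keys whose handful of training
examples happened to miss a ±1-bin difference — near-identical conformers
whose descriptor lands on the far side of a bin edge. The held-out FN
count is therefore *reported*, not asserted, by the evaluation tests;
expect a few percent at this corpus size and essentially zero at database
scale.

The same sparsity inverts the threshold sweep under the default pass
policy: raising the threshold shrinks the trained key set, unknown keys
pass, and the rejected fraction *falls* — the opposite of the
production-scale trend, where efficiency grows almost linearly with the
threshold. Under the strict policy the trend is restored and is in fact
guaranteed: corpora restricted at nested thresholds give nested observed
maps, closure and fill preserve set inclusion, so the allowed set at a
higher threshold is contained in the allowed set at a lower one and the
rejected set can only grow. The threshold-sweep property test asserts
monotonicity in strict mode and prints the pass-mode fractions for
comparison.

For the workflow-level no-loss check (filtered and unfiltered neighbor
searches returning identical neighbor sets), the study conditions use a
search threshold of 0.95 with rigid-copy neighbors: at that threshold
incidental marginal neighbors — the sparse-coverage FN population — do
not occur, exact copies have $\Delta Q \equiv 0$ which every filter
admits, and the volume bound is provably sound, so the no-loss property
is structural rather than statistical. The saving is real: roughly 40% of
superposition optimizations are skipped on the synthetic corpora.

## The synthetic corpus generator

Filter construction and evaluation need labeled pair corpora; the
generator supplies them without external data. Conformers are grown by
sequential random placement: each atom at a bonded distance
(1.3–1.6 Å, uniform) from a random parent in a uniform random direction,
rejected on a hard-core clash closer than 0.8× the radius sum to any
non-parent atom (the parent is exempt — bonded distances are always inside
the hard-core radius of the partner). Elements are drawn from a
drug-like palette (C-rich, with N, O, S, F, Cl). Atom counts span 6–24 by
default, wide enough that volume bins overlap across the corpus —
otherwise the filters would never fire under the pass policy.

"Similar" pairs are a conformer plus a perturbed copy: isotropic
coordinate jitter of scale σ followed by a random rigid motion, so σ = 0
gives $ST = 1$ exactly and σ = 0.05 Å gives $ST \approx 0.99$. Torsional
resampling is deliberately not modeled — a pure shape method needs no
bond topology, and the jitter-plus-rigid-motion model spans the full ST
range with one knob. "Dissimilar" pairs are two independent conformers.
Every pair is labeled with the *optimizer's* ST, not a proxy, so ground
truth is internally consistent with the evaluation pipeline; train and
test corpora share no conformer ids.

What the generator does not emulate: real valence chemistry, torsional
correlation, aromatic flatness, and the empirical descriptor
distributions of real compound databases (its distributions are
qualitatively right — right-skewed, $Q_x$ spread ≫ $Q_z$ spread — but not
quantitatively matched). Passing tests therefore demonstrate the
correctness and internal guarantees of the machinery, not the absolute
efficiency figures one would measure over a real database.

## Problem sizes and tolerances

The reference study corpus is 2,000 training and 5,000 held-out pairs
(30% perturbation pairs at σ = 0.05 Å); every one of the 7,000 labels is
an optimized ST. Descriptor identities are asserted to 10⁻⁹–10⁻¹⁰
relative, rigid invariance to 10⁻⁸ over 100 random transforms, grid
quadrature agreement to 0.5% (0.1 Å spacing, 5 Å padding), Monte-Carlo
agreement to 3% (10⁷ points), rigid-copy recovery and superposition
symmetry to 10⁻⁶ in ST. Degenerate inputs are handled explicitly: empty
conformers and unknown elements (in strict radius mode) are errors, flat
2-D SDF records are skipped with a logged count, an empty training
restriction is an error in `build_filter_set()` but only a flagged row in
`threshold_sweep()`.

## File formats

Everything tabular is TSV with mandatory headers: descriptor tables
(`id n_atoms v_an v_mp v_so qx qy qz rg`, six significant digits), labeled
pair lists (`id1 id2 st`), verdict tables, and the `qfilter-1` filter
format — `#`-prefixed metadata (volume type, component, threshold, bin
sizes, rounding convention) followed by `v1bin v2bin dqmin dqmax` rows —
which round-trips byte-exactly. Structures travel as V2000 SDF, one
conformer per record, parsed with ChemmineR. The `shapequad` script under
`inst/cli/` exposes the workflow (`descriptors`, `simulate`,
`build-filter`, `apply-filter`, `evaluate`, `sweep`, `neighbor`) with a
YAML config file and per-flag overrides; every randomized command
requires an explicit `--seed`.

## A small worked example

```{r example}
set.seed(NULL)  # everything below is seeded explicitly
conf <- random_conformer(12, seed = 42, id = "mol1")
d <- shape_descriptors(conf)
d

copy <- perturb_conformer(conf, sigma = 0.05, seed = 7, id = "mol1b")
shape_tanimoto(conf, copy)

# a filter set from a tiny corpus, applied to one pair
corp <- build_corpus(corpus_spec(60, 40, seed = 11))
fs <- build_filter_set(corp$train, corp$descriptors, bin_config())
fs
apply_cascade(fs, d, shape_descriptors(copy))
```

## Known limitations

* Generalization FN at small corpus sizes, as analyzed above; the filters
  are meant to be built from large precomputed neighbor sets.
* The analytic volume is truncated at third-order intersections; for very
  dense atom clusters (not produced by the generator's hard-core rule)
  higher orders would matter.
* Feature/pharmacophore ("color") similarity, multi-conformer ensembles
  and alignment recycling are out of scope; the package scores pure
  steric shape for single conformers.
* The superposition optimizer is a local method from four deterministic
  starts; pathological shapes with many equivalent optima may need the
  optional seeded random restarts.
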