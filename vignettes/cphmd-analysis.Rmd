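---
title: "Analysing constant-pH MD titrations and H-bond networks with phtitra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing constant-pH MD titrations and H-bond networks with phtitra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phtitra)
```

## The problem

Constant-pH molecular dynamics (CpHMD) in the λ-dynamics formulation lets
every titratable side chain exchange protons with a pH bath during the
simulation: each site carries a continuous coordinate λ, with λ = 1 the
deprotonated and λ = 0 the protonated physical end state, and intermediate
values unphysical alchemical mixtures. Carboxylates and histidine have two
chemically distinct protonation sites, so a second coordinate χ describes
tautomer interconversion. An engine emits per-frame (λ, χ) series per
residue per simulated pH; everything downstream — pKa estimation,
pH-coupled hydrogen bonding, backbone flexibility — is post-processing,
which is what this package implements as a tested, reusable library.

## Titration model

### State classification

A frame is a **pure deprotonated** observation when λ ≥ 0.8 and the
tautomer coordinate is pure (absent, χ < 0.2, or χ > 0.8); **pure
protonated** when λ ≤ 0.2 under the same χ condition; everything else —
mid-band λ or mixed tautomer — is **discarded**. The four cutoffs live in
`state_cutoffs()` and are configurable, but the defaults are the
conventional bands and we recommend leaving them: widening the pure bands
admits alchemical mixtures into the counts, narrowing them discards
usable statistics. Classification enforces the partition
`n_deprot + n_prot + n_discarded = n_total` on every call, and malformed
records (λ outside [0, 1]) are rejected with residue/frame context rather
than silently clipped.

### Deprotonated fractions and the Hill fit

At each pH, `S = n_deprot / (n_deprot + n_prot)`; discarded frames never
enter the denominator. A pH window with no pure frames at all has an
undefined fraction: it is reported as `NA`, dropped from fitting with a
warning, and never interpolated. The titration curve is the generalized
Henderson–Hasselbalch (Hill) model

$$S(\mathrm{pH}) = \frac{1}{1 + 10^{\,n\,(\mathrm{p}K_a - \mathrm{pH})}},$$

strictly increasing in pH for Hill coefficient $n > 0$ and equal to 1/2 at
pH = pKa by construction — the package treats that identity as a contract
and the test suite asserts it to 1e−9 for every converged fit.

Numerical choices, in full:

* **Algorithm**: bounded least squares (L-BFGS-B) in (pKa, n), with
  n ∈ [10⁻³, 50] and pKa allowed 20 units beyond the grid so the bound
  never binds on realistic data. A two-parameter monotone logistic-type
  model needs nothing heavier.
* **Initialisation**: pKa starts at the pH of the point closest to
  S = 0.5 (grid midpoint if all points are extreme), n at 1. The surface
  is benign; this start converges in all our seeded recovery runs.
* **Stationarity check**: the optimizer occasionally reports a
  line-search failure when started at (or reaching) an exact optimum, as
  happens on noiseless input; the fit is accepted as converged when the
  numerical gradient of the residual sum of squares is below 10⁻⁶.
* **Degenerate titrations**: if every observed fraction is above 0.95 the
  midpoint lies below the simulated grid; the fit reports the grid edge as
  a one-sided bound (`ph_range_flag = "below_grid"`, `converged = FALSE`)
  and refuses to extrapolate a point estimate, symmetrically for fractions
  below 0.05. Outside the grid the two parameters are not jointly
  identifiable, and a confidently printed number there would be noise.
* **Weighting**: the fit is unweighted by default. pH points can carry
  very different pure-frame counts, so `weights = "counts"` weights each
  point by its number of pure observations; we default to unweighted
  because the per-pH sampling design (equal frames per pH) is the common
  case and unweighted fits are what most published titration analyses do.

### ΔpKa and charges

`pka_shift()` subtracts the residue type's reference pKa — the intrinsic
value in a short unstructured model pentapeptide — from the fitted pKa, so
an environment that stabilises the protonated form gives a positive shift.
The shipped defaults (Asp 4.0, Glu 4.4, His 6.5) are conventional model
compound values and deliberately editable (`reference_pka_table()`, YAML
accepted): reference sets differ between force-field parameterisations,
and the shift is only meaningful against the set used to calibrate the
engine. `interpolate_charges()` implements the linear λ-interpolation of
per-atom partial charges between the end-state charge sets; linearity (and
exact reproduction of the end states) is part of the test contract.

### Per-replica versus pooled fits

Replicas of the same pH can be fitted separately (fit each replica's
files, compare pKa spread — a convergence diagnostic) or pooled by
concatenating records before counting. Both are supported because neither
is canonical; pooling weights replicas by frame count, per-replica fitting
exposes between-replica variance. `cumulative_fraction_series()` provides
the running-S convergence diagnostic within one trajectory.

## H-bond networks

### Criteria and chemistry

An H-bond requires donor–acceptor heteroatom distance ≤ 3.5 Å (default,
configurable) and an angular criterion of 20° or 60°. The angle is
implemented as **deviation from donor–H···acceptor linearity**
(180° − ∠(D, H, A)): a perfectly linear bond scores 0°, and the criterion
admits bonds below the cutoff. This is the only geometrically sensible
reading — a literal sub-20° D–H–A angle would put the acceptor nearly on
top of the donor — and it makes 20° the strict and 60° the permissive
choice, with the 20° edge set provably nested in the 60° one (a tested
invariant).

Donor/acceptor resolution is rule-based (`donor_acceptor_table()`):
nitrogen and oxygen heavy atoms accept; those with a hydrogen within a
1.25 Å covalent cutoff in the same residue donate through each such
hydrogen. Water residues are recognised by name. This couples protonation
to H-bonding naturally: a modelled carboxyl hydrogen makes the hydroxyl
oxygen a donor, and `apply_protonation_states()` strips the titratable
hydrogens (Asp HD1/HD2, Glu HE1/HE2, His HD1) of residues declared
deprotonated before detection. When per-frame protonation trajectories are
not supplied, a fixed state per run is applied; frames with mid-band λ in
the source simulation should follow the rounded dominant state of their
residue, which is how the pipeline treats them.

### Bridges, occupancy, graph sets

A water bridge connects two protein groups through 1–3 mutually H-bonded
waters; every consecutive link must satisfy the criteria, in either
donation direction. The search walks the group–water and water–water
H-bond graphs to depth 3; because only the *minimal* water count per pair
is recorded and a pair either bridges in a frame or does not (path
multiplicity and water identity are ignored), matrix-product reachability
is exactly equivalent to exhaustive simple-path enumeration — the
acceptance suite verifies this against a brute-force enumerator on 50
random systems.

Occupancy is the percentage of analysed frames in which an interaction is
present. Nodes are residues — the granularity at which such networks are
usually drawn — with backbone/side-chain membership tracked per atom for
set selection, and edges are undirected (donation and acceptance are not
distinguished). Three graph sets are computed, each with a canonical
minimum-occupancy threshold per angle criterion:

| Set | Admits | 20° | 60° |
|---|---|---|---|
| 1 backbone_sidechain_water | backbone + side-chain direct bonds, water bridges | 10% | 50% |
| 2 sidechain_water | side-chain to side-chain, direct + bridged | 10% | 25% |
| 3 sidechain_direct | side-chain to side-chain, direct only | 10% | 15% |

A `graph_spec()` carrying a threshold inconsistent with this mapping is
rejected unless explicitly overridden; per-set occupancy is computed from
the per-frame records (a pair is present in a frame when *any* qualifying
interaction exists that frame), not by filtering the pooled summary, so
set-specific occupancies are exact. Multi-replica data may be concatenated
before occupancy (the default, weighting replicas by frame count) or
analysed per replica; the concatenation default matches how pooled-replica
network analyses are usually run. Frame subsampling is explicit
(`select_frames()`: first/last/stride), never hard-coded.

## Backbone conformation

### PAD

Backbone flexibility is summarised per residue by a circular dispersion of
the φ/ψ series — the package calls it PAD (per-residue angular
dispersion). With $\bar R$ the combined mean resultant length of the φ and
ψ unit-vector representations (per-angle resultant lengths combined in
quadrature, so an ensemble of identical conformations scores exactly
$\bar R = 1$),

$$\mathrm{PAD} = \frac{180}{\pi}\sqrt{-2\ln \bar R},$$

capped at 180°. It is 0 for a rigid residue, strictly positive for any
ensemble with two distinct conformations, monotone in injected noise, and
invariant to frame order and frame duplication — all tested. Several
variants of such dispersion measures exist (φ-only, ψ-only, other circular
spreads); the metric is therefore pluggable (`pad_profile(metric = ...)`)
and the package's guarantees are stated in terms of the invariants above,
not of any particular published profile. Resultant lengths within 10⁻¹²
of unity are treated as exactly 1 so rigid ensembles cannot acquire
spurious sub-microdegree dispersion from floating-point rounding.

### Helix assignment

A residue is helical in a frame when φ ∈ [−100°, −30°] and ψ ∈ [−67°, −7°]
— a standard α-basin window — and it belongs to a run of at least 4
consecutive in-window residues, since an isolated residue in the basin is
not a helix. Everything is configurable. This is deliberately a
dihedral-window method: it approximates, but is not, a
hydrogen-bond-pattern assignment such as STRIDE or DSSP, and contents
computed by the two families differ at helix termini. Chain-terminal
residues lack φ or ψ and are never assigned, so even an ideal helix caps
below 100% overall content while interior residues reach exactly 100%.

## Synthetic generators: what they emulate, and what not

`simulate_titration_records()` draws, at each pH, pure-state labels from
the Hill law at the true (pKa, n), λ uniformly inside the matching cutoff
band — not point masses, so the classifier's boundaries are genuinely
exercised — and χ near 0 or 1. Configurable fractions of mid-band-λ and
mixed-χ frames are injected with exact bookkeeping, which is what the
filter-audit tests reconcile against the classifier. Draws are independent
by default; an optional two-state Markov mode (resample with probability
`markov_flip`, keep otherwise) produces autocorrelated series with the
same stationary law to stress convergence diagnostics. What it does *not*
emulate: λ inertia within the mid band, χ–λ coupling, replica-exchange
artefacts, or force-field-dependent tautomer preferences. Passing
parameter recovery on this generator therefore demonstrates the estimator
chain is correct and unbiased under the sampling law — not that any given
simulation is converged.

`build_toy_ensemble()` grows backbones from ideal helix dihedrals
(φ = −57°, ψ = −47°; extended values outside the span) with ideal bond
geometry and per-frame Gaussian dihedral noise, then realises engineered
contacts: a donor hydroxyl, an optional 1–3-water chain, and an acceptor
oxygen placed collinearly at 2.9 Å spacing (ideal H-bond geometry) in the
Bernoulli-chosen "on" frames, stretched to 4.5 Å spacing — beyond the
distance cutoff — in "off" frames. Contact assemblies are laid out with
clearance from the backbone and from each other, so the recovered edge set
is exactly the engineered one plus the backbone's own helical H-bonds.
The realized occupancies are recorded per contact. These ensembles are
geometric fixtures, not physical structures: side chains are minimal,
contacts are detached from the backbone, and no solvent beyond the bridge
waters exists.

Test and validation problem sizes are part of the package's design:
parameter recovery uses 20 seeded datasets (truths cycled over
pKa ∈ {3.5, 4.5, 6.5} × n ∈ {0.8, 1.0, 1.2}) at 10,000 draws per pH on the
grid 3–7, which bounds the mean absolute pKa error at 0.1 and the Hill
error at 0.15 with comfortable margin; the graph oracle runs 50 random
systems of up to 12 groups and 15 waters, small enough for exhaustive
enumeration yet large enough to produce multi-water bridges; threshold
behaviour uses 2,000-frame ensembles where binomial fluctuation of a 50%
contact is ±3 percentage points at 3σ.

## File formats and determinism

Titration records travel in a header-bearing tab-separated dialect
(`# pH<TAB>value`, then `frame / residue_id / lambda / chi`, `NA` for
absent χ) — engines differ in native formats, and this is the package's
engine-agnostic interchange, trivially produced by converters. Structures
use multi-model PDB (read via bio3d with alternate locations resolved to
highest occupancy; written by a fixed-width emitter at the format's
3-decimal coordinate precision). All writers are deterministic given
inputs; `run_pipeline()` emits a manifest without timestamps so identical
configuration and inputs give byte-identical output trees. Reported
distances round half-up to one decimal, matching how such distances are
conventionally quoted (round-half-even would print 2.75 Å as 2.7).

## Known limitations

* The Hill fit assumes a single two-state site per residue; coupled sites
  or tautomer-specific pKa decomposition are out of scope.
* Energetic or orbital H-bond scoring, π and C–H···O interactions are not
  detected; the criteria are purely geometric.
* Helix content is dihedral-window based (see above); β and turn classes
  are not assigned.
* The donor/acceptor rules rely on modelled hydrogens; structures without
  hydrogens must be protonated upstream.
* Occupancies from pooled replicas with unequal frame counts weight
  replicas proportionally to length; use per-replica mode when that is not
  wanted.
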