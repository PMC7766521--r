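---
title: "Deuteration and receptor binding: models and methods in deutbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deuteration and receptor binding: models and methods in deutbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deutbind)
```

## The problem

Replacing exchangeable protons (those bonded to N, O or S) by deuterium
changes hydrogen-bond strengths: the X–D bond is more compact than X–H,
which lengthens the donor–acceptor heteroatom separation (the Ubbelohde
effect) and thereby modulates every interaction the bond participates in.
For a ligand such as histamine binding to its H~2~ receptor, deuteration
acts on two competing environments — the aqueous solution the ligand leaves
and the binding site it enters — so the net effect on affinity is a small
difference of two large numbers and has to be bookkept carefully.

`deutbind` implements the analysis layer of such a study: trajectory
analytics (conformers, hydration structure, hydrogen-bond occupancies), the
empirical deuteration geometry transform, binding-site cluster and solvent
shell extraction, and the H/D thermodynamic cycle with affinity-unit
conversions. Molecular dynamics and quantum chemistry engines are
deliberately out of scope; their outputs (trajectories, per-residue
decompositions, component electronic energies) are *inputs* here, and a
synthetic-data module generates statistically controlled stand-ins so every
stage is testable on a desk.

## The thermodynamic cycle

For each isotope state (H, D) the binding energy is assembled from a
hydration leg and a receptor-interaction leg,

$$\Delta E_\mathrm{BIND} = \Delta E_\mathrm{INTER} - \Delta E_\mathrm{HYDR},$$

and deuteration-induced changes are D-minus-H differences,
$\Delta\Delta E_X = \Delta E_X(\mathrm{D}) - \Delta E_X(\mathrm{H})$, so

$$\Delta\Delta E_\mathrm{BIND} = \Delta\Delta E_\mathrm{INTER} -
  \Delta\Delta E_\mathrm{HYDR}.$$

A negative $\Delta\Delta E_\mathrm{BIND}$ means deuteration strengthens
binding. We fixed the D-minus-H direction as the canonical internal form
because it makes every reported component difference carry its natural
sign; printed summaries round to two decimals only at report time.

```{r cycle}
cy <- read_cycle_components(system.file("extdata", "cycle_components.tsv",
                                        package = "deutbind"))
cy
```

Affinity conversions use $\Delta G = -RT\ln(10)\,\mathrm{p}K_i$ and the
relative Cheng–Prusoff form
$\Delta\Delta G = -RT\ln(10)\,\Delta\mathrm{pIC_{50}}$ with
$R = 1.98720425\times10^{-3}$ kcal mol^-1^ K^-1^ and $T = 298.15$ K by
default; this temperature reproduces both published conversions at their
printed precision (300 K would shift the pIC~50~ conversion by 0.01
kcal mol^-1^). Ligand speciation uses an independent-site protonation
model: the monocation fraction is the product of the probability that the
aliphatic amine (p$K_a$ 9.7) is protonated and the ring imidazole
(p$K_a$ 6.0) is neutral. The model treats the two sites as uncoupled,
which is adequate at physiological pH where both factors are near
saturation.

```{r affinity}
signif(dg_from_pki(4.3), 2)
round(ddg_from_pic50(7.25, 7.80), 2)
round(100 * monocation_fraction(7.4, 6.0, 9.7))
```

## The empirical deuteration transform

Nuclear quantum effects of H→D substitution are emulated geometrically:
every exchangeable X–H bond is contracted by a fixed fraction (default
0.023, following neutron-diffraction evidence that deuteration reduces the
attraction in acidic N–D bonds by 2.3%) by moving the hydrogen along the
X→H direction; heavy atoms never move, and a constraint list
(atom pair + frozen length) is emitted for any downstream engine that
re-optimizes the remaining degrees of freedom. The transform composes
multiplicatively — applying fractions $f_1$ then $f_2$ equals one
application of $1-(1-f_1)(1-f_2)$ — which the tests assert to $10^{-9}$ Å.
We apply the contraction once, from the protiated geometry; iterating it
against re-optimization cycles is an engine-side concern.

"Exchangeable" is operationalized as: every hydrogen within 1.2 Å of an
N, O or S heavy atom, paired to its nearest such atom. An exact tie between
two candidate donors is treated as malformed input rather than broken
arbitrarily. One consequence of the 1.2 Å detection default is that the
cysteine S–H stub in the synthetic pocket is built at 1.15 Å (a physical
S–H bond is ~1.34 Å); with a physical stub the S–H bond would not register
under the default rule.

## Synthetic systems: what they emulate and what they do not

The generators reproduce the *statistical* structure of the study systems,
not their physics:

* `build_histamine()` constructs an idealized histamine monocation
  (planar imidazole ring, standard bond lengths, 18 atoms when protonated)
  with the ethylamino torsion CG–CB–CA–N2 set exactly. The ring–CB rotamer
  is fixed at χ1 = −60° so that a requested torsion of 62.1° yields a
  N1–N2 distance of 3.0 Å and 158.8° yields 4.4 Å — the same gauche/trans
  regimes as the published representative structures (3.01/4.54 Å; exact
  values are template-dependent).
* `solvate()` packs rigid 3-site waters (O–H 0.9572 Å, H–O–H 104.52°, the
  standard rigid-water geometry) uniformly into a droplet or box with a
  2.4 Å heavy-atom clash exclusion, after satisfying pinned contacts
  exactly on a donor-H direction of the named site.
* `synth_trajectory()` draws frames i.i.d.: a conformer state per frame
  (gauche torsions uniform in 40–90°, trans in 140–180°, straddling the
  62.1°/158.8° representatives), Bernoulli contact schedules at the
  requested marginal occupancy (bonded contacts placed at 2.8 Å on the
  donor-H axis, broken at 5.0 Å), then Gaussian jitter on all atoms.
  Frames are i.i.d. by design — the estimators in scope are marginal
  statistics, so autocorrelation is deliberately absent. Nothing here has
  a Boltzmann weight; passing recovery tests shows the estimators are
  unbiased on data with known truth, not that the generator mimics real
  solvation dynamics.
* `make_pocket_complex()` arranges 16 residue stubs (minimal backbone plus
  functional side-chain atoms) so that the designed anchor geometry holds
  exactly: one Asp98 carboxylate oxygen accepts from the ligand ammonium
  at 2.8 Å, Tyr250's hydroxyl donates to the other carboxylate oxygen, and
  Thr190's hydroxyl donates to the Asp186 backbone carbonyl at 2.76 Å. It
  is a synthetic fixture, not a homology model.

The default `jitter_sigma` is 0.01 Å. The choice is an error-budget
decision made before any statistics were collected: the gauche sampling
window ends exactly at the classification boundary (90°), so Cartesian
jitter must contribute far less than a degree of torsion noise for
label-vs-drawn-state recovery to reflect sampling error rather than
boundary chatter. At 0.01 Å the torsion noise is a fraction of a degree
and misclassification against the generator's own state log stays below
one percent.

One global integer seed drives every stochastic draw (via a single seeded
generator whose state is saved and restored around each call), so all
generators are bit-reproducible given (spec, seed).

## Conformer analytics

Classification uses two internal coordinates — the N1–N2 distance and the
side-chain torsion — and only the torsion magnitude, making it invariant
to the dihedral sign convention. The bands are |φ| ≤ 90° (gauche),
|φ| ≥ 120° (trans), and an explicit intermediate band between them rather
than a forced binary, because trajectories genuinely contain mixed
structures with and without the internal N2–H···N1 contact; both
thresholds are configuration-exposed. The torsion is measured over the
heavy-atom quadruple CG–CB–CA–N2 (ring attachment carbon to amine
nitrogen), the natural "rotation of the ethylamino group" once one asks
for a torsion whose representative values match the published 62.1°/158.8°
magnitudes.

Populations are exact counts with Wilson 95% intervals (bounded and
well-behaved at extreme fractions, unlike the Wald interval).
Representative frames come from k-medoids clustering in
(|φ|, d~N1N2~) space — medoids, unlike k-means centroids, are actual
frames one can extract and depict. The metric treats the torsion axis with
circular angular distance and scales both axes by their sample standard
deviation. Initialization is deterministic (global medoid, then
farthest-point additions) and medoid updates break ties toward the lowest
frame index, so results are bit-reproducible; the `seed` argument exists
for interface stability only. The implementation materializes the full
pairwise distance matrix, so clustering is intended for series up to a few
thousand frames.

## Hydration analytics

`compute_rdf()` normalizes a pair-distance histogram by
$n_\mathrm{valid}\,\rho\,V_\mathrm{shell}$ so the ideal-gas limit is 1.
Because the systems are finite and non-periodic, a center contributes to a
distance bin only when the entire spherical shell around it fits inside
the analysis region (per-bin valid-center exclusion). This is exact — no
truncated-shell volume approximations — at the cost of discarding
near-boundary centers at large r; bins with no valid center are `NA`.
Region volumes are analytic for boxes and spheres; when no region is
given, a droplet envelope (union of 3 Å spheres around the target atoms)
is volume-estimated by seeded Monte Carlo with 10^5^ samples and
summarized as an effective sphere for the boundary bookkeeping — an
approximation appropriate for blob-shaped droplets only. Defaults:
dr = 0.05 Å, r~max~ = 10 Å.

Coordination numbers integrate $\rho\,g(r)\,4\pi r^2$ by the trapezoid
rule on bin midpoints, which the tests check against direct neighbor
enumeration (agreement within 2%) and against the $\tfrac43\pi\rho r^3$
closed form on uniform gases.

Hydrogen bonds use the common geometric convention — donor–acceptor
distance ≤ 3.5 Å and D–H···A angle ≥ 135°, both boundaries inclusive and
both configuration-exposed. The published analysis states no criteria;
these defaults are consistent with the reported 2.8–3.0 Å first-shell
peaks. Occupancy is the bonded-frame fraction per (donor heavy atom,
acceptor) pair, counting a pair once per frame even when two hydrogens of
the same donor qualify; per-donor simultaneous counts average over all
frames including unbonded ones.

## The surrogate interaction score

`surrogate_energy()` exists so the end-to-end pipeline has a computable
stand-in where a study would insert engine energies: the sum over detected
hydrogen bonds of a Gaussian well $-5\exp(-((d-2.9)/0.3)^2)$ kcal mol^-1^.
The well is evaluated at the effective separation
$d = d(\mathrm{D,A}) + (\ell_\mathrm{ref} - d(\mathrm{D,H}))$ with
reference X–H lengths matching the generators (N 1.01, O 0.96, S 1.15 Å):
at reference geometry the correction vanishes and the well is the plain
heavy-atom-distance well, while a contracted (deuterated) donor bond acts
as an elongated effective heteroatom separation — the Ubbelohde response
the surrogate is meant to exhibit. A well on the heavy-atom distance alone
would be exactly invariant under the deuteration transform (the hydrogen
moves along the bond axis; heavy atoms do not), which would make the
surrogate blind to the very effect under study. The score is a geometric
device internal to this package; pipeline reports label it as a surrogate
and it is never a substitute for the component energies consumed by the
cycle.

## Decomposition bookkeeping

Per-residue MM-GBSA-style tables are consumed as delimited text with the
total binding free energy carried alongside. Filtering is inclusive on
both thresholds (favorable ≤ −0.06, unfavorable ≥ +0.02 kcal mol^-1^)
because published tables contain rows at exactly those values; the sign
gap between the thresholds guarantees the partitions are disjoint.
Percentages are of the signed total, so a favorable residue's share of a
favorable total is positive.

## Numerical conventions

* Coordinates are always Å, angles always degrees; atom indices are
  1-based throughout (R's native indexing; PDB serials are 1-based
  anyway).
* Dihedrals are signed, in (−180°, 180°], cis = 0, matching the standard
  convention implemented by bio3d and Biopython; the suite cross-checks
  random geometries against bio3d to 10^-9^ degrees. Classification uses
  |φ| and is convention-independent.
* Degenerate geometry (coincident atoms, collinear torsion axes,
  zero-length bonds) raises errors rather than returning NaN.
* PDB I/O delegates to bio3d (wwPDB fixed columns, three-decimal
  coordinates, occupancy/B-factor written as 1.00/0.00 and ignored on
  read); XYZ is parsed in-package. Round-trips are exact to 10^-3^ Å for
  PDB.
* Exact rank ties in water-shell selection resolve toward the lower
  residue number; fewer in-cutoff waters than requested returns all of
  them with a warning flag rather than failing.

## Problem sizes

The bundled demonstration pipeline and the test suite run at desk scale by
choice: droplets of tens of waters, trajectories of 300–800 frames for
module tests and 2000–5000 frames for the statistical recovery checks,
uniform-gas RDF fixtures of ~10^3^ particles over a handful of frames.
These sizes put the binomial sampling bands well inside the tolerances
being asserted while keeping the whole suite in the tens of seconds.

## Known limitations

* No periodic boundary conditions, unit cells or velocities; the RDF edge
  handling assumes a convex analysis region.
* The i.i.d. frame model cannot test estimators of dynamical quantities
  (lifetimes, autocorrelation, reweighting) — these are out of scope.
* The element heuristic covers organic/biomolecular atoms, not metals.
* The pocket fixture's stub residues have designed, not physical,
  side-chain geometry; only the anchor contacts are meaningful.
* The speciation model ignores site–site coupling and tautomer
  equilibria within the neutral ring.
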