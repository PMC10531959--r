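---
title: "Determining fragment binding poses from semi-ambiguous methyl distance restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining fragment binding poses from semi-ambiguous methyl distance restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmr2dock)
```

## The problem

Protein–fragment complex structures are usually solved by X-ray
crystallography, but weakly binding fragments often resist
co-crystallization and soaking. Intermolecular NOEs offer a solution-state
alternative: cross-peak intensities between assigned ligand protons and
receptor methyl groups encode distances up to roughly 6 Å. The catch is
that assigning the receptor methyls requires weeks of NMR work, so the
restraints are recorded *semi-ambiguously*: the ligand side of every
restraint is assigned, while the protein methyls are anonymous labels
`M_n`.

`nmr2dock` implements the molecular-replacement-style answer to this
problem. Given a network of proton-to-anonymous-methyl distance bounds,
the coordinates of the candidate methyl carbons, and a rigid ligand
conformer, it:

1. enumerates every injective mapping of anonymous labels onto methyl
   sites that is consistent with the available partial assignment;
2. optimizes a rigid-body ligand pose against the distance bounds for
   each mapping;
3. ranks all calculated structures by a violation target function; and
4. validates the best-ranked pose through the *target function contrast*
   (TFC) with the first structurally distinct alternative.

## The target function

For a pose $(R, t)$ and an assignment $a$, each restraint contributes a
squared bound violation:

$$v_i = \max\!\big(0,\; d_i - u_i - s,\; \ell_i - s - d_i\big), \qquad
\mathrm{tf} = \sum_i v_i^2 \; + \; w_\mathrm{clash} \sum_{jk}
\max(0,\, 2.8\,\text{Å} - r_{jk})^2$$

where $d_i$ is the distance from the posed ligand proton to the assigned
methyl carbon, $(\ell_i, u_i)$ are the lower/upper limits, $s$ is an
optional per-restraint slack, and the second sum is a soft-sphere clash
penalty over ligand–receptor heavy-atom pairs. Distances are measured to
the methyl *carbon*; this is the convention that the customary 0.7 Å
markup on proton–proton NOE distances accounts for.

Two conventions matter:

* **Tolerance** is multiplicative and symmetric: a 10% tolerance sets
  $u = 1.1\,d$ and $\ell = 0.9\,d$. Mean restraint distances are the
  natural normalizer for ligand dimensions precisely because absolute
  slop grows with $d$.
* **`methyl_slack` defaults to 0.** A non-zero slack is meant to absorb
  sub-Ångström methyl-carbon movement from side-chain torsions when
  fitting *experimental* networks. Because the slack acts independently
  per restraint, however, it also relaxes the discrimination between
  assignments: with 0.5 Å slack, wrong assignments of an exact in-silico
  network routinely become exactly satisfiable and validation loses all
  contrast. In-silico benchmarks are exactly realizable, so the default
  is zero; set a small positive value only for experimental data.

## Validation: the target function contrast

All calculated structures — several refined poses per assignment, not
just the winner — are ranked by tf. The TFC is the tf difference between
the best structure and the first one whose heavy-atom rmsd from it
exceeds 2 Å (computed in the fixed receptor frame, without
re-superposition, because superposing would erase exactly the
binding-mode difference being measured). A result is validated when
TFC > 0.2 Å².

Retaining several poses per assignment is essential: at large tolerances
the dominant failure mode is pose ambiguity *within* the correct
assignment — displaced poses that satisfy every widened bound. A ranking
that kept only each assignment's best pose would overstate the contrast
and validate unresolved results.

Success against a reference structure additionally requires heavy-atom
rmsd below 2 Å and a matching fragment orientation. The orientation test
is an automated stand-in for a visual overlay inspection: the ligand
principal axes of the two poses (signs fixed by atom correspondence) must
agree to within 90°.

When no ranked structure is structurally distinct from the best one, the
TFC is reported as `Inf` with a loud warning. This only happens when
feasibility pruning removed every competitor, which is why the full run
(`run_nmr2()`) optimizes all combinations by default and uses pruning
only as an optional accelerator (it provably never changes the optimum).

## Ligand topology parameters

The apparent ligand dimensions are computed over the *active* protons
(those carrying at least one restraint): `L_length` is the maximal
proton–proton distance, `L_width` the largest pair-vector component
orthogonal to the length direction, both by exhaustive pair scan (ties on
the length are broken toward the lexicographically smallest proton-id
pair). Normalizing by the mean restraint distance gives

$$r_l = L_\mathrm{length} / \langle d \rangle, \qquad
  r_w = L_\mathrm{width} / \langle d \rangle ,$$

with $\langle d \rangle$ the mean of the central distances before
tolerance. Empirically, calculations mostly fail when $r_l + r_w < 2$ and
mostly succeed above it; the benchmark library is stratified around that
boundary. Because the parameters use active protons, deleting restraints
shrinks the apparent topology — which is exactly how sparse data degrades
convergence.

Binding-site suitability is summarized by `site_diagnostics()`: at least
three methyl-bearing residues are needed, and they must not all lie in
one half-space through the ligand centroid (`one_sided`, tested by a
Frank–Wolfe minimum-norm-point computation over the unit direction
vectors). A `spread_score` (ratio of smallest to largest singular value
of the centered methyl coordinates) quantifies how isotropic the beacon
constellation is. The optional `pocket_ligand_ratio()` compares effective
ellipsoid volumes of pocket and ligand heavy atoms; it is an approximate
diagnostic only.

## The engine

Pose optimization per assignment runs multi-start simulated annealing
over the six rigid-body degrees of freedom (default 6 restarts × 1500
steps, geometric cooling 0.996, initial temperature from the median tf of
random poses), with each restart's best pose refined by an
analytic-gradient Armijo descent; the overall best pose receives a final
Nelder–Mead polish. Pure annealing is not sufficient here: with exact
restraints the feasible set is essentially a point inside a search sphere
of ~10–13 Å radius, and the hinge-squared target is C¹ with an
inexpensive analytic gradient, so annealing finds the basin and descent
finishes the job. One restart is seeded from a trilateration estimate:
each proton carrying at least four restraints is located by linearized
sphere intersection, and the conformer is Kabsch-fitted onto the
estimates.

The search sphere is centered on the methyl centroid with radius
`max(site–centroid distance) + L_length/2 + 2 Å`. Every random draw
derives from the configuration seed and a hash of the assignment's site
indices, so results are bit-reproducible and independent of enumeration
order; assignments whose tf remains above `abandon_tf` (default 15 Å²)
after two restarts are not refined further, as they are far outside
contention for either the ranking or the contrast.

Feasibility pruning cuts assignment prefixes in which two placed labels
restrain a common proton but their site separation exceeds the sum of the
upper bounds (or falls below the largest lower-minus-upper difference).
This removes only provably infeasible branches; a property test checks
that the optimum is identical with pruning on and off.

## What the synthetic benchmark emulates

Every case is generated from a seed and consists of a binding site
(methyl "beacons" plus a sparse receptor heavy-atom shell), a rigid
planar ligand, a ground-truth pose, and the restraint network measured
from it. Design choices, and why:

* **Beacon constellations are irregular.** Directions start from a
  spherical spiral but receive per-point angular jitter, and each residue
  sits at its own radial depth (0.85–1.25 × the nominal 6 Å radius).
  Regular layouts are exactly C2-symmetric, and metrically uniform shells
  make permuted assignments almost as satisfiable as the true one —
  symmetric information is precisely what the method cannot resolve, so
  leaving the symmetry in would test the wrong thing. Valine, leucine and
  isoleucine contribute two methyl carbons ~2.5 Å apart.
* **Ligands are planar.** Fragment libraries are dominated by aromatic
  and heteroaromatic scaffolds. Planarity makes the ligand achiral, so a
  flip across a *coplanar* beacon constellation is an exact pose
  degeneracy — this is the mechanism behind the one-sided-site failures,
  and it only exists if the generator respects it. The in-plane proton
  pattern is deliberately asymmetric (the width pair is skewed along the
  length axis), so no spurious in-plane mirror degeneracy is introduced.
  The realized length/width match their targets within 5%.
* **Restraints use a 7 Å carbon cutoff** (≈6 Å proton NOE range plus the
  0.7 Å carbon markup). Placements are redrawn until the network has at
  least 12 restraints (the working floor for fragments), no proton–carbon
  contact below 2.5 Å, and an exactly clash-free truth pose; the mean
  generated restraint distance (~5.2 Å) sits at the literature's median.
* **Buried pockets are molded around the ligand.** For well-spread
  ("suitable") sites, wall pseudo-atoms are placed at `pocket_offset`
  (default 3.4 Å, van der Waals contact) from the posed ligand's heavy
  atoms, leaving one ~50° opening toward the largest angular gap in the
  beacon constellation. Real fragment pockets wrap their ligand
  (pocket/ligand size ratios near 2), and this steric confinement is what
  excludes displaced poses once tolerance widens the bounds. The
  benchmark library emulates the reported spread of pocket/ligand ratios
  by using a roomy 5.2 Å offset for its compact fragments and the snug
  3.4 Å for its elongated ones. One-sided and collinear sites get no
  mold — they model shallow surface patches, which is why they cannot pin
  down a pose.
* **Partial assignment is emulated truthfully**: a selected label learns
  exactly what auxiliary experiments would reveal about its true site —
  methionine/alanine/threonine typed exactly, valine/leucine/isoleucine
  constrained to that group, and same-residue pairs linked when both
  methyls of a two-methyl residue are selected. Misleading constraints
  are never generated.
* **One master seed fans out** to per-case seeds through a documented
  splitting rule, so any case regenerates in isolation and library
  manifests are byte-identical across runs.

What passing tests on this generator do *not* show about real data:
receptor flexibility (methyls move), spin diffusion and exchange
averaging in the NOE-to-distance conversion, non-rigid ligands, and the
full steric texture of a protein pocket are all outside the model. The
benchmark demonstrates the combinatorial and geometric core of the
method — assignment resolution, tolerance degradation, partial-assignment
uplift, topology dependence — under controlled conditions, not
performance on experimental spectra.

## Benchmark protocol and problem sizes

`run_benchmark()` mirrors the five standard conditions (exact restraints;
10% and 20% tolerance, each without and with partial assignment) over a
library of cases, and `aggregate_report()` reports per-condition success
rates, rmsd and TFC statistics both over all cases and over the
population that validates under every condition, so conditions can be
compared on a common footing. The default problem sizes — 10–20 cases of
5 methyl residues (≤6 methyl sites, ≤720 assignment combinations each),
5–8 protons — keep a full five-condition benchmark within minutes on one
CPU while preserving every qualitative behavior of interest; the engine
itself handles larger sites, with combinatorics growing factorially.

The engine seed used for a condition deliberately ignores the
partial-assignment flag: with and without PA, each surviving assignment
is optimized identically, so partial assignment acts purely by removing
combinations from the ranking — making "PA never lowers the contrast" an
exact mechanism rather than a stochastic tendency.

## Numerical choices and degenerate inputs

* Ties in the ranking are broken by lexicographic assignment order; ties
  for `L_length` by the smallest proton-id pair.
* Near-identical poses (heavy-atom rmsd < 0.5 Å) within an assignment
  are deduplicated, keeping the lowest tf.
* `L_width` is 0 for collinear protons; `length_width()` requires two
  protons and errors below that.
* Networks must satisfy `0 < lower ≤ d ≤ upper`; TSV parsing reports the
  offending line numbers.
* A ligand without hydrogens is rejected at read time with advice to
  protonate first — hydrogen placement is a solved external problem and
  deliberately out of scope.
* The NOE build-up conversion uses initial slopes through the origin and
  the isolated-spin-pair sixth-root law against a reference pair; pairs
  with non-positive slopes are dropped with a warning. It is a
  self-consistent stand-in, not a relaxation-matrix treatment.

## Known limitations

Rigid ligands only (supply alternative conformers as separate runs);
single receptor assembly; PDB input only; no explicit receptor torsion
sampling (the per-restraint slack is a crude surrogate and is off by
default); overlapped NMR peaks (two labels on one site) are rejected
rather than modeled. The TFC threshold of 0.2 Å² was chosen for perfect
in-silico data and is expected to be conservative for experimental
networks.
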