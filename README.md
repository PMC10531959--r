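# nmr2dock

Determine protein–fragment binding poses from **semi-ambiguous NMR
distance restraints** — networks in which the ligand protons are assigned
but the receptor methyl groups are anonymous labels `M_n`. This situation
arises in fragment-based drug discovery when intermolecular NOEs are
measured without spending weeks on protein methyl assignment: the data
constrain the pose, but only up to the unknown mapping of labels onto
methyl sites.

`nmr2dock` solves the combined combinatorial/geometric problem:

* enumerate every injective assignment of anonymous labels onto
  binding-site methyl carbons, honoring partial-assignment knowledge
  (amino-acid type sets, same-residue pairs);
* optimize a rigid-body ligand pose for each assignment against the
  distance bounds by multi-start simulated annealing with analytic
  gradient refinement;
* rank all calculated structures by the violation target function
  `tf = Σ max(0, d − upper, lower − d)² + clash penalty` (Å²);
* validate the best pose through the **target function contrast (TFC)**:
  the tf gap to the first structurally distinct pose (heavy-atom
  rmsd > 2 Å, no re-superposition). `TFC > 0.2` validates the result.

It also computes the ligand **topology parameters**
`r_l = L_length/⟨d⟩`, `r_w = L_width/⟨d⟩` (ligand dimensions over the
active protons, normalized by the mean restraint distance) that predict
convergence — calculations mostly fail when `r_l + r_w < 2` — plus
binding-site suitability diagnostics, CYANA-style `.upl`/`.lol` writers,
an NOE build-up to distance converter, and a fully seeded synthetic
benchmark generator so everything is testable without downloads.

## Worked example

Generate a synthetic benchmark case (binding site, planar fragment,
ground-truth pose, anonymized restraint network), run the full
calculation, and validate:

```r
library(nmr2dock)

case <- make_case(seed = 42)
case
#> <nmr2_case> case_42 : 33 restraints, 6 methyl sites, 7 protons

topology_parameters(case$network)
#> # A tibble: 1 × 6
#>   L_length L_width mean_d   r_l   r_w n_restraints
#>      <dbl>   <dbl>  <dbl> <dbl> <dbl>        <int>
#> 1      6.5     3.5   5.51  1.18 0.635           33

fit <- run_nmr2(case$network, case$sites, case$ligand, case$receptor,
                engine_config(seed = 7))
fit
#> <nmr2_fit> 1007 ranked structures from 720 assignments; best tf = 0.0000 A^2

val <- compute_tfc(fit)
val
#> <nmr2_validation> TFC = 12.463 (validated)

classify_success(val, case$truth_pose)
#> # A tibble: 1 × 4
#>   success validated rmsd_to_reference axis_angle_deg
#>   <lgl>   <lgl>                 <dbl>          <dbl>
#> 1 TRUE    TRUE               1.28e-15              0
```

Reading: the ligand's length and width are 1.18 and 0.64 times the mean
restraint distance (`r_l + r_w = 1.8`, near the empirical convergence
boundary). All 720 methyl-assignment combinations were optimized; the
best of the 1007 ranked structures has zero bound violations, the first
pose differing from it by more than 2 Å costs 12.5 Å² more — far above
the 0.2 validation threshold — and the recovered pose matches the ground
truth to numerical precision.

A five-condition benchmark (exact restraints; ±10% and ±20% tolerance,
each with and without partial assignment) over a seeded library:

```r
lib <- make_library(10, master_seed = 2024)
report <- run_benchmark(lib$cases)
tidy(report)          # per-condition success rate, rmsd, TFC statistics
autoplot(report)      # success bars with TFC overlay
plot_topology_scatter(report$rows)   # r_l vs r_w colored by outcome
```

For real data, start from a protonated PDB file instead:

```r
cx      <- read_complex("complex_h.pdb", ligand_residue_name = "LIG")
methyls <- find_binding_site_methyls(cx, cutoff = 7)
net     <- extract_restraints(cx, methyls, max_distance = 7, seed = 1)$network
net     <- apply_tolerance(net, 0.10)
net     <- attach_partial_assignment(net, types = list(M_3 = "MET"))
```

A thin command-line wrapper with `extract`, `topology`, `run`, `synth`
and `bench` subcommands is installed at
`system.file("cli", "nmr2dock.R", package = "nmr2dock")`.

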