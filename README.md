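# quatstruct

Quaternary-structure analysis for oligomeric enzymes: point-group symmetry
detection, apo/product-bound conformational profiling, inter-subunit
"interlock" contact classification, substrate-induced compaction metrics,
and the supporting biophysical fits (Matthews coefficient, Hill kinetics,
thermofluor melting curves).

## The problem

Many sugar-activating nucleotidyltransferases are only active as symmetric
oligomers. Human UDP-glucose pyrophosphorylase (UGP) — the sole mammalian
route from glucose-1-phosphate to UDP-glucose — assembles into a D4
octamer: two cyclic C4 tetramers stacked back to back and related by
perpendicular 2-fold axes. In the octamer, the sugar-binding loop of each
subunit is stabilised by hydrogen bonds *from the neighbouring subunit* (an
arginine–aspartate pair), a mechanism called the **interlock**; monomeric
relatives achieve the same stabilisation intramolecularly (the **lock**).
Product binding also compacts the assembly measurably. Quantifying all of
this from deposited coordinates requires a pipeline that can

- detect the point group (Cn/Dn) of a multi-chain assembly and classify its
  interfaces (end-to-end vs side-by-side);
- superpose apo and product-bound subunits on a stable frame and report
  per-residue Cα and side-chain displacement maxima for named regions;
- find typed contacts (H-bond ≤ 3.5 Å, salt bridge ≤ 4.0 Å, hydrophobic
  C–C ≤ 4.5 Å; heavy-atom criteria) and decide lock vs interlock;
- measure per-axis extents and bounding-box volume in the symmetry frame
  and report the percent volume change between states
  (`(V_holo/V_apo − 1)·100`, negative = compaction);
- compute crystal metrics `V_M = V_cell/(Z·M)` and solvent content
  `(1 − 1.230/V_M)·100`, fit `v = V_max·x^H/(K^H + x^H)` (Hill; H = 1 is
  Michaelis–Menten, compared by extra-sum-of-squares F-test), and fit
  Boltzmann sigmoids `F(T) = 1/(1 + exp((T_m − T)/slope))` to melting
  curves.

`quatstruct` implements all of the above as a tidyverse-native R package:
assemblies are atom-level tibbles, results come back as tibbles or small S3
objects with `tidy()`, `glance()` and `autoplot()` methods. A synthetic
generator builds assemblies with *known* ground truth (planted symmetry,
contacts, hinge deformations, compaction factors, kinetic and melt
parameters), so every analysis stage is validated end to end without
downloading structures.

## Worked example

```r
library(quatstruct)

# a D4 octamer of toy helical subunits, with a mutual Arg-Asp contact
# planted between ring neighbours at 2.9 A
sub     <- make_subunit(seed = 1, n_residues = 30)
octamer <- make_assembly(sub, "D", n = 4)
octamer <- plant_contact(octamer, region_resno = 15, partner_resno = 25,
                         distance = 2.9)

detect_point_group(octamer)
#> <symmetry_model> D4  (residual 0.000 A)
#>   principal axis: [0.000 -0.000 1.000]
#>   4 secondary 2-fold axes
#>   cycle: A->B B->C C->D D->A E->H F->E G->F H->G

glance(detect_interlock(octamer, region_definition("binding", c(15, 15))))
#> # A tibble: 1 x 6
#>   region  classification n_stabilizing n_inter_chain n_recurring_pairs ...
#> 1 binding interlock                142            78                 1
```

The point group is recovered with zero residual, and the binding region is
classified `interlock`: its stabilising contacts are intermolecular and the
same partner pair recurs in all eight chains. Now deform the assembly —
tilt residues 28–30 by 6° about a hinge and shrink the whole octamer
isotropically by 5% — and measure the compaction:

```r
pair <- make_apo_holo_pair(octamer, region_definition("tip", c(28, 30)),
                           angle = 6, compaction_factor = 0.95)
compaction_report(pair$apo, pair$holo)
#> <compaction_report> chains A,B,C,D,E,F,G,H
#>   extents apo  :  108.86  108.86   64.94 A
#>   extents holo :  103.41  103.41   61.45 A
#>   deltas       :   -5.44   -5.44   -3.49 A
#>   volume change: -14.6 %
```

A 0.95 linear scale is a 0.95³ − 1 = −14.26% volume change; the report
recovers it (the extra −0.3% comes from the hinge tilt). Kinetics and
melting curves round-trip the same way:

```r
kin <- simulate_kinetics("Hill", v_max = 10, k = 2, h = 1.7,
                         noise_sd = 0.3, seed = 42)
tidy(fit_kinetics(kin, "Hill"))
#> # A tibble: 3 x 3
#>   term   estimate std_error
#> 1 v_max     10.4      0.336
#> 2 k_half     2.05     0.147
#> 3 hill_h     1.60     0.139

compare_kinetic_models(kin)$preferred     # "Hill" (F = 25.7, p = 0.007)

fit_melt(simulate_melt(t_m = 55.65, slope = 2, noise_sd = 0.02, seed = 42))
#> <melt_fit> Tm = 55.88 C, slope = 2.07 C (n = 71, RSS = 0.03383)
```

For real structures, `read_structure()` ingests PDB or mmCIF files,
`read_regions()` loads named residue regions from YAML (a config for human
UGP ships in `inst/extdata/hugp_regions.yaml`, with isoform numbering
offsets handled by `resolve_region()`), and `run_quaternary_report()`
chains every stage over an apo/holo pair into one JSON report — see
`vignette` sources in `vignettes/` for the full methods description.

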