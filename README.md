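# coatmap

Protein–protein interfaces and correlated evolution in vesicle coat
assemblies such as the clathrin lattice, with first-class support for
the low-resolution (C-alpha-only) cryo-EM models in which such
assemblies are typically solved.

Who it is for: structural bioinformaticians analysing large multi-chain
complexes where all-atom detail is unavailable for the assembly even
though it exists for the components, and anyone studying whether the
interfaces of an assembly are evolutionarily constrained and whether its
components co-evolve.

## What it computes

**Interface residues from solvent accessibility.** With all-atom
coordinates, ASA is computed by deterministic Shrake–Rupley quadrature
(probe 1.4 Å) and a residue is classified as interface when it is buried
in the complex (relative accessibility < 7%) and exposed in the isolated
chain (> 10%), relative to a configurable per-residue-type maximum-ASA
table. With C-alpha-only models the probe is enlarged to 3.5 Å, each
residue is a single C-alpha bead, and the percentage criterion is
replaced by residue-type-dependent absolute cutoffs — the C-alpha ASA
values corresponding to 7% and 10% accessibility — calibrated from
all-atom training structures by per-type isotonic regression
(`calibrate_calpha_cutoffs()`).

**Assembly decomposition.** Chains with any inter-chain Cα–Cα distance
≤ 5 Å are near neighbours; each chain is analysed within its own
subcomplex (the chain plus its neighbours), which keeps whole-coat
calculations tractable without removing any relevant occluder.

**Conservation of interfaces.** Orthologue hits are filtered (> 30%
identity, > 70% query coverage, strict), per-column conservation is
scored as sequence-weighted entropy with the lowest-score-most-conserved
convention, and interface residues are compared against non-interface
surface-exposed residues with a bootstrap interval on the difference.

**Mirror-tree correlated evolution.** Genetic distance matrices
(Poisson- or Gamma-corrected amino-acid distances) are compared between
families by Pearson correlation over common species, with a
species-permutation significance test and unrelated baseline pairs;
neighbour-joining trees are built for inspection and export.

**Synthetic benchmark generators.** Deterministic multi-chain complexes
with a known buried interface (all-atom and C-alpha-only renditions) and
orthologue families simulated along species trees with site-class and
family-level rate control — the fixtures all tests run on, and a
self-contained way to validate the whole chain.

## Worked example

Generate a three-helix bundle, detect its interface in the all-atom
regime, and test whether interface sites are more conserved in a family
whose slow sites coincide with that interface:

```r
library(coatmap)

gc  <- generate_complex(complex_scenario(n_chains = 3, length = 40, seed = 11))
gc$all_atom
#> <coat_structure> synthetic-11: 3 chains, 120 residues, 972 atoms

cp  <- compute_sasa(gc$all_atom, probe_radius = 1.4, n_points = 480)
iso <- isolated_profiles(gc$all_atom, probe_radius = 1.4, n_points = 480)
ifc <- detect_interface_allatom(cp, iso)
nrow(ifc)
#> [1] 15
head(ifc, 4)
#>   chain resno insert res_type complex_value isolated_value
#> 1     A     5               K     0.7467233       51.59843
#> 2     A     9               E     0.1866808       59.43903
#> 3     A    16               Q     0.7467233       61.67881
#> 4     A    20               L     3.1825135       48.96292
```

Each row is a residue buried in the complex (`complex_value`, percent
accessibility, all < 7) yet exposed once its chain is isolated
(`isolated_value` > 10): residue K5 of chain A drops from 51.6% to 0.7%
accessibility on complex formation.

```r
part <- classify_surface(iso[["A"]], ifc)
table(part$class)
#> interface   surface
#>         7        33

fam  <- simulate_family(evolution_scenario(
  n_taxa = 16, n_sites = nrow(part), seed = 21,
  site_classes = ifelse(part$class == "interface", "interface", "surface")))
prof <- conservation_scores(fam)
cmp  <- compare_interface_conservation(prof, part, n_boot = 2000, seed = 42)
cmp$difference
#> [1] -2.12215
cmp$ci
#> [1] -2.556377 -1.686977
```

The mean conservation score of interface residues is 2.12 z-units below
the non-interface surface residues (lower = more conserved), with a
bootstrap interval excluding zero — the interface is significantly more
conserved, as expected when interface sites evolve at one fifth the
surface rate.

The full chain — structures, calibrated C-alpha detection, conservation,
and a mirror-tree table with baseline pairs — runs from one
configuration:

```r
report <- run_pipeline(system.file("extdata", "config_synthetic.yaml",
                                   package = "coatmap"))
report
#> <run_report>
#>   structures: 2
#>   interface residues: 16, 20
#>   conservation comparisons: 1
#>   mirror pairs:
#>             a            b        role            r p_value
#>   clathrin_hc beta_adaptin interacting  0.976996330   0.002
#>   clathrin_hc   mu_adaptin interacting  0.972265450   0.002
#>  beta_adaptin   mu_adaptin interacting  0.964235296   0.002
#>   clathrin_hc unrelated_ap    baseline -0.004316498   0.476
#>  beta_adaptin unrelated_ap    baseline -0.025191451   0.562
```

Families evolving on a shared species tree correlate near r = 0.97 with
permutation p = 0.002, while the unrelated baseline pairs sit at r ≈ 0 —
the mirror-tree signature of correlated evolution between assembly
components.

A thin command-line front end over the same functions is installed at
`system.file("cli", "coatmap.R", package = "coatmap")` with subcommands
`neighbors`, `sasa`, `interface`, `calibrate`, `conserve`, `mirror` and
`run`.

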