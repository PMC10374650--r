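# ffdat — a relational data scheme for transferable force fields

Classical molecular simulation (MD/MC) rests on force fields.  A
*transferable* force field is a chemical construction plan: interaction
potentials attached to types of atoms or fused atom groups (`CH3`,
`CH2`, a hydroxyl oxygen, ...), from which a model of any molecule in
the covered chemistry can be derived.  In the literature these plans are
printed in incompatible notations, unit systems and functional forms,
which makes them hard to move between publications, databases and
simulation engines.

ffdat is an R implementation of a formal data scheme for such
construction plans (the TUK-FFDat scheme), for force-field developers,
database maintainers and simulators who need the plans machine-readable:

* **Tags** name interaction-site types as `group-site-nbonds-maxorder`
  (e.g. `A-C-2-1`, the interior CH₂ of an alkane chain; `Ak-O-2-1`, an
  alcohol oxygen).  `X` is a wildcard, so one pattern record such as
  `(X-C-X-1, 1, X-C-X-1)` covers every alkane C–C bond.
* **Seven record sections** hold a whole transferable force field:
  intermolecular (Lennard-Jones U = 4ε[(σ/r)¹² − (σ/r)⁶] + k_C·q_ij/r,
  or n-6 Mie, with geometric-ε / arithmetic-σ combination rules),
  bond, angle, torsion (e.g. the cosine series
  c₀ + c₁(1+cosΦ) + c₂(1−cos2Φ) + c₃(1+cos3Φ)), improper, scaled 1,n
  interactions, and special pair potentials.  Rigid constraints are
  `none` entries carrying the fixed length/angle.
* **Three interchangeable representations** — tibbles, a single-file
  SQLite database, and an XLSX workbook (one sheet per section) — with
  validated, lossless round-trips.
* **An atom-typing engine** that fuses hydrogens into united-atom sites
  (polar H stay explicit), assigns functional groups by subgraph motifs
  and derives concrete tags.
* **An assembler** that enumerates bonds/angles/torsions/impropers/1,n
  and special pairs on the site graph, resolves each against the dataset
  (most-specific-match wins; ties are errors), and evaluates energies on
  coordinates.

The alkane/alcohol subset of the TraPPE united-atom force field is
bundled as `load_bundled()` (energies on the ε/k_B Kelvin scale).

## Worked example

```r
library(ffdat)

trappe <- load_bundled()
trappe
#> <ff_dataset> trappe-ua-alkane-alcohol [K-A-e]
#>   intermolecular  11 record(s)
#>   bond            3 record(s)
#>   angle           5 record(s)
#>   torsion         11 record(s)
#>   improper        0 record(s)
#>   one_n           0 record(s)
#>   special         2 record(s)

site_report(type_molecule(make_fixture("ethanol")$graph))
#> # A tibble: 4 × 5
#>    site element fused_h group tag
#>   <int> <chr>     <int> <chr> <chr>
#> 1     1 C             3 A     A-C-1-1
#> 2     2 C             2 Ak    Ak-C-2-1
#> 3     3 O             0 Ak    Ak-O-2-1
#> 4     4 H             0 Ak    Ak-H-1-1

build_component_ff(trappe, make_fixture("ethanol")$graph)
#> <ff_component> ethanol from trappe-ua-alkane-alcohol [K-A-e]
#>   4 site(s); net charge 5.55112e-17 e
#>   terms: bond 3, angle 2, torsion 1, improper 0, special 0 ; 1,n scaled 0, excluded 1
```

Ethanol types into four united sites; the CH₃ stays on the uncharged
alkane parameters while the α-carbon, oxygen and hydroxyl hydrogen carry
the alcohol charges (+0.265, −0.700, +0.435 e), summing to zero at
machine precision.  All three bonds resolve to rigid (`none`) records,
so they contribute constraint residuals instead of energy:

```r
bu <- make_fixture("n-butane")
ff <- build_component_ff(trappe, bu$graph)
molecule_energy(ff, bu$coords)           # idealized trans geometry
#> <ff_energy> total 0 (bonded 0)
#> # A tibble: 6 × 2
#>   kind     energy
#>   <chr>     <dbl>
#> 1 bond          0
#> 2 angle         0
#> 3 torsion       0
#> 4 improper      0
#> 5 one_n         0
#> 6 special       0
#>   3 rigid constraint(s), max |deviation| 0
```

At the trans reference every flexible term sits at its minimum.  Rotating
the central dihedral to cis costs exactly 2(c₁ + c₃) = 2292.70 K, the
textbook barrier of the alkane torsion:

```r
cis <- ffdat:::chain_coords(rep(1.54, 3), rep(114, 2), 0)
molecule_energy(ff, cis)$breakdown$energy[3]
#> [1] 2292.7
```

Datasets convert losslessly between formats, here tibbles → SQLite →
workbook:

```r
write_database(trappe, "trappe.sqlite")
write_workbook(read_database("trappe.sqlite"), "trappe.xlsx")
```

A thin command-line wrapper over the same functions ships in
`inst/cli/ffdat.R` (`convert`, `validate`, `query`, `type`, `build`,
`energy`, `fixture`).

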