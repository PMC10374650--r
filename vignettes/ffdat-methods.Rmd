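---
title: "The ffdat data scheme: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ffdat data scheme: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffdat)
```

## The problem

A transferable force field is a chemical construction plan: a catalogue of
interaction potentials attached to *types* of atoms or fused atom groups,
from which a simulation-ready model of any molecule in the covered
chemistry can be derived.  Publications print these catalogues in wildly
different notations, unit systems, and functional forms, which makes the
data hard to exchange between force-field developers, databases and
simulation engines.  ffdat implements a relational data scheme that
formalizes such construction plans: a tag notation for site types, seven
record sections covering every interaction class, a fixed registry of
potential functions, and the machinery that turns a dataset plus a
molecular graph into a component-specific force field with evaluable
energies.

## Tags

A site type is named by four hyphen-joined parts,
`group-site-nbonds-maxorder`:

* **group** — functional-group abbreviation (`A` alkane, `Ak` alcohol,
  `E` ether, ..., see `ff_groups()`);
* **site** — element symbol, with a united carbon and its fused hydrogens
  written `C`;
* **nbonds** — the number of bonds the site forms with other interaction
  sites;
* **maxorder** — the highest bond order the site enters into.

`X` in any part is a wildcard.  `A-C-2-1` is the interior CH~2~ of an
alkane chain; `X-C-X-1` is any singly-bonded carbon site; `X-X-X-X`
matches everything.  Pattern records keep the tables compact: one
`(X-C-X-1, 1, X-C-X-1)` bond row covers every alkane C–C bond.

Two conventions deserve a note because the source material is not fully
self-consistent about them:

* **Field order.**  The defining table and all printed data place the
  bond count third and the maximum order fourth; one passage of running
  text reads the two parts in the opposite roles.  We follow the table
  and the data (`A-C-2-1` is the 2-bond CH~2~, which only makes sense
  with bond count third).
* **What `nbonds` counts.**  The data list the ethanol oxygen as
  `Ak-O-2-1` although one of its two neighbors is an explicit hydrogen
  site.  `nbonds` is therefore the site's degree *in the site graph*:
  fused hydrogens are invisible (they are not sites), explicit polar
  hydrogens count.  An isolated united site (methane) gets `0-0`.

## The seven sections

A dataset (`ff_dataset`) holds one tibble per section:

1. **intermolecular** — one tag, function id, parameters (charge,
   dispersion energy, size), DOI reference;
2. **bond** — tag pair + bond order;
3. **angle** — tag triple (tag 2 is central) + two orders;
4. **torsion** — tag quadruple (in-line) + three orders;
5. **improper** — central tag 0 + three neighbor tags/orders;
6. **1,n** — per-separation scaling factors for the van der Waals and
   electrostatic channels;
7. **special** — extra pair potentials at a given bond-count separation.

The id column of sections 2–5 and 7 may hold the literal `none`, marking
a rigid constraint whose fixed value sits in `p1`.  On the angle table we
treat tag 2 as the central site: the printed data place the distinctive
tag in the middle column and the descriptive text agrees, while one
column-legend line says "tag1 central"; we follow the data.

Datasets round-trip between three representations: tibbles in memory, a
single-file SQLite database (tables named as above; `1n_potential`
starts with a digit and is always quoted), and an XLSX workbook with one
sheet per section.  Writes are deterministic (rows sorted by tag tuple)
and validated first; reads coerce leniently (numeric cells stored as
text are accepted) and report malformed cells with their table, row and
column.  Because no spreadsheet-writing package is available in our
dependency footprint, the workbook writer emits minimal OOXML directly
— worksheet XML with inline strings inside a zip container assembled in
R (deflate streams from `memCompress()`, CRC-32 computed internally);
reading uses readxl, which also accepts legacy `.xls`.

## Potential functions and units

`ff_potentials()` registers every function the scheme ships: four
intermolecular forms (12-6 Lennard-Jones and n-6 Mie with
Lorentz–Berthelot-style combination rules, charge products, an
r~min~-parameterized variant with an explicit dielectric), three bond
forms (harmonic, quartic, `(k4/4)(r² − r0²)²`), three angle forms
(harmonic, a distance-coupled cross-term form, cosine-harmonic), six
torsion forms (the classic four-coefficient cosine series, harmonic,
plain cosine series, `c0[1 − cos(2Φ+Φ0)]`, a cos-power series and a
four-term shifted series), the harmonic improper, and the `k12/r¹²`
special repulsion.  The registry is open: new `(section, id)` entries
can be added at runtime.

Angles are stored and passed **in degrees** throughout, so harmonic
angle constants are on the energy/deg² scale of the stored data;
radian helpers are never applied implicitly.  Evaluators are otherwise
unit-agnostic — the single physical constant, the Coulomb prefactor
e²/4πε₀, comes from a unit profile.  Two profiles ship: `"eV-A-e"`
(14.399645 eV·Å) and `"K-A-e"` (167 101 K·Å, i.e. divided by k~B~).
The scheme's declared energy unit is eV, but the bundled TraPPE values
are the well-known ε/k~B~ numbers in Kelvin; since the source states no
conversion, both profiles are exposed and none is applied silently.
The bundled dataset is marked `K-A-e`.

Scaled 1,n interactions default to factor 0 for n ≤ 4 and 1 for n > 4
on both channels unless the dataset's sixth section says otherwise.
Pairs scaled to (0, 0) are recorded as *exclusions* rather than
zero-energy terms, because explicit exclusion lists are what downstream
engines consume.

## Typing engine

`unite_atoms()` fuses each hydrogen into its heavy neighbor unless its
context is polar (O–H, S–H, N–H by default), matching the united-atom
convention in which hydroxyl hydrogens remain explicit.  Group
assignment runs small subgraph matchers in a fixed priority order —
carboxylic acid before alcohol, ester before ether and ketone, acetal
before ether — then ring perception (kekulized benzene `B`,
cyclopentane `CA5`, cyclohexane `CA6`, larger saturated rings `CA`),
then the alkane default `A` for any remaining carbon (alkenes and
alkynes included).  The group label covers every site inside a motif:
in ethanol the O, the hydroxyl H *and* the α-carbon are `Ak`, while the
CH~3~ beyond the α position reverts to `A`.  That scope rule is not
spelled out by the scheme itself; we infer it from the parameter layout,
where α-carbons (`Ak-C-x-1`, charged) are parameterized separately from
plain alkane carbons, and a neutral ethanol requires the CH~3~ to
resolve to the uncharged alkane type.  Typing for the bundled
alkane/alcohol chemistry is exact; the remaining groups are matched
best-effort and the matcher set is extensible.  When a ring member also
sits inside a functional motif, the motif wins (a cyclohexanol α-carbon
is `Ak`, not `CA6`) — the scheme leaves this open and we prefer the more
specific chemistry.

## Assembly and resolution

`enumerate_terms()` lists bonds (edges), angles (length-2 paths,
center unique), torsions (simple in-line length-3 paths), improper
candidates (every 3-subset of neighbors around a site of degree ≥ 3),
1,n pairs (shortest-path bond distance d ≥ 3, n = d + 1, counted over
*all* sites including explicit hydrogens — the published special-pair
separations only make sense if hydrogen sites count) and special-pair
candidates at the separations present in the dataset.

`resolve_term()` matches a concrete tuple against the records of its
section in forward or reversed orientation (impropers: central tag
fixed, neighbors as a multiset) and picks the candidate with the
highest specificity: the number of non-wildcard tag fields plus one per
exact bond order.  Ties are a hard error, never a silent first match —
the scheme defines no precedence rule, so guessing would be worse than
failing.  Two deliberate softenings:

* an **improper candidate** with no matching record is dropped rather
  than raised, because an empty improper section is a legitimate
  statement that the force field defines no impropers (the bundled
  TraPPE-UA set is exactly such a case, yet must build isobutane);
  unresolved bonds, angles and torsions remain fatal;
* a site pair that is both a **special pair and a 1,n pair** receives
  *both* contributions: the published dist-4/5 hydroxyl repulsions
  coexist with the default 1,n scalings.

`molecule_energy()` reports per-kind sums.  Rigid terms contribute zero
energy; their geometric deviation from the fixed value is returned as a
constraint residual and warned about above a configurable tolerance
(10⁻⁶ Å or degrees — tight because the reference geometries are
constructed, not measured).  Torsions use the IUPAC dihedral convention
(trans = 180°); the improper angle is measured between the central→third
bond and the plane of the first two neighbors.

## Fixtures and what the tests show

The fixture generator builds explicit-hydrogen graphs for eleven small
alkanes, alcohols, an ether and an alkene by filling standard valences
over a heavy-atom skeleton, and supplies united-atom reference
coordinates at the idealized geometry (bonds 1.54/1.43/0.945 Å, angles
114/112/109.47/108.5°, torsions trans) wherever the bundled dataset
fixes the geometry.  These molecules exercise every code path — pattern
resolution, rigid constraints, branching, explicit hydrogens, special
pairs — but they are small (≤ 8 sites) and conformationally trivial;
passing tests demonstrate the correctness of the bookkeeping and the
closed forms, not the thermodynamic quality of any force field, and say
nothing about large, cyclic or multivalent chemistries beyond the
matcher coverage described above.

Problem sizes are deliberately desk-scale: enumeration oracles run
brute-force path searches on ≤ 8-site graphs, energy identities use a
few hundred grid points, and the whole suite — including the acceptance
checks — recomputes everything from scratch in well under a minute.

## Known limitations

* No simulation-engine export (LAMMPS/GROMACS decks), conformer
  generation, minimization, long-range electrostatics or cutoffs.
* Cis/trans-dependent torsion variants are not represented.
* Tags are the only site identity; there is no SMILES/InChI mapping.
* Aromatic input must be kekulized; V3000 connection tables are
  rejected.
* Group matchers beyond the alkane/alcohol chemistry are best-effort
  pattern translations of formula-style motif descriptions.
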