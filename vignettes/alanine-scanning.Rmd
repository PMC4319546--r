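---
title: "Alanine scanning of binding-site residues: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alanine scanning of binding-site residues: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abscan)
```

## The question and the model

Binding-site residues contribute very unequally to ligand recognition.
Alanine-scanning mutagenesis probes each contribution by deleting one side
chain at a time: alanine keeps the backbone and Cβ but removes everything
beyond, without introducing new chemistry. `abscan` performs this scan
computationally on a protein–ligand complex and scores each deletion as

$$\Delta\Delta G = E_\mathrm{mut} - E_\mathrm{wt},$$

the change in *intermolecular* interaction energy of the fixed pose. The
sign convention makes favourable residues score positive: removing a side
chain that interacts favourably (negative energy) with the ligand raises
the mutant energy. Residues with $\Delta\Delta G$ at or above a threshold
(default 0.5 kcal/mol, an inclusive $\ge$ comparison) are flagged hotspots.

Two assumptions underpin the whole approach, and both are inherited from
the experimental technique it emulates: (a) the point mutation does not
materially rearrange the protein, and (b) the ligand binds the mutant in
the same pose as the wild type. Under (a) and (b), truncation with frozen
coordinates is not an approximation shortcut but the model itself; it is
also why the ranking, rather than the absolute $\Delta\Delta G$, is the
robust output.

## The energy function

The scorer is a semi-empirical AutoDock4-style pairwise sum over
receptor–ligand atom pairs within a non-bonded cutoff of 8 Å, with four
weighted terms (weights from the AutoDock4.1 bound-state calibration, kept
in a single editable table, `scoring_params()`):

* **van der Waals** — Lennard-Jones 12-6, $A_{ij}/r^{12}-B_{ij}/r^6$, with
  $R_{ij}=(R_{ii}+R_{jj})/2$ and $\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}$;
  the minimum is exactly $-\epsilon_{ij}$ at $R_{ij}$.
* **hydrogen bond** — a 12-10 well of depth 5.0 kcal/mol at 1.9 Å for O/N
  acceptors (1.0 kcal/mol at 2.5 Å for S), applied to (polar H, acceptor)
  pairs, which then do not take the 12-6 term.
* **electrostatics** — screened Coulomb with the Mehler–Solmajer sigmoidal
  distance-dependent dielectric,
  $\varepsilon(r) = A + B/(1+k\,e^{-\lambda B r})$.
* **desolvation** — Gaussian-attenuated product of atomic solvation
  parameters and fragmental volumes,
  $(S_iV_j + S_jV_i)\,e^{-r^2/2\sigma^2}$ with $\sigma = 3.6$ Å and
  $S = \mathrm{solpar} + 0.01097\,|q|$.

The 12-6 and 12-10 pair distance is smoothed toward $R_{ij}$ by up to
0.25 Å (flat-bottom well, as in grid-based implementations of the same
force field) and capped at 100 kcal/mol at very short range. Components are
reported post-weighting, so the total is their exact sum.

Two deliberate deviations from grid-based AutoDock usage, both documented
here because they change individual numbers but not the ranking logic:

1. **No angular H-bond attenuation.** The grid implementation modulates the
   12-10 term by probe-direction factors that are not recoverable for
   arbitrary pairwise rescoring. Since the pose is identical in wild type
   and mutant, the angular factor is constant for every pair that both
   share; it can only affect the terms of the mutated residue itself.
2. **Intermolecular energy only.** Receptor-internal, ligand-internal and
   torsional-entropy terms are constant for a fixed pose and cancel in the
   mutant-minus-wild-type difference.

## Preparation: types, hydrogens, charges

Crystal structures rarely carry hydrogens and never carry partial charges,
so `prepare_receptor()` reproduces the receptor-preparation contract of the
AutoDock tool chain natively:

* **Bond perception** — two atoms bond iff their distance is under the
  covalent-radius sum + 0.45 Å (and above 0.4× that sum: anything closer is
  a clash, not a bond); hydrogens keep one bond, to the nearest heavy atom.
* **Atom typing** — carbons in planar (mean out-of-plane deviation
  < 0.1 Å) 5/6-membered rings are aromatic `A`; all oxygens are acceptors
  `OA`; a nitrogen is an acceptor `NA` iff it has no hydrogen and at most
  two heavy neighbours (pyridine/imidazole-like lone pair); sulfur is `SA`
  unless oxidised; H on N/O/S is the polar donor `HD`.
* **Polar-hydrogen completion** (`check_hydrogens()`) — missing backbone
  amide H and side-chain O–H/N–H/S–H are added at ideal geometry (0.96 Å
  O–H, 1.01 Å N–H, 1.34 Å S–H); histidine is protonated on NE2, the common
  neutral tautomer; disulfide cysteines get no thiol H; the operation is
  idempotent. Nonpolar hydrogens are *not* added — the united-atom step
  would remove them again — so when the input has no hydrogens at all, the
  PEOE iteration runs on the polar-hydrogen-only model rather than on an
  all-atom model that is immediately re-merged.
* **Gasteiger PEOE charges** — electronegativity
  $\chi = a + bq + cq^2$ per element/hybridisation class; at iteration $k$
  each bond transfers $(\chi_j-\chi_i)/\chi^+_\mathrm{donor}\,(1/2)^k$;
  eight iterations. Formal charges are imposed before iterating:
  Asp/Glu/C-terminal carboxylates (−0.5 per oxygen), Lys Nζ and N-terminal
  amines (+1), Arg guanidinium (+0.5 per NH nitrogen). Every step —
  iteration, hydrogen addition, united-atom merging — conserves total
  charge to numerical precision, and typing/charging are
  permutation-invariant, both enforced by tests.

Ligands selected from the complex are prepared the same way with a neutral
formal-charge seed (charges already annotated on the atoms are honoured as
seeds). This covers ordinary organic ligands; metal ions and unusual
chemistry are out of scope for native preparation by design, because their
ionic state cannot be inferred from geometry — such ligands enter through a
user-prepared PDBQT, whose charges and types are taken verbatim. Appending
water records to that PDBQT is the supported way to score bridge waters as
part of the ligand.

## Binding-site definition and mutagenesis

A receptor residue is in the site iff the minimum over all (residue atom,
ligand atom) distances is ≤ the cutoff (default 4.5 Å, inclusive).
Hydrogens count on both sides — the definition says *atoms*, and the
prepared model's polar hydrogens are genuine contact atoms. Waters, ions
and hetero "residues" are never site members. The site is provably monotone
in the cutoff, and the implementation is tested for equality with an
all-pairs double loop.

`mutate_to_alanine()` deletes side-chain atoms beyond Cβ, re-idealises the
Cα–Cβ bond to 1.53 Å along its existing direction, renames the residue and
touches nothing else; ALA is skipped (identity), GLY is skipped (the
mutation would *add* atoms), and nonstandard residues are skipped with a
record. Proline is truncated with a ring-opening warning rather than
refused — its backbone N geometry is the user's to judge. Each mutant
carries a steric certificate: a clash is a non-bonded pair (1-2 and 1-3
excluded) closer than 0.6× the vdW-radius sum. A statistical-potential
model score is deliberately not computed; for truncation-only mutants the
contract such a score serves — rejecting broken models — is met by the
clash count, which is reported per mutant.

An optional local minimiser (`minimize_local()`, off by default) relieves
clashes by soft-sphere steepest descent (up to 200 iterations, converged
when the largest per-step shift drops under 0.001 Å) followed by 200
annealing-style steps with small seeded random kicks, with bond-length
terms and a weak positional tether so the model cannot drift; only atoms
within 5 Å of the mutated residue may move, a worse-ending relaxation is
discarded, and the result is deterministic for a given seed. It is off by
default because truncation removes atoms and cannot create new overlaps;
it exists for strained input models.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| site cutoff | 4.5 | Å | the conventional contact-distance definition of a small-molecule site |
| hotspot threshold | 0.5 | kcal/mol | a stringent bound relative to typical per-residue averages (~0.4) |
| non-bonded cutoff | 8.0 | Å | standard range of the pairwise force field |
| smoothing width | 0.5 | Å | flat-bottom tolerance matching grid-table behaviour |
| desolvation σ | 3.6 | Å | Gaussian width of the solvation-volume overlap |
| PEOE iterations | 8 | — | charges converge geometrically under the (1/2)^k damping |
| clash fraction | 0.6 | of vdW sum | separates real overlap from tight packing |

## What the synthetic generator does and does not emulate

`make_toy_complex()` builds residues from internal-coordinate templates
(standard bond lengths/angles, fixed rotamers) on an α-helical backbone —
chosen because that backbone keeps fixed-rotamer side chains sterically
clean — and places ligand atoms just outside the side-chain tips of the
requested contact residues, verifying afterwards that the realised site is
exactly the requested one. It emulates what the pipeline needs: correct
topology, realistic local geometry, controllable contacts, deterministic
expansion. It does *not* emulate folded tertiary structure, pocket
enclosure (a real ligand is surrounded, not flanked), crystallographic
disorder, or ligand covalent structure (toy ligand atoms are unbonded
points with set charges). Green tests on these fixtures therefore certify
the machinery — parsing, preparation, geometry, energetics, ranking,
reporting — not predictive accuracy on real complexes, which is what the
deposited-structure case studies (`scripts/case_studies.R`, network
required) are for. The acceptance script scans a 24-residue mixed-sequence
helix with a four-atom polar ligand (heteroatom charges −0.4/−0.3 balanced
by +0.35 carbons): sizes chosen to exercise every residue class and both
polar terms while expanding in well under a minute.

## Numerical choices and degenerate inputs

* Alt-locs: highest occupancy wins, alphabetical id on ties; resolution
  never increases the atom count.
* Multi-MODEL files: first model only, with a warning.
* Insertion codes are part of residue identity (`"A:52:B"`).
* Empty binding site at the given cutoff: a warning and an empty result,
  not an error — a legitimate outcome for a distant ligand.
* An apo structure (no suitable hetero group) is an error naming the
  problem; an unscoreable ligand aborts with the instruction to supply a
  prepared PDBQT.
* Ties in the ΔΔG ranking break by residue id, so reports are bitwise
  reproducible for a given input and seed (asserted in tests).
* Skipped residues appear in every report with their reason and no
  energies.

## Known limitations

* Absolute ΔΔG values are force-field-scale numbers on a fixed pose; they
  are comparable within a site, less so across proteins.
* No backbone or rotamer relaxation: a mutation that would trigger real
  rearrangement (assumption (a) violated) is outside the model.
* The distance-only H-bond term can over-credit geometrically poor donors
  at the mutated residue itself.
* Metal-containing sites require user-supplied charges via PDBQT.
* Glycine positions cannot be probed at all — inherent to alanine
  scanning, not to this implementation.
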