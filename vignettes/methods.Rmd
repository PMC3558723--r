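---
title: "Methods: symmetry-aware Ca packing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symmetry-aware Ca packing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the package answers

One proposed mechanism for T cell receptor (TCR) triggering holds that two
TCR complexes dimerize in *cis* through the C and F beta strands on the
outer face of the alpha-chain constant domain (here "Ca" — the
immunoglobulin-like domain, not the alpha-carbon atom). If such a dimer
were physiological, crystal lattices of TCR/pMHC complexes — which sample
energetically favourable protein-protein arrangements — should show it in
at least some entries. `tcrlattice` implements the three computations such
a test needs:

1. **Packing analysis.** Enumerate every molecule the crystal symmetry
   places next to the asymmetric unit and classify all inter-molecular
   contacts made by each Ca domain.
2. **Dimer assessment.** For every Ca-Ca contact pair, measure whether the
   two copies are related by a true two-fold, how that two-fold is
   oriented relative to the cell membrane, and which Ig-fold elements
   carry the interface.
3. **Sequon analysis.** Locate N-X-S/T glycosylation sequons on the Ca
   domain, apply an efficiency rule, and ask whether expected glycans
   physically occlude the hypothesized C/F-strand interface.

## Crystal symmetry expansion

A deposited file contains one asymmetric unit (ASU); the lattice is the
ASU replicated by the space-group operators plus integer cell
translations. Operators are resolved from the Hermann-Mauguin symbol
against a bundled table covering the 65 Sohncke space groups (the only
groups chiral macromolecules can crystallize in), in their standard and
common alternative settings. Mates are generated in fractional
coordinates and kept when any atom comes within the *mate radius* of the
ASU.

The lattice-translation search window is derived per entry from the cell
dimensions and the molecule's bounding sphere (a molecule larger than its
cell can touch second-shell neighbours), never fixed at one shell. The
property suite checks the expansion against a brute-force operator-window
enumeration.

Numerical choices: alternate-location atoms keep the highest-occupancy
conformer (ties broken by altloc label order); model 1 only; hydrogens
and waters dropped at parse time; all analysis in Cartesian angstroms,
fractional coordinates only inside symmetry application.

## Contact detection and classification

A contact is a heavy-atom pair within the *contact cutoff*, default
4.5 Å — the standard crystal-contact criterion. One qualifying pair
suffices to register a contact: marginal, "barely touching" interfaces
must still appear in the survey, and interface-size judgements belong to
the assessment stage, not detection. The partner must belong to a
*different molecule instance*: a different complex in the ASU, a chain
not assigned to any complex, or any symmetry mate. Contacts within a
complex (the Ca's own heterodimer packing against Cb, for instance) are
never recorded; waters, ions and glycan HETATM groups are excluded on the
partner side because the survey classifies protein partners.

Partner classification is manifest-driven: a curated TSV assigns each
chain's author-numbered residue ranges to named domains (Va/Ca/Vb/Cb, MHC
subdomains, peptide, CD4). Curation rather than automatic domain
segmentation keeps the survey reproducible: its verdicts cannot drift
with a segmentation heuristic. The bundled
`survey_manifest_template.tsv` spells out the conventional chain layout
for one class I and one class II entry and leaves explicit `CURATE`
placeholders elsewhere; the pipeline raises a hard error on undeclared
chains, so an uncurated manifest fails loudly.

## Strand mapping

Ca residues are mapped to Ig-fold elements (strands A-G and the
connecting loops) by global pairwise alignment (BLOSUM62, gap open 11,
extend 1) of the entry's Ca sequence to a bundled species reference, with
element labels transferred through aligned non-gap columns. Transfers
below 30% identity are refused with a `strand-transfer-unreliable`
warning rather than silently degrading. The bundled references are
curated constant-region sequences for human and mouse with author
numbering anchored to the conventional TCR alpha-chain numbering, so the
conserved human sequons fall at N141 (start of the C strand), N175 (EF
loop) and N186 (F strand), and the murine ones at N185 (EF loop) and
N199 (FG loop). Strand boundaries are a curated Ig C1-set topology; they
are bundled data, editable without touching code.

## Dimer assessment

**Symmetry.** The two Ca instances are superposed by least squares
(Kabsch) over matched backbone atoms; the relating rigid transformation
is decomposed into its rotation angle and the screw component (the
translation projected on the rotation axis). A crystallographic or
pseudo two-fold has an angle near 180 degrees and near-zero screw; the
acceptance thresholds default to angle >= 160 degrees and screw <= 3 Å —
tolerant of lattice distortion but strict enough to exclude glancing
asymmetric touches. Pairs with under 80% of the manifest Ca segment
resolved raise `insufficient-coordinates` instead of guessing.

**Orientation.** Each complex's *membrane axis* is the unit vector from
its variable-module (Va+Vb) backbone centroid to its constant-module
(Ca+Cb) centroid — pointing toward the membrane. Centroids are used
rather than C-terminal residues because connecting peptides are
frequently disordered. For a symmetric pair the two-fold axis is compared
with the sign-aligned mean of the two membrane axes; tilt at or below
45 degrees classifies the pair *upright-side-by-side* (both receptors
standing, as a signalling-competent dimer must), beyond it
*flat-on-membrane*. The 45-degree boundary is the midpoint between the
two ideal geometries and is exposed in the configuration; it is reported
with every result. A geometric note: for an *exact* two-fold the
sign-aligned mean membrane axis is the bisector of the two axes, which is
either parallel or perpendicular to the two-fold axis — the tilt is then
exactly 0 or 90 degrees, and intermediate tilts arise only for
approximate (real-crystal) two-folds. Non-symmetric pairs are classified
*asymmetric-touch* with the angle between the two membrane axes reported
instead.

**Interface composition.** Unique Ca-side contact atoms are tallied per
Ig element on each side of the pair (an atom counts once regardless of
how many pairs it joins, avoiding double-weighting), the two sides are
averaged and normalized. A pair is *consistent with the C/F-strand
dimerization model* only when it is symmetric, upright, and the combined
C-strand plus F-strand fraction reaches 0.5.

## Sequon analysis

The scanner reports every N-X-S/T with X != P, overlapping hits
included; the proline exclusion is the standard sequon definition.
Efficiency follows the published rule for N-X-S sites — efficient unless
X is Trp, Asp, Glu or Leu; the rule is stated for the S form only, so
N-X-T sites default to efficient, and the rule table is swappable for
alternative published rules. A site *occludes* the putative interface
when it is efficient and its Asn lies on the C or F strand (or on an
observed interface element set, when one is supplied). Solvent
accessibility is deliberately out of scope: the verdict reports strand
location only.

## The synthetic generator and what it does (not) show

`make_crystal_scenario()` builds backbone-only pseudo-Ig complexes (four
48-residue domains: Va/Ca/Vb/Cb; two stacked four-strand sheets per
domain; 3.8 Å residue spacing) and plants five packing situations with
exactly known ground truth: an isolated molecule, a lattice contact
through F strands across a crystallographic two-fold (space group P2), an
upright exact two-fold dimer, a flat two-fold (axis perpendicular to the
membrane axes), and a 90-degree asymmetric touch. Planted contacts are
tuned by a root search to a 3.9 Å closest approach; the F strand
protrudes 2.5 Å beyond the sheet face and loops dip below it, so planted
face-to-face contacts are carried by F-strand atoms alone. Unit cells are
three molecular diameters wide except where a contact is planted,
isolating the intended interface. `make_sequences()` draws background
residues from the 17 amino acids other than N, S and T, so planted
sequons are the only sequons.

Passing on these fixtures demonstrates the geometry, symmetry handling
and bookkeeping are exact. It does not demonstrate robustness to
features of real crystals — disorder, alternate conformations,
near-threshold interfaces, low-identity Ca sequences — beyond what the
thresholds above were designed for; the full-survey checks on deposited
entries exist for that and require a one-time structure fetch
(`inst/cli/fetch_structures.R`) plus completed manifest curation.

## Problem sizes and determinism

The test suite and acceptance script run entirely on the synthetic
generator: five scenarios at 48 residues per domain across ten seeds
(fifty full pipeline runs), a 10^4-sequence scanner comparison against a
regex oracle, and exhaustive truth tables for the efficiency rule. Every
stage is deterministic given a seed; survey outputs are byte-identical
across reruns and independent of manifest row order, and every run
writes a provenance sidecar (thresholds, structure checksums).

## Known limitations

- Chain curation for the 22 deposited survey entries ships as a template;
  the full-survey checks only run after fetch + curation.
- The murine FG-loop site is printed inconsistently in the literature
  (Asn199 vs N189); the bundled numbering reproduces 185/199
  self-consistently, and tests assert the site count, not the label.
- No buried-surface-area or assembly-level (PISA-style) scoring; the
  biological-vs-crystallographic judgement here is purely geometric.
- No NCS handling beyond what the coordinate file states, no biounit
  generation, and no electron-density-level validation of glycan
  occupancy.
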