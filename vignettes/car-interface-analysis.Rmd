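---
title: "Analysing the CAR mRNA interaction surface: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the CAR mRNA interaction surface: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocar)
library(dplyr)
```

## The system

During translocation, the mRNA codon next in line for the ribosomal A-site
(the "+1 codon") passes a composite surface on the small subunit head: the
Watson-Crick edge of 16S/18S rRNA C1054, the Hoogsteen edge of the adjacent,
stacked A1196, and the planar guanidinium group of ribosomal protein S3
arginine R146 stacked on A1196 (the **CAR** surface, for C1054-A1196-R146).
The surface is anchored to the A-site by base stacking of C1054 with the
wobble anticodon nucleotide. A +1 codon conforming to the GCN pattern can
engage the surface: G at position 1 Watson-Crick pairs with C1054, and C at
position 2 forms a trans Watson-Crick/Hoogsteen ("reverse Hoogsteen") pair
with A1196 - N6 of the adenine donating to N3 of the cytosine, and N4 of the
cytosine donating to N7 of the adenine - with additional hydrogen bonds from
the guanidinium donors of R146.

`ribocar` implements the analysis machinery for studying this surface in
molecular-dynamics trajectories of a restrained ribosome subsystem:
subsystem construction, emission of the staged preparation protocol,
per-frame hydrogen-bond and stacking geometry, multi-run statistics, and a
synthetic-trajectory generator that lets every stage be exercised and
validated at desk scale. It does not run any MD engine; engine parameters are
emitted as data.

## Subsystem construction

`select_shell()` keeps a residue when **any** of its atoms lies within
`radius` (default 40 Angstrom) of any atom of the anchor residue - the
conventional anchor being the G530 nucleotide of the 530 loop, immediately
adjacent to the decoding centre. The any-atom rule is deliberately inclusive:
residues partially entering the shell are retained whole. Gaps of at most
`gap_fill_max` residues (default 10) between kept segments of one chain are
then filled, reducing the number of artificial chain breaks; the published
curation of such subsystems is judgment-based, so the gap rule is a parameter
rather than a hard-coded reproduction. Every remaining segment terminus that
is not a native chain terminus is recorded as a break point with one cap
record; capping is bookkeeping here (terminal-residue flags), with cap
chemistry left to the MD engine's preparation tools.

`build_restraint_mask()` partitions the selection into an unrestrained core
and a restrained outer "onion shell" at a default positional weight of
20 kcal mol^-1 A^-2, serialisable as JSON or as an AMBER-style residue mask.
The core is user-supplied (or `core_by_radius()` for an inner-radius rule),
and `check_buffer()` verifies the convention that at least one unrestrained
residue buffers the residues of interest from the shell.

`substitute_nucleotide()` swaps a base in place the way template-based
preparation tools grow residues: sugar and phosphate atoms never move; for a
same-family substitution (pyrimidine to pyrimidine, purine to purine) base
atoms shared by name keep their coordinates; atoms unique to the new base are
grown from an idealized template positioned on the residue's glycosidic frame
(glycosidic nitrogen, the N-C1' bond direction, and the original base-plane
normal), preserving the orientation of the base plane relative to the
backbone to well under 5 degrees. Cross-family substitutions rebuild the
whole base on the same frame, since shared atom names no longer imply shared
geometry.

## The staged protocol as data

`default_schedule()` returns, as a plain data object, the staged
preparation protocol for the restrained subsystem: eleven minimization rounds
ramping the restraint weight 100, 75, 65, 55, 45, 30, 20, 15, 10, 5,
1 kcal mol^-1 A^-2 (20,000 steps with 2,500 steepest-descent first, then
10,000/2,500, 5,000/2,500, 3,000/2,500 twice, and six rounds of 2,000/2,000);
20 ps of heating at a 2 fs timestep with all residues restrained at
20 kcal mol^-1 A^-2; 3 ns of equilibration at 1 fs with inherited
velocities; production at 300 K sampled at 100 frames per ns with only the
onion shell restrained; environment: truncated octahedral box, 12 Angstrom
solvent margin, TIP3P water, Na+ counter-ions. The ramp was designed against
energy-slope convergence criteria; since no energies exist without an engine,
those criteria are carried as documentation fields, not recomputed. The
production length is a per-study choice and is a parameter (default 35 ns).
An optional `pre_restraint_md_ps` flag (0/10/100) records the stabilisation
variant of inserting short unrestrained MD before fixing the shell
coordinates. `render_schedule()` emits one document per stage - 11
minimization rounds plus heating, equilibration and production - either as
JSON that `parse_schedule()` round-trips exactly, or as AMBER mdin-style
text with `ntr`/`restraint_wt`/`dt` lines.

## Per-frame geometry

**Hydrogen bonds.** `detect_hbonds()` uses the cpptraj-style criteria: an
event requires donor-to-acceptor heavy-atom distance strictly below 3.0
Angstrom *and* donor-H-acceptor angle (vertex at the hydrogen, which the
criteria's common implementations use) of at least 135 degrees, for at least
one hydrogen of the donor. Both cutoffs are arguments. Donor hydrogens are
found geometrically (same residue, within 1.25 Angstrom); a donor without an
explicit hydrogen raises a diagnostic rather than being skipped, because the
angle criterion is meaningless without it. For trajectory work,
`hydrogen_topology()` computes the donor-H connectivity once on the clean
topology and `series_extract()` passes it to every frame - connectivity is
chemical, and per-frame coordinate noise must not be able to "detach" a
hydrogen.

**Edges.** The edge vocabulary follows the Leontis-Westhof taxonomy; since
edge atom memberships are rarely spelled out, the package fixes them
explicitly in `edge_table()`: C WC = {N4 donor, N3, O2 acceptors}; G WC =
{N1, N2 donors, O6 acceptor}; G Hoogsteen = {O6, N7 acceptors}; A WC = {N6
donor, N1 acceptor}; A Hoogsteen = {N6 donor, N7 acceptor}; U WC = {N3
donor, O2, O4 acceptors}; plus the arginine guanidinium donors NE, NH1, NH2
and backbone amide N. Adenine N6 and guanine O6 belong to both edges of
their base; `classify_edge()` therefore takes the frame and resolves the
ambiguity geometrically, assigning the edge whose heavy-atom centre of mass
is nearest the partner atom. Atoms on no defined edge (such as O2')
classify "off-edge"; unknown residue types classify "unclassified" but the
event is retained.

**Distances.** Edge-to-edge separations (`edge_distance()`) are distances
between mass-weighted centres of the edge's donor and acceptor heavy atoms
(standard atomic masses; hydrogens excluded, matching the "heavy atoms"
convention). The guanidinium group presents two donor pairs;
`guanidinium_edge_distance()` reports the smaller of the NE/NH1- and
NE/NH2-pair centre-of-mass distances each frame, with ties resolved
deterministically to NE/NH1. Stacking (`stacking_distance()`) is the
distance between mass-weighted centres of the ring heavy atoms - the fused
9-atom purine system, the 6-atom pyrimidine ring, and CZ/NE/NH1/NH2 for the
guanidinium "ring"; exocyclic atoms are excluded, reading "base rings"
literally. Stacked pairs read 3-4 Angstrom and unstacked ones above 5, so
`is_stacked()` uses the midpoint 4.5 as its default, exposed as a parameter.

**RMSD.** `backbone_rmsd()` measures per-frame RMSD over backbone atoms
(protein N/CA/C/O; nucleic P/O5'/C5'/C4'/C3'/O3') after optimal least-squares
superposition. The superposition can be disabled (`fit = FALSE`); note the
textbook identity "one atom displaced by d among n atoms gives RMSD
d/sqrt(n)" holds only without fitting - optimal superposition provably
reduces it to d sqrt(n-1)/n - so exact closed-form checks use `fit = FALSE`
while invariance-under-rigid-motion checks use the default.

**Series.** `series_extract()` produces tidy per-frame time courses (bond
counts, edge/guanidinium/stacking distances) at a stride, recording the
effective sampling rate so time stays in ns; `bin_series()` pools frames
into fixed-width bins (default 1 ns), keeps and flags a trailing partial
bin, and - because every frame lands in exactly one bin - its
frame-weighted bin means reproduce the global mean exactly.

## Multi-run statistics

Frames within a run are autocorrelated, so the replication unit throughout
is the MD run: `aggregate_runs()` computes run means first, then group means
and standard errors (SD of run means / sqrt(n_runs)) over runs. A group with
a single run reports SE 0 with a flag. `compare_groups()` is a two-sided
Welch (unequal-variance) t-test on run-level means - "t-test" alone
underdetermines the variant, and Welch is the safer default for small,
possibly heteroscedastic run sets; the choice is recorded in the result's
`method` field. Simulation under the null (see the test suite and
`scripts/acceptance.R`) confirms the nominal 5% type-I error within +/- 2
points over 2000 draws.

`contact_map()` reports, per residue pair, the fraction of frames with at
least one hydrogen bond, pooled frame-weighted across runs (an average of
per-run frequencies is available behind `pooling = "runs"`; frame-weighting
is the default since runs can differ in length and "average frequency over
pooled frames" is the more common convention). Display categories follow the
usual contact-figure thresholds: strong at frequency >= 0.10 (boundary
inclusive), weak for 0.025 < f < 0.10 (lower boundary strict), none
otherwise.

## The synthetic generator

`make_pair()` builds idealized two-residue structures for WC G:C, WC A:U and
the trans WC/Hoogsteen A:C pair from idealized residue templates (shipped as
plain text with explicit hydrogens, canonicalized to ring-centroid origin
and base plane = xy). The first residue keeps its template pose; the second
is placed by a deterministic multi-start rigid-body optimisation whose
objective holds every defining donor-acceptor distance at the target
(default 2.9 Angstrom, the canonical hydrogen-bond heavy-atom separation),
drives donor-H-acceptor geometries towards linear, and keeps the base planes
parallel (zero propeller/buckle). Construction is verified: for formed
targets the detector must find exactly the defining bond list, or the
generator aborts. A target of 5 Angstrom produces an "open" pair with no
bonds.

`make_car_fixture()` assembles the miniature decoding-centre neighbourhood:
C1054 (chain R, E. coli numbering), A1196 stacked on it with the Hoogsteen
edge presented outward, the R146 guanidinium stacked above, an anticodon
trinucleotide with the wobble base (default G) stacked below C1054, an
A-site codon facing the anticodon as non-interacting scenery, and the +1
codon: position 1 pairs C1054 when it is G; position 2 forms the reverse
Hoogsteen pair with A1196 when it is C. All stack rises default to 3.7
Angstrom, inside the 3.5-4.0 band typical of stacked bases. Non-C bases at
position 2 (G, A and U alike - pairing is defined only for C) and non-G
bases at position 1 are placed with their WC edge 6.5 Angstrom from the
partner edge, comfortably past the >= 4 Angstrom separation used to model
the poorer fit of non-GCN codons, so they form no bonds at construction.
The arginine is an isolated residue, which suffices for every guanidinium
metric.

`make_trajectory()` scripts per-frame bond states: frames marked broken
displace the partner residue rigidly 6.5 Angstrom along the pairing axis
(beyond the 6 Angstrom convention separating stacked/paired from broken),
then i.i.d. Gaussian noise of SD `noise_sigma` (default 0.1 Angstrom) is
added to every coordinate. The seed fully determines the trajectory and is
recorded, with the schedule, as a `ground_truth` attribute.
`recover_schedule()` classifies each frame's state from coordinates alone: a
frame is formed when the ring-centre separation is nearer the formed than
the broken geometry (decision boundary at the +3.25 Angstrom midpoint) or
when any hydrogen bond survives; at the default noise it recovers scripted
schedules essentially exactly. The raw "any bond detected" series is
noisier by design - a 2.9 Angstrom bond under 0.1 Angstrom per-atom noise
sits one axial SD below the 3.0 cutoff, so formed frames transiently lose
individual bonds roughly a quarter of the time - which is the realistic
flickering the binning utilities exist to smooth.

What the generator does *not* emulate: force-field energetics, solvent,
autocorrelated thermal motion (noise is white by construction), backbone
continuity of the fixture's mRNA/anticodon strands, and conformational
substates. Passing tests therefore demonstrate the correctness of the
measurement machinery on known ground truth, not the reproduction of any
simulated ensemble's biology.

## Numerical choices and degenerate inputs

- Ties in the guanidinium minimum-edge rule go to NE/NH1; ambiguous edge
  atoms resolve by nearest edge COM; both rules are deterministic.
- `bin_series()` keeps partial trailing bins flagged rather than dropping
  them, preserving the exact mean-conservation identity.
- Identical constant groups in `compare_groups()` return t = 0, p = 1
  (the Welch statistic is 0/0 there).
- Structures without explicit hydrogens are legal inputs everywhere except
  hydrogen-bond detection, which raises a typed diagnostic.
- Zero-frame trajectories, empty selections, cores outside the selection,
  unknown pair types and schedule ranges outside the frame count all raise
  typed errors (`car_*_error` condition classes).
- Problem sizes used by the tests and the acceptance script - 200-frame
  trajectories, 20 noisy fixtures, 2000 null simulations, fixtures of ~70-400
  atoms - were chosen as the smallest sizes at which the stochastic
  properties are stable.

## Known limitations

Trajectory input is multi-model PDB only (binary formats would need an
external reader feeding the same `car_trajectory()` contract). The numbering
map covers the landmarks this analysis uses, not a full 16S/18S alignment.
The fixture geometry is a construction for validating measurements, not a
replica of any deposited subsystem; in particular the exact residue list of
the published 495-residue subsystem is not reproduced here, so shell
selection is validated against brute-force oracles on synthetic structures
instead.
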