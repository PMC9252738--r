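---
title: "Designing loop-grafted chimeras: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing loop-grafted chimeras: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeragraft)
```

`chimeragraft` designs chimeric proteins by transplanting loops between
two structurally related inputs. This vignette explains the models the
package implements, the parameters that matter, the choices made where
the design was genuinely open, and what the synthetic test fixtures do
and do not establish about behaviour on real structures.

## The unit of grafting

A loop is treated as a super-secondary structure: two regular
secondary-structure elements (helix or strand) plus the coil connecting
them. This matters because successful grafts preserve the geometric
overlay of the flanking elements: the cut points (recombination
boundaries) lie on the SSEs, not in the coil, and the transplanted
fragment always carries the donor's entire coil. The package therefore
never asks the user for a chimeric sequence; it derives every admissible
sequence from structure alone.

## Secondary structure

The default assignment is an internal implementation of the
hydrogen-bond approach of Kabsch and Sander: the amide H is placed 1 Å
from N along the preceding carbonyl direction, the electrostatic bond
energy is

$$E = 0.084 \cdot 332 \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)\ \mathrm{kcal/mol},$$

a bond exists when $E < -0.5$, and the usual n-turn and bridge patterns
yield an 8-state assignment collapsed to three states (3~10~, α and π
helices to H; bridges and ladders to E; everything else, including turns
and polyproline II, to C). An adapter for an external DSSP executable is
available (`assignSSE(backend = "dssp")`) for users who want
bit-compatibility with that tool; the internal backend is the default so
the package has no hard external dependency, and the two agree at the
3-state level wherever we have compared them. Exact boundaries of
elements may differ by ±1 residue between implementations, which is why
boundary-sensitive workflows expose user overrides (`applyOverride`) and
user-defined loops (`defineCustomLoop`).

Two length floors are applied after collapse: a helix run shorter than 3
residues or a strand run shorter than 2 is absorbed into coil. These
floors remove collapse artefacts; genuinely meaningful small elements
(e.g. a 3-residue helix interrupting a functional coil) are better
handled explicitly, by overriding the region to coil or drawing a custom
loop across it, than by silent heuristics.

## Loop geometry

Loop geometry is summarised by four parameters: the distance $D$ between
the two element anchors and the hoist ($\delta$), packing ($\theta$) and
meridian ($\rho$) angles. The package fixes the following conventions
(the literature leaves them partly open, so they are stated here and
verified against an independent rotation-matrix construction in the
tests):

* an element's **axis** is the principal axis of its Cα coordinates,
  oriented N→C — this works uniformly for helices and strands, unlike
  helix-specific fits;
* its **anchor** is the projection of the coil-side terminal Cα onto the
  axis line, so the geometry measures the bracing at the loop rather
  than at the element midpoints;
* $\theta$ = angle between the two axes; $\delta$ = angle between the
  first axis and the inter-anchor unit vector $m$; $\rho$ = right-handed
  signed dihedral of the second axis about $m$, measured from the
  $(v_1, m)$ plane, in $(-180°, 180°]$.

All four are invariant under rigid motion of the structure; $D$ and
$\theta$ are additionally invariant under chain reversal. With
coincident anchors ($D = 0$) the meridian is undefined and reported as 0
with a degenerate flag. Note that the principal axis of a short helix
differs measurably from its screw axis (≈6° for 11 residues, shrinking
with length); the synthetic generator records both so tests can
distinguish convention from noise.

## Flexibility and correlated motion

Four per-residue flexibility sources share one container: crystal
B-factors read from the file; NMR-ensemble values
$B_i = \tfrac{8\pi^2}{3}\,\mathrm{RMSF}_i^2$, with models least-squares
superposed on the first model before measuring fluctuations so that
rigid-body drift between models does not masquerade as mobility; and
theoretical values from Gaussian and anisotropic elastic network models.
The ENMs are built from Cα contact topology with the conventional
defaults of the field's reference implementations — GNM cutoff 10 Å, ANM
cutoff 15 Å, uniform spring constant 1, all non-trivial modes — because
only relative flexibility drives loop selection; theoretical profiles
are rescaled to the experimental mean when experimental values exist.
Zero modes are eigenvalues below $10^{-8}$ of the largest; GNM must shed
exactly one (otherwise the contact graph is disconnected and the error
says to increase the cutoff), ANM exactly six.

ANM modes also give residue–residue cross-correlations
$C_{ij} = \langle \Delta R_i \cdot \Delta R_j\rangle /
\sqrt{\langle\Delta R_i^2\rangle\langle\Delta R_j^2\rangle}$, and
segment-level correlations are plain arithmetic means over the matrix
block — the mean (rather than a maximum or a weighted variant) is the
assumption here, applied both loop↔loop and coil↔SSE. The second view
exists because the coil is the engineered part: a strong
coil↔distal-loop correlation flags a candidate for co-grafting.

Both implementations are cross-checked in the test suite against an
independent R implementation of the same models (`bio3d`), with rank
agreement r > 0.99, and against closed-form results on a 3-bead path
graph (fluctuations ∝ 5/9, 2/9, 5/9; end-to-end correlation −0.8).

## Superposition and residue pairing

The internal aligner is sequence-independent: it ranks all contiguous
fragment pairs (length 8, stride 2) by superposition RMSD, keeps up to
12 well-separated seeds — a single best seed is unsafe because regular
elements are self-similar under their screw symmetry and can lock a
register-shifted local minimum — and refines each by alternating
mutually-nearest-neighbour assignment (4 Å gate, kept sequence-collinear)
with least-squares refitting until the pair set converges. The result
with the most aligned pairs (ties: lower RMSD) wins; fewer than 20
pairs is an error. Any external rigid-body aligner meeting the same
contract can be substituted.

The residue pairing then proceeds in three deterministic passes with two
parameters:

1. greedy acceptance of cross-chain Cα pairs in ascending distance order
   (cutoff 1.9 Å; ties broken by distance, then scaffold, then insert
   index — so the result is independent of input order);
2. correlativity: the maximum-cardinality subset strictly increasing in
   both sequences, ties resolved by smaller total distance — this keeps
   the most structural signal while unpairing doublets that cross the
   sequence order, rather than discarding both members of every
   crossing;
3. a single-pass outlier filter on the sequence offset Δ = scaffold −
   insert index: doublets with |Δ − median(Δ)| > 4·SD(Δ) are unpaired,
   with the SD computed over all doublets before any removal. The filter
   runs after correlativity and is not iterated; both choices are open
   in principle and fixed here for reproducibility.

## Boundary enumeration and the chimera library

Every pairing doublet whose two sides lie on corresponding flanking SSEs
is a candidate boundary. An SSE position unpaired in the global pairing
is rescued by pairing it with the residue flanking the gap in the other
sequence — operationally, the partner of its nearest paired neighbour,
ties to the N-terminal side — provided that partner lies on the
corresponding SSE.

The library is the deduplicated set of chimeras over every non-empty
subset of selected loop pairs and every boundary combination per
included loop. Construction order (fewer loops first, then lexicographic
boundary order) and a 32-bit FNV-1a sequence hash make the library and
its identifiers reproducible byte for byte. Designs identical to the
scaffold, or to an earlier design, are rejected; grafted coil regions of
distinct loops must not overlap (loops may share a flanking SSE — the
boundary combinations that would make adjacent grafts collide are simply
skipped).

**Boundary membership** is the one genuinely consequential open choice:
when the chimera switches from scaffold to insert at a boundary doublet,
which chain contributes the boundary residues themselves? The default
(`insert_inclusive`) takes both boundary residues from the insert —
`scaffold[… n_S−1] + insert[n_I … c_I] + scaffold[c_S+1 …]` — which
matches the published case study this pipeline replicates (a scaffold
region 146–166 replaced by insert 148–167). The alternative
(`scaffold_inclusive`) is kept behind the `boundaryConvention` switch
because the replaced-region bookkeeping of other experiments may follow
it.

## Modelling preparation and scoring

For each design the package prepares inputs for an external
homology-modelling run: the scaffold template with the grafted loops'
coils deleted (only grafted coils — the scaffold must still inform the
rest of the model), one fragment per grafted loop comprising the
insert's whole super-secondary range, independently re-superposed onto
the scaffold region using only that region's doublets and then re-paired
locally, and one combined PIR alignment per design in which grafted coil
positions are covered only by the fragment, positions outside grafted
loops only by the scaffold, and overlaid flank positions by both
templates (so the modelling tool receives restraints from both where
they agree). Model energies (DOPE-style and Rosetta-style) are produced
by external licensed tools, never re-implemented; `ingestScores` merges
their per-design tables and assigns dense ranks (lower = better, ties
share a rank, missing metrics flagged). The ranking logic is
regression-tested against a checked-in synthetic score table.

## The synthetic generator, and what the tests do and do not show

Fixtures are built from ideal bond geometry (N–Cα 1.458 Å, Cα–C 1.525 Å,
C–N 1.329 Å) and canonical dihedrals (helix −57/−47, strand −139/135,
coil −70/140), with three controlled deviations: per-residue Gaussian
displacement, *correlated along the chain* (Gaussian kernel, bandwidth 2
residues) so that bond geometry stays physical — uncorrelated noise of
the same magnitude would stretch Cα–Cα distances past any plausible
chain-break threshold; homolog pairs sharing an architecture but with
divergent coil (optionally flank) sequences and a recorded random rigid
motion; and multi-model ensembles with recorded per-residue fluctuation
amplitudes. Every fixture is seed-deterministic and carries its ground
truth (states, element axes, correspondence, RMSF).

These fixtures exercise every pipeline stage, but they are idealised:
real homolog pairs diverge by insertions inside elements, bent helices,
register shifts in sheets and genuinely disordered loops, none of which
the generator emulates. Passing tests therefore establish correctness of
the algorithms under their stated assumptions, and recovery rates (e.g.
≥95% pairing recovery at σ = 0.3 Å) quantify noise robustness — they do
not guarantee equal performance on structurally divergent real pairs,
where the recommended-similarity warning (<8 Å RMSD, <20% length
difference) is the practical guard. Isolated strands are a further
caveat: a lone extended segment has no hydrogen-bond partner and is
assigned coil, so strand-flanked fixtures are annotated from generator
truth rather than through the assignment backend.

Test and acceptance problem sizes — chains of 20–40 residues, 20-seed
recovery panels, libraries of tens to a few thousand designs — were
chosen as the smallest sizes at which every code path (multi-loop
subsets, shared flanks, rescue doublets, dedup) is exercised with fully
enumerable oracles.

## Known limitations

* The case-study replication (design counts 18/24/432/474, 1.27 Å
  superposition RMSD, the 0.42 coil correlation, and the published graft
  sequence) requires the two reference PDB entries, which are not
  distributed with the package; the corresponding acceptance tests
  report the missing inputs until `inst/extdata/usecase/` is populated.
* Loop-geometry conventions (axis fit, anchors, meridian sign) are fixed
  and oracle-checked internally but are not guaranteed to agree
  numerically with other implementations of the same nomenclature.
* The internal aligner targets globally similar, single-domain pairs; it
  does not attempt flexible or multi-domain alignment.
* mmCIF input, side-chain handling and physically realistic ensemble
  generation are out of scope.
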