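---
title: "Quantifying lipid packing defects and protein-membrane interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid packing defects and protein-membrane interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdefect)
```

## The problem

Amphipathic proteins such as the N-terminal region of alpha-synuclein
(residues 1--60) bind lipid membranes by inserting into *packing defects*:
patches of the bilayer surface where headgroups fail to shield the glycerol
backbone and acyl chains from water.  Cholesterol reshapes this defect
landscape — its condensation suppresses small, shallow defects while
concentrating exposure into fewer, larger and deeper ones — and thereby
modulates both electrostatic protein binding and downstream behaviour such
as vesicle clustering.  `memdefect` implements the grid-based defect
quantification used in that line of work, together with the accompanying
protein--membrane hydrogen-bond and interaction-energy analyses, for planar
bilayer coordinate files (GRO, multi-model PDB).

## The defect model

For one leaflet of a planar bilayer (normal along +z):

1. **Grid.** The xy plane of the box is tiled by a square grid with a
   requested cell edge of 0.1 nm; cell counts are `round(L / cell)` per
   axis and the edge is recomputed as `L / n` so the grid tiles the box
   exactly.  At the default spacing each cell has area 0.01 nm².
2. **Overlap inequality.** A cell is *covered* by an atom when the 2D
   distance between the cell center and the atom's xy projection (with
   periodic wrap) is at most the atom's van der Waals radius.  Headgroup
   atoms of the leaflet's lipids define coverage; a cell no headgroup atom
   covers is a defect cell.
3. **Depth.** The glycerol plane is the mean z of the leaflet's
   glycerol-role atoms.  A defect cell is *deep* when no lipid atom above
   the plane 1 Å (0.1 nm) below the glycerol level overlaps it — including
   the case of no underlying atom at all, the deepest possible exposure —
   and *shallow* otherwise.
4. **Merging.** Defect cells whose centers lie within 0.3 nm (periodic)
   belong to the same defect; components are found with a deterministic
   union-find, so labels do not depend on enumeration order.  In
   `per_class` mode deep and shallow cells merge separately (per-class
   size distributions); in `all` mode every defect cell merges and the
   defect is deep if any member cell is deep, on the reasoning that one
   deep access point makes the whole defect insertion-competent.
5. **Statistics.** Per frame and leaflet: defect count, total and mean
   area, and the leaflet-area fraction, reported for deep, shallow and
   total.  Across frames: means with population SDs, and count ratios
   against a reference membrane (e.g. sterol-free).

### The defect size constant

Defect areas pooled across frames are binned (1 Å² bins by default) into a
probability distribution P(x), and the small-defect regime is fit by

$$ P(x) = A\, e^{-x / A_0}, $$

with the decay constant A0 in Å² the *defect size constant*: larger A0
means relatively more large defects.  The fit is count-weighted least
squares on ln P(x) over occupied bins in `[fit_min, fit_max]`; counts are
the inverse-variance weights for log-counts, which keeps sparsely
populated tail bins from dominating.  `fit_max` defaults to the largest
bin still holding at least 5 counts, restricting the fit to the
well-sampled regime; the fit refuses (rather than extrapolates) when fewer
than 3 occupied bins or 50 samples fall in range.  `fit_size_constant()`
returns a classed model object with `print`, `summary`, `coef`, `predict`,
`residuals`, `simulate` and `plot` methods.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `cell_size` | 0.1 | nm | grid resolution; cell area is its square |
| `merge_distance` | 0.3 | nm | defect-cell merging radius (links up to 3rd-nearest cells) |
| `depth_threshold` | 0.1 | nm | deep plane depth below the glycerol level |
| `fit_min` | 5 | Å² | lower edge of the exponential fit window |
| `bin_width` | 1 | Å² | histogram bin width for the size distribution |
| vdW radii | Bondi | nm | element-keyed (H 0.120, C 0.170, N 0.155, O 0.152, P 0.180), overridable in the topology config |

Radii are element-based rather than force-field atom types so the analysis
is reproducible from coordinates plus a small text config alone.

## Interaction analyses

Hydrogen bonds use the standard geometric criterion — donor--acceptor
distance ≤ 0.35 nm and H--donor--acceptor angle ≤ 30° — with hydrogens
attached to the nearest N/O/S heavy atom within 0.12 nm, since GRO/PDB
coordinate files carry no bond records.  Only bonds crossing the
protein/membrane boundary are counted.  All distances use the minimum
image convention in the orthorhombic box.

Interaction energies are plain-truncation cutoff sums at 1.2 nm (12 Å):
Coulomb $f\,q_i q_j / r_{ij}$ with $f = 138.935485$ kJ mol⁻¹ nm e⁻², and
Lennard-Jones $4\varepsilon_{ij}[(\sigma_{ij}/r_{ij})^{12} -
(\sigma_{ij}/r_{ij})^6]$ with Lorentz--Berthelot combination.  These are
*cutoff-scheme* energies intended for relative and ensemble comparisons
and for testing the decomposition logic (by residue decade 1--10 ... 51--60
and by lipid species); they deliberately do not include mesh-Ewald
reciprocal-space terms, so absolute agreement with PME simulation output
is out of scope.  Per-lipid normalisation divides by *contact lipids* —
lipid residues with at least one atom within the cutoff of any protein
atom — since dividing by all lipids of a large patch would dilute the
quantity with non-interacting molecules.  Ensemble statistics follow the
multiple-independent-runs convention: the ensemble mean is the mean of run
means and the quoted spread is the SD across runs.

## The synthetic membrane generator

All tests run against synthetic bead bilayers rather than stored
simulation snapshots, so every expected value is a construction, not a
regression number.  `generate_bilayer()` emulates SV-like planar bilayers:

* two mirrored leaflets on a jittered square lattice (0.8 nm spacing,
  jitter SD 0.05 nm hard-clipped at 0.1 nm);
* phospholipid pseudo-species LPC/LPE/LPS, each a large head bead
  (radius 0.75 nm), a glycerol bead at a fixed level and two 2-bead tail
  chains below it; LPS carries the net −1 e headgroup charge;
* composition presets matching SV-like mixtures (12% PS + 20% PE + 68% PC,
  plus 10% or 40% sterol variants), apportioned by documented
  largest-remainder rounding;
* sterol-like LST with a small hydroxyl head bead (0.25 nm) and a neck
  bead; the condensation knob kappa in [0, 1] interpolates between uniform
  random sterol placement and growth of a single connected patch.

The head-bead radius was chosen from the coverage geometry: the farthest
cell center is $a/\sqrt{2} \approx 0.57$ nm from a lattice site, plus at
most ~0.14 nm of clipped jitter, so 0.75 nm guarantees that a sterol-free
leaflet covers every grid cell — zero defects by construction.  Defects
appear only where sterols cluster (four sterol lattice neighbours leave
their central plaquette unshielded) or where `carve_defect()` removes
coverage explicitly.

Condensation is modelled geometrically: a sterol with at least 3 of its 4
lattice neighbours sterol drops its neck bead below the deep plane,
mimicking the tighter, deeper exposure of a condensed patch, while
isolated sterols keep the neck just above the plane (shallow exposure).
Increasing kappa therefore shifts the defect population from many small
shallow defects to few large deep ones — the qualitative signature of
cholesterol condensation — and the package's trend test verifies exactly
that with a sign test across seeds.

`carve_defect()` provides exact ground truth: it removes the headgroup
atoms covering a chosen contiguous set of cells, re-covers every
collaterally exposed neighbour cell with a tiny patch bead at its center
(radius 0.03 nm, covering only its own cell), and either plants a tail
bead just above the deep plane in each target cell (shallow) or lowers
every above-plane atom overlapping the targets well below it (deep).
Carved regions keep ≥ 0.5 nm clearance from existing defects so the 0.3 nm
merge cannot connect them.  The z-architecture uses fixed per-bead levels
(no z jitter) with margins of several hundredths of a nanometre, so the
glycerol-plane shifts induced by carving (a few lipids lowered out of
hundreds) cannot flip a depth class.

### What the generator does not emulate

Bead lipids have no conformational disorder, no water, no thermal
roughness of the interface, and their defects are vacancy-like rather than
thermally transient.  Passing tests therefore demonstrate that the
*measurement machinery* — projection, overlap, merging, depth
classification, fitting, energy decomposition — is exact on systems with
known answers; they do not certify numerical values for any particular
all-atom force field or composition.  Real MD frames are analysed with the
same code paths via the GRO/PDB readers and a topology config describing
the force field's residues.

## Numerical and design choices

* Internal unit is nm everywhere; PDB Å values convert at the boundary.
  Boxes are orthorhombic only; triclinic input is rejected.
* The overlap inequality is the simplest reading consistent with
  projecting atoms onto the grid: center-to-projection distance ≤ radius.
  The brute-force oracle used in tests implements the same inequality
  independently (all atoms × all cells), so agreement checks the
  windowed implementation, not the definition.
* Leaflet assignment: midplane from the mean z of lipid phosphorus atoms
  (fallback: mean headgroup z); residues follow the sign of their mean
  headgroup z relative to it, ties to upper.  Residues whose headgroup
  atoms were removed (carved rim lipids) fall back to the mean over all
  their atoms.
* Defect statistics are computed per leaflet; the protein-facing upper
  leaflet is the default for protein systems, and `leaflet = "both"`
  reports each.
* Population SD across frames; SD of run means across independent runs.
* Cells with no underlying atom at all are deep: a fully exposed solvent
  channel is the deepest possible defect.
* Element inference takes the first alphabetic character after leading
  digits, which resolves both PDB-style hydrogen names ("1H5'") and the
  generator's single-letter pseudo-elements.

## Problem sizes

The shipped test-suite and acceptance analyses use leaflets of 16--256
lipids (boxes 3.2--12.8 nm), 1--3 carved defects of 1--8 cells, 5000
synthetic area samples for the A0 recovery study, 12 seeds for the
condensation trend, and 20 random systems for each oracle comparison —
sizes chosen so each property is sampled well while the whole suite stays
desk-scale.  Trajectory selection (first frame, stride, last frame) is
exposed as CLI options rather than hard-coded, since which frames of a
production run should enter the averages is a study-level decision.

## Known limitations

* Absolute interaction energies are cutoff-truncated and cannot be
  compared to Ewald-summed simulation output; only relative and ensemble
  comparisons are meaningful.
* The per-lipid energy normalisation (contact lipids) is one of several
  defensible conventions; the contact count is always reported so others
  can be derived.
* The depth threshold scan interpretation of "varying the defect
  threshold" (histogram over defect sizes with a small-defect fit) follows
  the established size-constant convention; a literal scan over the depth
  threshold is available through `depth_threshold` but is not the default
  analysis.
* Binary trajectory formats (XTC/TRR/DCD) and triclinic boxes are out of
  scope; convert to multi-model PDB or concatenated GRO first.
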