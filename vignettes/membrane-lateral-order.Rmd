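---
title: "Quantifying sterol lateral and orientational order in membrane leaflets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sterol lateral and orientational order in membrane leaflets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolorder)
```

## The scientific problem

Cholesterol orders fluid phospholipid bilayers and drives the formation of
the liquid-ordered phase and of cholesterol-enriched nanodomains. A striking
microscopic signature of this behavior is how sterols arrange *around each
other* within one leaflet: cholesterol avoids direct sterol-sterol contact
(the first coordination shell, roughly 0.4-0.8 nm between centers of mass,
is occupied almost exclusively by phospholipid acyl chains) and instead
accumulates in the second shell near 1 nm, where proximal sterols adopt a
three-fold symmetric arrangement tied to the two off-plane methyl groups
(C18, C19) on cholesterol's rough beta-face. A "flat" sterol with those
methyls removed loses the three-fold motif and organizes into linear arrays
instead. `sterolorder` implements the statistics needed to see all of this
in per-frame coordinate snapshots of a bilayer:

* per-leaflet lateral pair correlation functions `g(r)` and
  coordination-shell occupancy ratios ([lateral_rdf()],
  [shell_density_ratio()]);
* two-dimensional neighbor density maps in each sterol's *molecular* frame,
  with peak extraction ([accumulate_density_map()], [find_peaks()]);
* the co-localization angle between a first-shell phospholipid's chain-chain
  axis and the sterol-to-lipid vector, folded to the 90-degree
  representation ([theta90_distribution()]);
* sector-resolved relative-orientation distributions of sterol pairs in the
  second shell, via the in-plane C6-C11 vectors
  ([sector_orientation_distributions()]).

Because the statistics only make sense when validated, the package also
ships a synthetic leaflet generator with exhaustive ground truth
([generate_leaflet()]); every analysis stage is exercised against it in the
test suite without requiring molecular-dynamics trajectories.

## The molecular reference frame

Each sterol defines an orthonormal right-handed frame: the origin sits at
ring carbon C13, the x-axis points from C13 to the off-plane methyl C18,
and the xz-plane contains the C13-C10 vector (z toward the headgroup).
Neighbor positions are expressed in this frame and projected onto its
xy-plane, so density maps are averaged in a way that preserves the
molecule's faces: the smooth alpha-face lies toward -x, and the xz-plane
splits the rough beta-face into beta-1 (y > 0) and beta-2 (y < 0).

Two conventions are deliberately explicit because the underlying geometry
fixes only the x-axis and the xz-plane:

* **Handedness.** We take `ey = ez x ex`. Whether the beta-1 face of a
  physical cholesterol corresponds to +y in this convention cannot be
  decided from the frame definition alone; maps can be mirrored by negating
  frame y if a different assignment is preferred.
* **Sectors.** In-plane angles are measured anticlockwise from +x and
  partitioned into eight named sectors NE [22.5, 67.5), N [67.5, 122.5),
  NW [122.5, 157.5), W [157.5, 202.5), SW [202.5, 247.5), S [247.5, 292.5),
  SE [292.5, 337.5), E [337.5, 22.5). These ranges are used verbatim (N
  spans 55 degrees and NW 35; together they tile the circle), and the
  intervals are half-open with exact boundaries assigned to the
  anticlockwise-later sector.

For the flat sterol analogue (species `DCHL`) the missing C18 is rebuilt by
tetrahedral reconstruction from C13's three remaining substituents
([reconstruct_tetrahedral_substituent()]), with a standard 0.153 nm C-C
bond, so that its frame (and hence its alpha/beta faces) can be defined
exactly like cholesterol's.

## Key parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| first coordination shell | 0.4-0.8 nm | sterol-sterol COM range of the contact shell |
| second coordination shell | 0.8-1.1 nm | capped at 1.1 nm to exclude third-shell contributions |
| first-shell lipid cutoff | 0.75 nm | max lateral chain-COM distance for co-localization pairs |
| `g(r)` bin width | 0.01 nm | resolves the sub-peaks near 0.45/0.65/0.73 nm |
| density-map grid | extent 2.5 nm, bin 0.05 nm | frame-xy window around each sterol |
| angle histogram bins | 5 degrees | both theta-90 and relative-orientation domains |

All distances are lateral (in-plane) minimum-image COM separations within
one leaflet: the analyses describe in-plane organization, sterol COMs in a
leaflet share a narrow z-slab, and cross-leaflet pairs are excluded
throughout (leaflets are assigned per frame from the headgroup-anchor height
relative to the mass-weighted z-centroid; see [assign_leaflets()]). A
3D-distance mode is available in [lateral_rdf()] for comparison. Centers of
mass are mass-weighted with united-atom masses by default (a geometric mode
exists), computed on whole (unwrapped) molecules. For the co-localization
reference vector we anchor at the sterol *ring* COM; anchoring at the
whole-molecule COM is available via `sterol_anchor = "molecule"` since both
conventions appear in the literature describing this statistic.

## What the synthetic generator emulates

[generate_leaflet()] places rigid molecular templates in a periodic box,
rotated only about the membrane normal: sterols stand upright (zero tilt),
so each molecule's frame xy-plane coincides with the lab plane and recorded
placement angles are directly frame angles. The default composition is a
128-phospholipid leaflet with a 20 mol% sterol fraction (32 sterols,
`mole_fraction_to_counts()`), in a box sized at 0.5 nm^2 per molecule —
about the equilibrium area per molecule of a saturated-PC/cholesterol
membrane at that composition. Four ordering modes are provided:

* `csr` — uniform random placement (the null model for `g(r) = 1`);
* `hard_disk` — dart throwing with a minimum-image exclusion radius;
* `triangular` — isolated motifs: each motif center receives satellites at
  frame angles {180, 45, 315} (the alpha/beta1/beta2 sector centers read
  off the three-fold map) at a set spacing (default 1.0 nm) with Gaussian
  angular jitter; motif centers are kept far enough apart that no
  inter-motif pair can enter the second shell;
* `linear` — the same construction with satellites at {0, 180}, emulating
  the two-fold organization of the flat sterol.

Satellites default to a fixed 180-degree orientation offset from their
center. This choice makes a motif self-consistent: because the satellite's
frame is the center's frame rotated by 180 degrees, every member sees its
partners at the *same* frame angles, so the recovered map peaks are the set
angles regardless of which molecule acts as reference. Orientation offsets
can instead be drawn von Mises or uniformly; placement angles for
first-shell lipids, and their orientation rule (`facing`, `collinear`,
`uniform`), are likewise configurable.

The ground-truth table records, per frame and molecule: position, rotation,
role (motif center, satellite, shell lipid, bulk), motif membership, the
jittered placement angle and radius, and the drawn orientation offset. Every
downstream statistic can be predicted from this table by direct enumeration,
which is exactly how the test suite validates the analysis chain.

**What the generator does not emulate** — and hence what passing tests do
not show about real membranes: sterol tilt and chain conformational
disorder (molecules are rigid and upright, so frame-projected and lateral
radii coincide more tightly than in a simulation), thermal density
fluctuations beyond placement jitter, flip-flop, correlated inter-motif
structure, and any energetics. Statistical recovery on these
configurations validates the estimators, not the physics.

## Numerical choices and degenerate inputs

* Bin conventions: radial bins and shells are left-open/right-closed, so a
  COM pair at exactly 0.8 nm belongs to the first shell; angle histograms
  are left-closed on a domain that tiles [0, 90] or [0, 360); sector
  boundaries go to the anticlockwise-later sector. Shell ratios computed
  directly agree with the annulus-area-weighted mean of `g(r)` to 1e-9 when
  bin edges align (regression-tested).
* `g(r)` normalization is per leaflet with the self-pair excluded: the
  target density uses `(N - 1)/A` when reference and target species
  coincide, which makes the CSR expectation exactly 1 at finite N.
* Frame construction rejects coincident or collinear C13/C18/C10 input;
  tetrahedral reconstruction rejects planar-symmetric substituents (zero
  bond-vector sum). Both raise classed degenerate-geometry errors rather
  than returning NaNs.
* Peak finding takes local maxima over the 8-neighborhood inside a radial
  band, thresholded at a multiple (default 2) of the in-band mean, then
  greedily pruned so no two peaks lie within the minimum separation
  (highest first). On sparse synthetic maps a pruning radius of 0.4 nm
  absorbs the deterministic secondary atom columns of a rigid template,
  which lie within 0.27 nm of each main peak.
* Ordered-pair bookkeeping in the orientation analysis means each unordered
  sterol pair contributes twice, once per choice of central molecule. A
  consequence worth knowing: the reverse view of a pair whose offset
  distribution is centered at mu appears at 360 - offset, and the tail of
  that reflected population can leak into the sector under study (about 4%
  for von Mises mu = 120, kappa = 8 in sector W), shifting the sector's
  plain circular mean by a couple of degrees. Recovery of an orientation
  rule is therefore best done over identified pairs; the sector histograms
  remain exact counts of what is in each sector.
* Histogram edge ties: a generator rule that produces angles exactly on a
  histogram bin edge (e.g. a fixed 180-degree offset with 5-degree bins) is
  assigned deterministically to the right-open bin, but an infinitesimal
  rigid rotation of the input can move such a sample across the edge; the
  equivariance tests therefore use generic (uniform) orientations.

## Problem sizes used in the validation suite

The statistical checks run at sizes chosen to make their Monte-Carlo bands
tight while staying desk-scale: the CSR null uses 250 molecules over 200
frames (g(r) flat within 3 sigma on 0.05 nm bins across 0.3-2.0 nm; shell
ratios within 0.05 of 1); three-fold recovery uses 80 sterols over 40
frames in a 30 nm box (exactly three peaks, each within one 0.05 nm /
5-degree bin of the set positions); brute-force equality checks run on
50-molecule fixtures; von Mises recovery uses 5000 pairs. The
`scripts/acceptance.R` script reruns all of these from scratch.

## Interfaces

The package is driven from R; [validate_config()] and [run_pipeline()]
provide a config-file front end (YAML in, delimited tables plus a JSON
summary with config hash, seed and package version out) for scripted,
reproducible runs, and `scripts/acceptance.R` is a ready-made command-line
entry point for the validation quantities. Coordinate I/O covers the GRO
and PDB dialects ([read_snapshots()], [write_snapshots()]); binary
trajectory formats (XTC/TRR/DCD) are out of scope — an adapter only needs
to produce `mem_snapshot` objects (atom table plus box) to plug in.

## Known limitations

* Rigid-template synthesis only; no sterol tilt, so analyses that would
  distinguish frame-projected from lab-lateral radii are exercised in the
  regime where they agree.
* The PDB dialect carries one box (CRYST1) per file; fluctuating-box
  trajectories should use GRO.
* Leaflet assignment assumes a planar bilayer with a meaningful z-midplane;
  strongly curved or vesicular geometries are out of scope.
* Quantitative values for real DSPC/DOPC-cholesterol membranes (shell
  ratios, equilibrium areas, peak positions) come from hundreds of
  nanoseconds of atomistic MD and are not reproduced here — they require
  such trajectories as input; this package provides the measurement
  machinery and validates it on synthetic ground truth.
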