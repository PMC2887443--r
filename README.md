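# sterolorder

Lateral and orientational order statistics for sterol-phospholipid
membrane leaflets.

Cholesterol's ordering of fluid membranes has a distinctive microscopic
signature: sterols avoid direct contact (their first coordination shell,
0.4-0.8 nm between lateral centers of mass, is filled by phospholipid acyl
chains) and accumulate in the second shell near 1 nm, where neighboring
sterols sit in a three-fold pattern — one site facing the smooth
alpha-face, and one each on the beta-1/beta-2 sub-faces defined by the two
off-plane methyls C18/C19. A flat sterol lacking those methyls organizes
linearly instead. `sterolorder` measures these signatures in per-frame
coordinate snapshots (GRO/PDB), for anyone analyzing atomistic membrane
simulations or building null models of leaflet organization:

- **`lateral_rdf()` / `shell_density_ratio()`** — per-leaflet lateral pair
  correlation `g(r) = rho(r) / rho_mean` between molecular centers of mass
  (minimum-image, in-plane, self-pair excluded) and the density ratio
  inside the first (0.4-0.8 nm) and second (0.8-1.1 nm) coordination
  shells.
- **`accumulate_density_map()` / `find_peaks()`** — 2D neighbor density in
  each sterol's molecular frame (origin C13, x along C13->C18, xz-plane
  through C13->C10), in atoms/nm^2 per reference per frame, with local-max
  peak extraction and sector labels.
- **`theta90_distribution()`** — the co-localization angle between a
  first-shell lipid's sn-1->sn-2 chain-COM vector and the sterol-to-lipid
  vector, folded to theta_90 = 90 - |90 - theta| (0 = collinear, 90 =
  facing), optionally resolved by angular sector.
- **`sector_orientation_distributions()`** — relative orientation of
  C6-C11 vectors for sterol pairs in the second shell, per sector
  (alpha = W, beta1 = NE, beta2 = SE highlighted).
- **`generate_leaflet()`** — synthetic leaflets with recorded ground truth
  (CSR, hard-disk, triangular three-fold, linear two-fold order), used by
  the whole test suite; `run_pipeline()` drives end-to-end runs from a
  YAML config.

Species roles (frame atoms, ring atoms, chains, anchors, united-atom
masses) come from a YAML species map; defaults for `CHOL` (17 ring sites),
`DCHL` (the flat analogue, 15 sites, off-plane methyls rebuilt by
tetrahedral reconstruction), `DSPC` and `DOPC` are bundled.

## Worked example

Generate a leaflet of 40 sterols arranged in triangular motifs (satellites
1.0 nm from their motif center at frame angles 180/45/315 with 5 degrees of
jitter), then recover the imposed order:

```r
library(sterolorder)
sm  <- load_species_map()
gen <- generate_leaflet(generator_params(
  n_lipids = 0, n_sterols = 40, mode = "triangular", box = c(24, 24, 10),
  spacing = 1.0, angular_jitter = 5, n_frames = 20, seed = 1))

shell_density_ratio(gen$snapshots, "CHOL", "CHOL", sm)
#> Coordination-shell density ratios for CHOL-CHOL over 20 frame(s)
#>    shell r_lo r_hi count    ratio
#> 1  first  0.4  0.8     0  0.00000
#> 2 second  0.8  1.1  1202 12.39218

dm <- accumulate_density_map(gen$snapshots, "CHOL", "CHOL", sm)
find_peaks(dm, threshold = 2, min_separation = 0.4, radial_band = c(0.8, 1.1))
#>        x      y         r       phi height sector
#> 1  0.725  0.675 0.9905806  42.95459    284     NE
#> 2 -0.975 -0.025 0.9753205 181.46880    250      W
#> 3  0.675 -0.725 0.9905806 312.95459    231     SE
```

The shell table says no sterol pair ever enters the contact shell (ratio
0), while the second shell is 12x enriched over the mean density — the
avoided-contact pattern. The three map peaks sit at radius ~1.0 nm and
angles ~45/181/313 degrees in the NE/W/SE sectors: the generator's
three-fold motif, recovered to within one grid bin. `plot(dm)` renders the
map.

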