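Package: sterolorder
Title: Lateral and Orientational Order Statistics for Sterol-Phospholipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of lateral organization in sterol/phospholipid bilayer
    snapshots: per-leaflet lateral pair-correlation functions and
    coordination-shell occupancy ratios, two-dimensional neighbor density maps
    in the sterol molecular reference frame with peak extraction,
    co-localization angle (theta-90) distributions between phospholipid acyl
    chains and proximal sterols, and sector-resolved relative-orientation
    distributions of sterol pairs in the second coordination shell. Reads and
    writes GRO and PDB coordinate snapshots, maps atoms to semantic roles via
    a species-map configuration, and ships a synthetic leaflet generator with
    recorded ground truth (random, hard-disk, triangular three-fold and
    linear two-fold spatial order) so every statistic can be validated
    without molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
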