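# Synthetic leaflet generator with recorded ground truth.
#
# Molecules are rigid templates rotated about the lab z-axis only (sterol
# long axis perpendicular to the membrane plane, zero tilt), anchored by the
# template origin (C13 for sterols, the chain midpoint axis for PCs). This
# makes each molecule's frame xy-plane coincide with the lab xy-plane, so
# placement angles recorded in the ground truth are directly frame angles.

#' Generator parameters
#'
#' Validates and defaults the parameters of [generate_leaflet()]. Default
#' composition is a 128-phospholipid leaflet with a 20 mol% sterol fraction
#' (32 sterols) in a box sized at 0.5 nm^2 per molecule.
#'
#' @param n_lipids Number of phospholipids (>= 0).
#' @param n_sterols Number of sterols; if `NULL`, derived from
#'   `sterol_fraction` via [mole_fraction_to_counts()].
#' @param sterol_fraction Sterol mole fraction in \[0, 1).
#' @param lipid_species,sterol_species Species names (must have rigid
#'   templates: DSPC/DOPC, CHOL/DCHL).
#' @param box Lateral box lengths `c(Lx, Ly)` or full `c(Lx, Ly, Lz)` in nm;
#'   `NULL` sizes a square box at `area_per_molecule` per molecule, Lz 10.
#' @param area_per_molecule Footprint used to auto-size the box (nm^2).
#' @param mode Spatial ordering: `"csr"` (uniform placement), `"hard_disk"`
#'   (dart throwing with exclusion radius `hard_core`), `"triangular"`
#'   (each motif center given satellites at frame angles
#'   `motif_angles`, default 180/45/315, at `spacing`), `"linear"`
#'   (satellites at 0/180).
#' @param spacing Center-satellite distance in nm (default 1.0).
#' @param angular_jitter SD of the satellite placement angle, degrees.
#' @param radial_jitter SD of the satellite distance, nm.
#' @param motif_angles Satellite frame angles (degrees); `NULL` takes the
#'   mode default.
#' @param orientation Orientation-offset rule for satellites relative to
#'   their motif center: `list(rule = "fixed", offset = 180)` (default;
#'   this makes the motif look identical from every member's frame),
#'   `list(rule = "vonmises", mu = , kappa = )`, or
#'   `list(rule = "uniform")`.
#' @param lipid_placement `list(rule = "uniform")` (default) or
#'   `list(rule = "shell", radius = 0.5, angles = c(...), orientation =
#'   "facing"|"collinear"|"uniform", per_sterol = k)` which rings each
#'   sterol with `k` lipids at the given first-shell frame angles before
#'   distributing the remainder uniformly.
#' @param hard_core Exclusion radius for `hard_disk` mode (nm).
#' @param n_frames Number of independently re-drawn frames.
#' @param seed RNG seed; identical params + seed give identical output.
#' @param bilayer If `TRUE`, a mirrored second leaflet (independent lateral
#'   placements) is added below the first.
#' @param area_jitter_sd Per-frame Gaussian SD of the lateral box area
#'   (nm^2); placements scale affinely with the box.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(n_lipids = 128, n_sterols = NULL,
                             sterol_fraction = 0.2,
                             lipid_species = "DSPC", sterol_species = "CHOL",
                             box = NULL, area_per_molecule = 0.5,
                             mode = c("csr", "hard_disk", "triangular", "linear"),
                             spacing = 1.0, angular_jitter = 5,
                             radial_jitter = 0, motif_angles = NULL,
                             orientation = list(rule = "fixed", offset = 180),
                             lipid_placement = list(rule = "uniform"),
                             hard_core = 0.45, n_frames = 50, seed = 1,
                             bilayer = FALSE, area_jitter_sd = 0) {
  mode <- match.arg(mode)
  if (is.null(n_sterols)) {
    n_sterols <- mole_fraction_to_counts(n_lipids, sterol_fraction)
  }
  stopifnot(n_lipids >= 0, n_sterols >= 0, n_lipids + n_sterols > 0,
            spacing > 0, angular_jitter >= 0, radial_jitter >= 0,
            hard_core > 0, n_frames >= 1)
  if (mode == "hard_disk" && hard_core >= spacing) {
    so_stop("hard-core radius must be smaller than the neighbor spacing",
            "sterolorder_config_error")
  }
  if (is.null(motif_angles)) {
    motif_angles <- switch(mode, triangular = c(180, 45, 315),
                           linear = c(0, 180), NULL)
  }
  if (is.null(box)) {
    L <- sqrt((n_lipids + n_sterols) * area_per_molecule)
    box <- c(L, L, 10)
  } else if (length(box) == 2) box <- c(box, 10)
  stopifnot(length(box) == 3, all(box > 0))
  if (!orientation$rule %in% c("fixed", "vonmises", "uniform")) {
    so_stop("orientation$rule must be fixed, vonmises or uniform",
            "sterolorder_config_error")
  }
  if (!lipid_placement$rule %in% c("uniform", "shell")) {
    so_stop("lipid_placement$rule must be uniform or shell",
            "sterolorder_config_error")
  }
  if (lipid_placement$rule == "shell") {
    if (is.null(lipid_placement$radius)) lipid_placement$radius <- 0.5
    if (is.null(lipid_placement$angles)) {
      lipid_placement$angles <- c(90, 162, 234, 306, 18)
    }
    if (is.null(lipid_placement$orientation)) lipid_placement$orientation <- "uniform"
    if (is.null(lipid_placement$per_sterol)) {
      lipid_placement$per_sterol <- length(lipid_placement$angles)
    }
  }
  structure(list(n_lipids = as.integer(n_lipids),
                 n_sterols = as.integer(n_sterols),
                 lipid_species = lipid_species, sterol_species = sterol_species,
                 box = as.numeric(box), mode = mode, spacing = spacing,
                 angular_jitter = angular_jitter, radial_jitter = radial_jitter,
                 motif_angles = motif_angles, orientation = orientation,
                 lipid_placement = lipid_placement, hard_core = hard_core,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 bilayer = isTRUE(bilayer), area_jitter_sd = area_jitter_sd),
            class = "generator_params")
}

#' Sterol count from a mole fraction
#'
#' `n_sterols = round(n_lipids * f / (1 - f))`, e.g. 128 lipids at 20 mol%
#' give 32 sterols and at 10 mol% give 14.
#'
#' @param n_lipids Number of phospholipids.
#' @param fraction Sterol mole fraction in \[0, 1).
#' @return Integer sterol count.
#' @export
mole_fraction_to_counts <- function(n_lipids, fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1) {
    so_stop("sterol fraction must lie in [0, 1)", "sterolorder_input_error")
  }
  as.integer(round(n_lipids * fraction / (1 - fraction)))
}

# dart-throwing with minimum-image exclusion; returns n x 2 positions
dart_throw <- function(n, box, min_dist, existing = NULL,
                       max_attempts = 2000L * max(n, 1L)) {
  pts <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(pts) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    p <- c(runif(1, 0, box[1]), runif(1, 0, box[2]))
    ref <- rbind(existing, pts)
    if (nrow(ref)) {
      dx <- min_image_1d(ref[, 1] - p[1], box[1])
      dy <- min_image_1d(ref[, 2] - p[2], box[2])
      if (min(dx^2 + dy^2) < min_dist^2) next
    }
    pts <- rbind(pts, p)
  }
  if (nrow(pts) < n) {
    so_stop(sprintf(
      "packing failed: placed %d of %d points at exclusion %.2f nm (achieved density %.3f nm^-2)",
      nrow(pts), n, min_dist, nrow(pts) / (box[1] * box[2])),
      "sterolorder_packing_error")
  }
  pts
}

# one leaflet's placement table for one frame
place_leaflet_frame <- function(p) {
  box <- p$box
  ns <- p$n_sterols; nl <- p$n_lipids
  rows <- list()
  add <- function(species, x, y, psi, role, motif = NA_integer_,
                  place_angle = NA_real_, place_radius = NA_real_,
                  orient_offset = NA_real_, anchor = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      species = species, x = x, y = y, psi = psi, role = role,
      motif = motif, place_angle = place_angle, place_radius = place_radius,
      orient_offset = orient_offset, anchor = anchor,
      stringsAsFactors = FALSE)
  }
  draw_offset <- function(n) {
    o <- p$orientation
    switch(o$rule,
           fixed = rep(if (is.null(o$offset)) 180 else o$offset, n),
           vonmises = rvonmises_deg(n, o$mu, o$kappa),
           uniform = runif(n, 0, 360))
  }
  if (p$mode %in% c("csr", "hard_disk") && ns > 0) {
    pts <- if (p$mode == "csr") {
      cbind(runif(ns, 0, box[1]), runif(ns, 0, box[2]))
    } else dart_throw(ns, box, p$hard_core)
    add(rep(p$sterol_species, ns), pts[, 1], pts[, 2], runif(ns, 0, 360),
        rep("free", ns))
  } else if (ns > 0) {
    k <- length(p$motif_angles)
    n_centers <- ns %/% (k + 1L)
    n_free <- ns - n_centers * (k + 1L)
    centers <- dart_throw(n_centers, box, 2 * p$spacing + 1.4)
    psi_c <- runif(n_centers, 0, 360)
    if (n_centers > 0) {
      add(rep(p$sterol_species, n_centers), centers[, 1], centers[, 2], psi_c,
          rep("center", n_centers), motif = seq_len(n_centers))
      for (m in seq_len(n_centers)) {
        ang <- p$motif_angles + rnorm(k, 0, p$angular_jitter)
        rad <- p$spacing + rnorm(k, 0, p$radial_jitter)
        off <- draw_offset(k)
        lab <- psi_c[m] + ang
        add(rep(p$sterol_species, k),
            (centers[m, 1] + rad * cos(deg2rad(lab))) %% box[1],
            (centers[m, 2] + rad * sin(deg2rad(lab))) %% box[2],
            wrap360(psi_c[m] + off), rep("satellite", k),
            motif = rep(m, k), place_angle = wrap360(ang),
            place_radius = rad, orient_offset = off, anchor = rep(m, k))
      }
    }
    if (n_free > 0) {
      placed <- do.call(rbind, lapply(rows, function(r) cbind(r$x, r$y)))
      free <- dart_throw(n_free, box, p$spacing + 0.5, existing = placed)
      add(rep(p$sterol_species, n_free), free[, 1], free[, 2],
          runif(n_free, 0, 360), rep("free", n_free))
    }
  }
  sterol_tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (nl > 0) {
    lp <- p$lipid_placement
    n_left <- nl
    if (lp$rule == "shell" && !is.null(sterol_tab) && nrow(sterol_tab)) {
      for (i in seq_len(nrow(sterol_tab))) {
        kk <- min(lp$per_sterol, n_left)
        if (kk <= 0) break
        ang <- lp$angles[seq_len(kk)]
        lab <- sterol_tab$psi[i] + ang
        px <- (sterol_tab$x[i] + lp$radius * cos(deg2rad(lab))) %% box[1]
        py <- (sterol_tab$y[i] + lp$radius * sin(deg2rad(lab))) %% box[2]
        psi_l <- switch(lp$orientation,
                        facing = lab + 90,
                        collinear = lab,
                        uniform = runif(kk, 0, 360))
        add(rep(p$lipid_species, kk), px, py, wrap360(psi_l),
            rep("shell_lipid", kk), place_angle = wrap360(ang),
            place_radius = rep(lp$radius, kk), anchor = rep(i, kk))
        n_left <- n_left - kk
      }
    }
    if (n_left > 0) {
      add(rep(p$lipid_species, n_left), runif(n_left, 0, box[1]),
          runif(n_left, 0, box[2]), runif(n_left, 0, 360),
          rep("bulk", n_left))
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic leaflet snapshots with ground truth
#'
#' Builds `n_frames` independently drawn configurations of rigid-template
#' molecules in a periodic box according to the ordering mode, returning
#' both the snapshots and a ground-truth table recording every placement
#' (position, rotation, role, motif membership, placement angle/distance,
#' orientation offset, leaflet). Identical parameters and seed reproduce
#' the output exactly.
#'
#' @param params A `generator_params` object (or arguments for one, passed
#'   via `...`).
#' @param ... Used to build `params` when it is not supplied.
#' @return List with `snapshots` (list of `mem_snapshot`, leaflets
#'   labelled), `ground_truth` (data.frame) and `params`.
#' @export
generate_leaflet <- function(params = NULL, ...) {
  if (is.null(params)) params <- generator_params(...)
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, {
    snaps <- vector("list", params$n_frames)
    gt <- vector("list", params$n_frames)
    templates <- list()
    for (sp in unique(c(params$sterol_species, params$lipid_species))) {
      templates[[sp]] <- template_for(sp)
    }
    for (f in seq_len(params$n_frames)) {
      box <- params$box
      scale <- 1
      if (params$area_jitter_sd > 0) {
        a0 <- box[1] * box[2]
        a <- max(a0 + rnorm(1, 0, params$area_jitter_sd), 0.5 * a0)
        scale <- sqrt(a / a0)
        box[1:2] <- box[1:2] * scale
      }
      pb <- params; pb$box <- box
      tab <- place_leaflet_frame(pb)
      tab$leaflet <- "upper"
      tab$z0 <- 5.0
      tab$mirror <- FALSE
      if (params$bilayer) {
        tab2 <- place_leaflet_frame(pb)
        tab2$leaflet <- "lower"
        tab2$z0 <- 5.0
        tab2$mirror <- TRUE
        tab <- rbind(tab, tab2)
      }
      tab$molid <- seq_len(nrow(tab))
      snaps[[f]] <- build_frame_snapshot(tab, box, templates, f)
      gt[[f]] <- cbind(frame = f, tab[, c("molid", "species", "leaflet", "x",
                                          "y", "psi", "role", "motif",
                                          "place_angle", "place_radius",
                                          "orient_offset", "anchor")])
    }
    list(snapshots = snaps, ground_truth = do.call(rbind, gt), params = params)
  })
}

build_frame_snapshot <- function(tab, box, templates, frame_index) {
  n_at <- vapply(tab$species, function(sp) nrow(templates[[sp]]), numeric(1))
  idx <- rep(seq_len(nrow(tab)), n_at)
  tm <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    t0 <- templates[[tab$species[i]]]
    if (tab$mirror[i]) t0[, 3] <- -t0[, 3]
    t0
  }))
  cs <- cos(deg2rad(tab$psi))[idx]
  sn <- sin(deg2rad(tab$psi))[idx]
  x <- tab$x[idx] + cs * tm[, 1] - sn * tm[, 2]
  y <- tab$y[idx] + sn * tm[, 1] + cs * tm[, 2]
  z <- tab$z0[idx] + tm[, 3]
  atoms <- data.frame(molid = tab$molid[idx], species = tab$species[idx],
                      name = rownames(tm), x = x, y = y, z = z,
                      stringsAsFactors = FALSE)
  snapshot(atoms, box, frame_index = frame_index,
           time = as.numeric(frame_index),
           leaflet = stats::setNames(tab$leaflet, tab$molid))
}
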