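# First-shell lipid selection and co-localization angle (theta-90) analysis.

# per-lipid chain geometry: sn-1 COM, sn-2 COM and lateral chain separation
chain_geometry <- function(snap, species_map, lipid_species) {
  c1 <- com_table(snap, species_map, lipid_species, subset = "sn1")
  c2 <- com_table(snap, species_map, lipid_species, subset = "sn2")
  stopifnot(identical(c1$molid, c2$molid))
  data.frame(molid = c1$molid, species = c1$species, leaflet = c1$leaflet,
             s1x = c1$x, s1y = c1$y, s1z = c1$z,
             s2x = c2$x, s2y = c2$y, s2z = c2$z,
             separation = sqrt((c2$x - c1$x)^2 + (c2$y - c1$y)^2),
             stringsAsFactors = FALSE)
}

#' Select first-shell lipids around a sterol
#'
#' A lipid belongs to the first coordination shell of a sterol when the
#' lateral minimum-image distance from the center of mass of at least one
#' of its acyl chains to the sterol's center of mass is at most `cutoff`
#' (default 0.75 nm). Each lipid is reported at most once; only lipids in
#' the sterol's leaflet are considered.
#'
#' @param snap A `mem_snapshot`.
#' @param sterol_id Molecule id of the reference sterol.
#' @param species_map A `species_map`.
#' @param cutoff First-shell cutoff in nm (default 0.75).
#' @param lipid_species Optional restriction to given phospholipid species.
#' @param sterol_anchor `"ring"` (ring-atom COM, default) or `"molecule"`
#'   (whole-molecule COM) as the sterol-side reference point.
#' @return Integer vector of lipid molecule ids (possibly empty).
#' @export
select_first_shell_lipids <- function(snap, sterol_id, species_map,
                                      cutoff = 0.75, lipid_species = NULL,
                                      sterol_anchor = c("ring", "molecule")) {
  sterol_anchor <- match.arg(sterol_anchor)
  sp <- snap$molecules$species[match(sterol_id, snap$molecules$molid)]
  if (is.na(sp) || species_map[[sp]]$kind != "sterol") {
    so_stop(sprintf("molecule %s is not a sterol in this snapshot", sterol_id),
            "sterolorder_input_error")
  }
  scom <- com_table(snap, species_map, sp,
                    subset = if (sterol_anchor == "ring") "ring" else "all")
  scom <- scom[scom$molid == sterol_id, , drop = FALSE]
  if (is.null(lipid_species)) {
    lipid_species <- species_of_kind(species_map, "phospholipid")
  }
  cg <- chain_geometry(snap, species_map, lipid_species)
  cg <- cg[cg$leaflet == scom$leaflet, , drop = FALSE]
  if (!nrow(cg)) return(integer(0))
  p <- c(scom$x, scom$y, 0)
  d1 <- min_image_lateral_distance(cbind(cg$s1x, cg$s1y, 0),
                                   matrix(p, nrow(cg), 3, byrow = TRUE), snap$box)
  d2 <- min_image_lateral_distance(cbind(cg$s2x, cg$s2y, 0),
                                   matrix(p, nrow(cg), 3, byrow = TRUE), snap$box)
  cg$molid[pmin(d1, d2) <= cutoff]
}

#' Co-localization angle between a lipid's chains and a sterol
#'
#' The angle between the lateral projections of (a) the vector joining the
#' sn-1 and sn-2 acyl-chain centers of mass and (b) the vector from the
#' sterol center of mass to the midpoint of the two chain COMs.
#'
#' @param sterol_com Sterol-side reference point (length-3, nm).
#' @param sn1_com,sn2_com Acyl-chain centers of mass (length-3, nm).
#' @param box Optional box for minimum-image displacements.
#' @return Angle theta in degrees on \[0, 180\].
#' @export
colocalization_angle <- function(sterol_com, sn1_com, sn2_com, box = NULL) {
  s <- as_point3(sterol_com, "sterol_com")
  p1 <- as_point3(sn1_com, "sn1_com")
  p2 <- as_point3(sn2_com, "sn2_com")
  d1 <- p1 - s; d2 <- p2 - s
  if (!is.null(box)) {
    d1 <- as.vector(min_image_disp(matrix(d1, 1), box))
    d2 <- as.vector(min_image_disp(matrix(d2, 1), box))
  }
  v_chains <- (d2 - d1)[1:2]
  v_ref <- ((d1 + d2) / 2)[1:2]
  n1 <- sqrt(sum(v_chains^2)); n2 <- sqrt(sum(v_ref^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    so_stop("undefined co-localization angle: zero-length lateral projection",
            "sterolorder_degenerate_geometry")
  }
  rad2deg(acos(pmin(1, pmax(-1, sum(v_chains * v_ref) / (n1 * n2)))))
}

#' Fold theta onto the 90-degree representation
#'
#' Both acyl chains are treated as equivalent: theta-90 = 90 - |90 - theta|,
#' mapping \[0, 180\] onto \[0, 90\]. 0 is the collinear arrangement, 90 the
#' `facing' one; the fold is invariant under swapping the chain labels
#' (theta -> 180 - theta).
#'
#' @param theta Angle(s) in degrees on \[0, 180\].
#' @return theta-90 in degrees on \[0, 90\].
#' @export
fold_theta90 <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 180)) {
    so_stop("theta must lie in [0, 180] degrees", "sterolorder_input_error")
  }
  90 - abs(90 - theta)
}

# shared binned angular distribution container
angle_distribution <- function(values, domain, bin_width, n_pairs = length(values)) {
  edges <- seq(domain[1], domain[2], by = bin_width)
  nb <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)
  counts <- if (length(values)) tabulate(idx, nbins = nb) else integer(nb)
  out <- data.frame(lo = edges[-length(edges)], hi = edges[-1],
                    mid = (edges[-1] + edges[-length(edges)]) / 2,
                    count = counts,
                    freq = if (sum(counts) > 0) counts / sum(counts) else rep(0, nb))
  structure(out, class = c("angle_distribution", "data.frame"),
            domain = domain, n_pairs = n_pairs, empty = n_pairs == 0)
}

#' @export
print.angle_distribution <- function(x, ...) {
  d <- attr(x, "domain")
  cat(sprintf("Angle distribution on [%g, %g) deg, %d pair(s)%s\n", d[1], d[2],
              attr(x, "n_pairs"), if (attr(x, "empty")) " [empty]" else ""))
  NextMethod()
}

# enumerate (sterol, first-shell lipid) pair angles across frames
theta90_pairs <- function(snapshots, sterol_species, lipid_species, species_map,
                          cutoff, sterol_anchor) {
  res <- list()
  for (s in snapshots) {
    anchor <- if (sterol_anchor == "ring") "ring" else "all"
    scom <- com_table(s, species_map, sterol_species, subset = anchor)
    cg <- chain_geometry(s, species_map, lipid_species)
    frames <- sterol_frames(s, species_map, sterol_species)
    for (i in seq_len(nrow(scom))) {
      lf <- scom$leaflet[i]
      cands <- cg[cg$leaflet == lf, , drop = FALSE]
      if (!nrow(cands)) next
      p <- c(scom$x[i], scom$y[i], scom$z[i])
      d1m <- min_image_disp(cbind(cands$s1x - p[1], cands$s1y - p[2],
                                  cands$s1z - p[3]), s$box)
      d2m <- min_image_disp(cbind(cands$s2x - p[1], cands$s2y - p[2],
                                  cands$s2z - p[3]), s$box)
      r1 <- sqrt(d1m[, 1]^2 + d1m[, 2]^2)
      r2 <- sqrt(d2m[, 1]^2 + d2m[, 2]^2)
      sel <- which(pmin(r1, r2) <= cutoff)
      if (!length(sel)) next
      fr <- frames[[as.character(scom$molid[i])]]
      for (j in sel) {
        vc <- c(d2m[j, 1] - d1m[j, 1], d2m[j, 2] - d1m[j, 2])
        vr <- c((d1m[j, 1] + d2m[j, 1]) / 2, (d1m[j, 2] + d2m[j, 2]) / 2)
        n1 <- sqrt(sum(vc^2)); n2 <- sqrt(sum(vr^2))
        if (n1 < 1e-12 || n2 < 1e-12) next
        theta <- rad2deg(acos(pmin(1, pmax(-1, sum(vc * vr) / (n1 * n2)))))
        mid_lab <- p + c((d1m[j, ] + d2m[j, ]) / 2)
        sec <- if (!is.null(fr)) {
          fc <- to_frame_coords(fr, mid_lab)
          sector_of(fc$phi)
        } else NA_character_
        res[[length(res) + 1L]] <- c(theta = theta, sector = sec,
                                     sterol = scom$molid[i],
                                     lipid = cands$molid[j],
                                     frame = s$frame_index)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(theta = numeric(0), sector = character(0),
                      sterol = integer(0), lipid = integer(0),
                      frame = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  df$theta <- as.numeric(df$theta)
  df$sterol <- as.integer(df$sterol)
  df$lipid <- as.integer(df$lipid)
  df$frame <- as.integer(df$frame)
  df
}

#' Co-localization angle distribution (theta-90)
#'
#' Histogram of the folded co-localization angle over all (sterol,
#' first-shell lipid) pairs across all frames. With `sector_resolved =
#' TRUE`, pairs are split by the angular sector of the lipid chain midpoint
#' in the sterol's molecular frame and one distribution per sector is
#' returned.
#'
#' @inheritParams select_first_shell_lipids
#' @param snapshots List of `mem_snapshot` objects.
#' @param sterol_species,lipid_species Species names.
#' @param bin_width Histogram bin width in degrees (default 5).
#' @param sector_resolved Split by sector of the lipid midpoint?
#' @return An `angle_distribution` on \[0, 90\], or a named list of 8 of
#'   them when `sector_resolved`. A zero-pair result is flagged via its
#'   `empty` attribute.
#' @export
theta90_distribution <- function(snapshots, sterol_species, lipid_species,
                                 species_map, bin_width = 5, cutoff = 0.75,
                                 sector_resolved = FALSE,
                                 sterol_anchor = c("ring", "molecule")) {
  snapshots <- as_snapshot_list(snapshots)
  sterol_anchor <- match.arg(sterol_anchor)
  check_species_known(species_map, sterol_species)
  check_species_known(species_map, lipid_species)
  pairs <- theta90_pairs(snapshots, sterol_species, lipid_species, species_map,
                         cutoff, sterol_anchor)
  t90 <- if (nrow(pairs)) fold_theta90(pairs$theta) else numeric(0)
  if (!sector_resolved) {
    return(angle_distribution(t90, c(0, 90), bin_width))
  }
  out <- lapply(sector_labels(), function(sec) {
    angle_distribution(t90[pairs$sector == sec], c(0, 90), bin_width)
  })
  names(out) <- sector_labels()
  out
}

#' Acyl-chain center-of-mass separation summary
#'
#' Mean and per-pair SD of the lateral sn-1/sn-2 chain COM separation, by
#' default restricted to lipids found in the first coordination shell of
#' some sterol (pass `sterol_species = NULL` for all lipids).
#'
#' @inheritParams theta90_distribution
#' @return List with `mean`, `sd` (nm) and `n` observations.
#' @export
chain_separation_summary <- function(snapshots, lipid_species, species_map,
                                     sterol_species = NULL, cutoff = 0.75) {
  snapshots <- as_snapshot_list(snapshots)
  check_species_known(species_map, lipid_species)
  seps <- numeric(0)
  for (s in snapshots) {
    cg <- chain_geometry(s, species_map, lipid_species)
    if (!is.null(sterol_species)) {
      ids <- snap_first_shell_union(s, sterol_species, species_map, cutoff,
                                    lipid_species)
      cg <- cg[cg$molid %in% ids, , drop = FALSE]
    }
    seps <- c(seps, cg$separation)
  }
  list(mean = if (length(seps)) mean(seps) else NA_real_,
       sd = if (length(seps) > 1) stats::sd(seps) else 0,
       n = length(seps))
}

snap_first_shell_union <- function(s, sterol_species, species_map, cutoff,
                                   lipid_species) {
  ids <- s$molecules$molid[s$molecules$species == sterol_species]
  unique(unlist(lapply(ids, function(id) {
    select_first_shell_lipids(s, id, species_map, cutoff, lipid_species)
  })))
}
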