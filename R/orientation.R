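# Sector-resolved relative orientation of sterol pairs (second shell).

#' Lateral C6-C11 orientation vector of a sterol
#'
#' Unit vector of the lab-xy projection of position(C11) - position(C6),
#' the in-plane orientation of the sterol ring.
#'
#' @param snap A `mem_snapshot`.
#' @param molid Molecule id of a sterol; `NULL` for all sterols of
#'   `species`.
#' @param species_map A `species_map`.
#' @param species Optional sterol species restriction (used when
#'   `molid = NULL`).
#' @return For a single `molid`, a length-2 unit vector; otherwise a
#'   data.frame `molid`, `ux`, `uy`.
#' @export
c6c11_lateral_vector <- function(snap, molid = NULL, species_map,
                                 species = NULL) {
  tab <- orientation_table(snap, species_map, species)
  if (!is.null(molid)) {
    i <- match(molid, tab$molid)
    if (is.na(i)) {
      so_stop(sprintf("molecule %s is not a sterol with orientation atoms", molid),
              "sterolorder_input_error")
    }
    return(c(tab$ux[i], tab$uy[i]))
  }
  tab
}

orientation_table <- function(snap, species_map, species = NULL) {
  sterols <- species_of_kind(species_map, "sterol")
  if (!is.null(species)) sterols <- intersect(species, sterols)
  a <- snap$atoms
  rows <- list()
  for (sp in sterols) {
    e <- species_map[[sp]]
    oa <- e$orientation_atoms
    sub <- a[a$species == sp & a$name %in% oa, , drop = FALSE]
    if (!nrow(sub)) next
    p6 <- sub[sub$name == oa[["c6"]], c("molid", "x", "y")]
    p11 <- sub[sub$name == oa[["c11"]], c("molid", "x", "y")]
    m <- merge(p6, p11, by = "molid", suffixes = c("6", "11"))
    dx <- m$x11 - m$x6; dy <- m$y11 - m$y6
    n <- sqrt(dx^2 + dy^2)
    if (any(n < 1e-12)) {
      so_stop(sprintf("undefined orientation: C6 and C11 laterally coincident for molecule %d",
                      m$molid[which(n < 1e-12)[1]]),
              "sterolorder_degenerate_geometry")
    }
    rows[[sp]] <- data.frame(molid = m$molid, species = sp,
                             ux = dx / n, uy = dy / n,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(molid = integer(0), species = character(0),
                      ux = numeric(0), uy = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Relative orientation angle between two in-plane vectors
#'
#' Signed anticlockwise angle from `a` to `b`, mapped to \[0, 360).
#'
#' @param a,b Length-2 vectors, or n x 2 matrices of vectors.
#' @return Angle(s) in degrees on \[0, 360).
#' @export
relative_orientation_angle <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(as.numeric(a), ncol = 2)
  if (is.null(dim(b))) b <- matrix(as.numeric(b), ncol = 2)
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  dot <- a[, 1] * b[, 1] + a[, 2] * b[, 2]
  wrap360(rad2deg(atan2(cross, dot)))
}

#' Sector-resolved sterol pair orientation distributions
#'
#' For every ordered sterol pair (central, neighbor) whose neighbor
#' ring-COM lies at a frame-projected radius inside `r_range` (default the
#' second coordination shell, 0.8-1.1 nm), the relative orientation angle
#' between the two C6-C11 lateral vectors is accumulated into the
#' distribution of the neighbor's angular sector in the central molecule's
#' frame. Every unordered pair in range contributes twice, once per choice
#' of central molecule.
#'
#' @param snapshots List of `mem_snapshot` objects.
#' @param sterol_species Sterol species name.
#' @param species_map A `species_map`.
#' @param r_range Radial range `c(lo, hi)` in nm (default `c(0.8, 1.1)`).
#' @param bin_width Angle bin width in degrees (default 5).
#' @param mode `"frame"` evaluates the shell radius and sector on the
#'   frame-projected displacement (default); `"lab"` uses the lab-frame
#'   lateral displacement for the radius (the sector is always a frame
#'   quantity).
#' @return Named list of 8 `angle_distribution`s on \[0, 360), one per
#'   sector, with attribute `preferred` naming the alpha/beta1/beta2
#'   sectors (`W`, `NE`, `SE`). Sectors with zero pairs are flagged empty.
#' @export
sector_orientation_distributions <- function(snapshots, sterol_species,
                                             species_map,
                                             r_range = c(0.8, 1.1),
                                             bin_width = 5,
                                             mode = c("frame", "lab")) {
  snapshots <- as_snapshot_list(snapshots)
  mode <- match.arg(mode)
  check_species_known(species_map, sterol_species)
  stopifnot(length(r_range) == 2, r_range[2] > r_range[1])
  angles <- stats::setNames(vector("list", 8), sector_labels())
  for (s in snapshots) {
    rc <- com_table(s, species_map, sterol_species, subset = "ring")
    if (nrow(rc) < 2) next
    frames <- sterol_frames(s, species_map, sterol_species)
    ot <- orientation_table(s, species_map, sterol_species)
    oi <- match(rc$molid, ot$molid)
    for (i in seq_len(nrow(rc))) {
      fr <- frames[[as.character(rc$molid[i])]]
      same <- which(rc$leaflet == rc$leaflet[i])
      same <- same[same != i]
      if (!length(same)) next
      d <- cbind(rc$x[same] - rc$x[i], rc$y[same] - rc$y[i],
                 rc$z[same] - rc$z[i])
      d <- min_image_disp(d, s$box)
      fx <- d %*% cbind(fr$ex, fr$ey)
      rad <- if (mode == "frame") sqrt(fx[, 1]^2 + fx[, 2]^2) else
        sqrt(d[, 1]^2 + d[, 2]^2)
      inr <- which(rad >= r_range[1] & rad <= r_range[2])
      if (!length(inr)) next
      phi <- wrap360(rad2deg(atan2(fx[inr, 2], fx[inr, 1])))
      sec <- sector_of(phi)
      ui <- c(ot$ux[oi[i]], ot$uy[oi[i]])
      uj <- cbind(ot$ux[oi[same[inr]]], ot$uy[oi[same[inr]]])
      ang <- relative_orientation_angle(matrix(ui, length(inr), 2, byrow = TRUE), uj)
      for (k in seq_along(inr)) {
        angles[[sec[k]]] <- c(angles[[sec[k]]], ang[k])
      }
    }
  }
  out <- lapply(sector_labels(), function(secl) {
    v <- angles[[secl]]
    angle_distribution(if (is.null(v)) numeric(0) else v, c(0, 360), bin_width)
  })
  names(out) <- sector_labels()
  attr(out, "preferred") <- c(alpha = "W", beta1 = "NE", beta2 = "SE")
  attr(out, "r_range") <- r_range
  class(out) <- "sector_orientation_set"
  out
}

#' @export
print.sector_orientation_set <- function(x, ...) {
  rr <- attr(x, "r_range")
  cat(sprintf("Sector-resolved pair-orientation distributions (shell %.2f-%.2f nm)\n",
              rr[1], rr[2]))
  for (nm in names(x)) {
    n <- attr(x[[nm]], "n_pairs")
    tag <- names(which(attr(x, "preferred") == nm))
    cat(sprintf("  %-2s: %6d pair(s)%s\n", nm, n,
                if (length(tag)) paste0("  <- ", tag) else ""))
  }
  invisible(x)
}
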