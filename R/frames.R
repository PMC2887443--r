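# Per-sterol molecular reference frame and frame-coordinate utilities.
#
# The frame has its origin at C13; x runs along C13->C18 (toward the
# off-plane methyl), the xz-plane contains the C13->C10 vector, and
# y = z cross x completes a right-handed triad. The xy-plane then splits
# the rough face into the beta-1 (y > 0) and beta-2 (y < 0) sub-faces,
# with the smooth alpha face toward -x.

#' Build a sterol reference frame
#'
#' @param c13,c18,c10 Positions (nm) of the C13, C18 and C10 sites.
#' @return A `sterol_frame`: origin plus orthonormal right-handed basis
#'   vectors `ex`, `ey`, `ez`.
#' @export
build_sterol_frame <- function(c13, c18, c10) {
  c13 <- as_point3(c13, "c13"); c18 <- as_point3(c18, "c18")
  c10 <- as_point3(c10, "c10")
  ex <- unit3(c18 - c13, what = "C13->C18 vector")
  v <- c10 - c13
  vz <- v - sum(v * ex) * ex
  ez <- unit3(vz, eps = 1e-9 * max(1, sqrt(sum(v^2))),
              what = "component of C13->C10 orthogonal to x (collinear frame atoms)")
  if (sum((c10 - c13) * ez) < 0) ez <- -ez  # sign fixed so C10 sits at z > 0
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  structure(list(origin = c13, ex = ex, ey = ey, ez = ez),
            class = "sterol_frame")
}

#' @export
print.sterol_frame <- function(x, ...) {
  cat("Sterol frame at origin", sprintf("(%.3f, %.3f, %.3f) nm\n",
                                        x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("ex", "ey", "ez")) {
    cat(sprintf("  %s = (% .6f, % .6f, % .6f)\n", ax, x[[ax]][1], x[[ax]][2],
                x[[ax]][3]))
  }
  invisible(x)
}

#' Reconstruct a tetrahedral substituent position
#'
#' Given a tetrahedral center and three of its substituents, places the
#' fourth along the negated sum of the unit bond vectors at the given bond
#' length. Used to rebuild the missing off-plane methyls of the flat sterol
#' analogue so its reference frame can be defined like cholesterol's.
#'
#' @param center Position of the central atom (nm).
#' @param neighbor1,neighbor2,neighbor3 Positions of the three known
#'   substituents (nm).
#' @param bond_length Bond length to the reconstructed site (nm); default
#'   0.153 (standard C-C).
#' @return Position of the reconstructed substituent (nm).
#' @export
reconstruct_tetrahedral_substituent <- function(center, neighbor1, neighbor2,
                                                neighbor3, bond_length = 0.153) {
  center <- as_point3(center, "center")
  nb <- rbind(as_point3(neighbor1, "neighbor1"),
              as_point3(neighbor2, "neighbor2"),
              as_point3(neighbor3, "neighbor3"))
  u <- t(apply(nb, 1, function(p) unit3(p - center, what = "center-neighbor bond")))
  s <- colSums(u)
  dir <- unit3(-s, eps = 1e-9,
               what = "negated bond-vector sum (planar-symmetric neighbors)")
  center + bond_length * dir
}

#' Express points in a sterol frame
#'
#' @param frame A `sterol_frame`.
#' @param points Numeric length-3 vector or an n x 3 matrix of lab-frame
#'   positions (nm).
#' @return data.frame with frame coordinates `x`, `y`, `z` (nm), the lateral
#'   radius `r_xy`, and the in-plane angle `phi` in degrees on \[0, 360)
#'   (0 along +x, anticlockwise; `phi` is 0 by convention at the origin).
#' @export
to_frame_coords <- function(frame, points) {
  stopifnot(inherits(frame, "sterol_frame"))
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 3)
  d <- sweep(points, 2, frame$origin)
  m <- cbind(d %*% frame$ex, d %*% frame$ey, d %*% frame$ez)
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  phi <- ifelse(r > 0, wrap360(rad2deg(atan2(m[, 2], m[, 1]))), 0)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], r_xy = r, phi = phi)
}

# sector boundaries as printed: half-open [lo, hi), E wrapping through 0.
# N spans 55 degrees and NW 35; the printed ranges tile the circle and are
# used verbatim.
.sector_breaks <- c(22.5, 67.5, 122.5, 157.5, 202.5, 247.5, 292.5, 337.5)
.sector_names <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE", "E")

#' Angular sector of an in-plane angle
#'
#' Maps frame angles (degrees) to the eight named sectors
#' NE \[22.5, 67.5), N \[67.5, 122.5), NW \[122.5, 157.5), W \[157.5, 202.5),
#' SW \[202.5, 247.5), S \[247.5, 292.5), SE \[292.5, 337.5) and E
#' \[337.5, 22.5) wrapping through 0. Intervals are half-open; an exact
#' boundary belongs to the anticlockwise-later sector.
#'
#' @param phi Numeric vector of angles in degrees (any real value).
#' @return Character vector of sector labels.
#' @export
sector_of <- function(phi) {
  if (any(!is.finite(phi))) {
    so_stop("sector_of: angles must be finite", "sterolorder_input_error")
  }
  phi <- wrap360(phi)
  .sector_names[findInterval(phi, .sector_breaks) + 1L]
}

#' Sector labels in anticlockwise order starting at E
#' @return Character vector of the 8 sector labels.
#' @export
sector_labels <- function() c("E", "NE", "N", "NW", "W", "SW", "S", "SE")

# Build frames for all sterols of given species in a snapshot, applying any
# configured tetrahedral reconstruction of missing frame atoms. Returns a
# list keyed by molecule id.
sterol_frames <- function(snap, species_map, species = NULL) {
  sterols <- species_of_kind(species_map, "sterol")
  if (is.null(species)) species <- sterols
  species <- intersect(species, sterols)
  out <- list()
  a <- snap$atoms
  for (sp in species) {
    e <- species_map[[sp]]
    ids <- snap$molecules$molid[snap$molecules$species == sp]
    for (id in ids) {
      sub <- a[a$molid == id, , drop = FALSE]
      pos <- function(nm) {
        i <- match(nm, sub$name)
        if (is.na(i)) NULL else c(sub$x[i], sub$y[i], sub$z[i])
      }
      get_site <- function(nm) {
        p <- pos(nm)
        if (!is.null(p)) return(p)
        rc <- e$reconstruct[[nm]]
        if (is.null(rc)) {
          so_stop(sprintf("molecule %d (%s): site '%s' absent and not reconstructable",
                          id, sp, nm), "sterolorder_input_error")
        }
        reconstruct_tetrahedral_substituent(pos(rc$center),
                                            pos(rc$neighbors[1]),
                                            pos(rc$neighbors[2]),
                                            pos(rc$neighbors[3]),
                                            rc$bond_length)
      }
      out[[as.character(id)]] <- build_sterol_frame(get_site(e$frame_atoms[["c13"]]),
                                                    get_site(e$frame_atoms[["c18"]]),
                                                    get_site(e$frame_atoms[["c10"]]))
    }
  }
  out
}
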