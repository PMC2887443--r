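# Lateral pair correlation g(r) and coordination-shell occupancy ratios.

#' Minimum-image lateral distance
#'
#' Euclidean distance of the minimum-image in-plane displacement (z is
#' ignored) between two points in a periodic box.
#'
#' @param p,q Numeric length-3 positions (nm), or n x 3 matrices.
#' @param box Box lengths (nm), lateral lengths first.
#' @return Numeric distance(s) in nm.
#' @export
min_image_lateral_distance <- function(p, q, box) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3)
  if (is.null(dim(q))) q <- matrix(as.numeric(q), ncol = 3)
  box <- as.numeric(box)
  if (any(box[1:2] <= 0)) {
    so_stop("box lateral lengths must be > 0", "sterolorder_input_error")
  }
  dx <- min_image_1d(p[, 1] - q[, 1], box[1])
  dy <- min_image_1d(p[, 2] - q[, 2], box[2])
  sqrt(dx^2 + dy^2)
}

# per-(frame, leaflet) reference/target COM tables
rdf_groups <- function(snapshots, species_a, species_b, species_map, com_atoms) {
  subset <- if (com_atoms == "ring") "ring" else "all"
  lapply(snapshots, function(s) {
    ca <- com_table(s, species_map, species_a, subset = subset)
    cb <- if (identical(species_a, species_b)) ca else
      com_table(s, species_map, species_b, subset = subset)
    list(snap = s, ca = ca, cb = cb)
  })
}

#' Lateral pair correlation function g(r)
#'
#' Per-leaflet lateral pair correlation between the centers of mass of
#' species `species_a` (reference) and `species_b` (target):
#' `g(r)` = observed pair density in the annulus at distance r divided by
#' the leaflet's mean target density (excluding the reference itself when
#' the species coincide), averaged over frames and leaflets. Distances are
#' in-plane minimum-image COM separations within one leaflet; cross-leaflet
#' pairs are excluded.
#'
#' @param snapshots List of `mem_snapshot` objects.
#' @param species_a,species_b Reference and target species names.
#' @param species_map A `species_map`.
#' @param bin_width Bin width in nm (default 0.01).
#' @param r_max Maximum distance in nm (default 2.5); truncated with a
#'   warning if it exceeds half the smallest lateral box length.
#' @param com_atoms `"all"` (whole molecule, default) or `"ring"`
#'   (sterol ring atoms only).
#' @param lateral If `FALSE`, 3D minimum-image distances are used instead of
#'   in-plane ones (comparison mode; the annulus normalization is kept).
#' @return A `radial_profile`: data.frame with bin edges/midpoints, raw
#'   ordered-pair `count`, `g` and a Poisson `sem`, plus attributes
#'   (`pair`, `n_frames`, `mean_density`).
#' @export
lateral_rdf <- function(snapshots, species_a, species_b, species_map,
                        bin_width = 0.01, r_max = 2.5, com_atoms = c("all", "ring"),
                        lateral = TRUE) {
  snapshots <- as_snapshot_list(snapshots)
  com_atoms <- match.arg(com_atoms)
  check_species_known(species_map, species_a)
  check_species_known(species_map, species_b)
  stopifnot(bin_width > 0, r_max > bin_width)
  half <- min(vapply(snapshots, function(s) min(s$box[1:2]), numeric(1))) / 2
  if (r_max > half) {
    warning(sprintf("r_max %.3f nm exceeds half the smallest lateral box length; truncating to %.3f nm",
                    r_max, floor(half / bin_width) * bin_width), call. = FALSE)
    r_max <- floor(half / bin_width) * bin_width
  }
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  expected <- numeric(nb)
  dens_acc <- 0; dens_n <- 0L
  ann <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  self_pair <- identical(species_a, species_b)
  any_b <- FALSE
  for (g in rdf_groups(snapshots, species_a, species_b, species_map, com_atoms)) {
    s <- g$snap
    area <- s$box[["x"]] * s$box[["y"]]
    for (lf in unique(g$ca$leaflet)) {
      A <- g$ca[g$ca$leaflet == lf, , drop = FALSE]
      B <- g$cb[g$cb$leaflet == lf, , drop = FALSE]
      na <- nrow(A); nbm <- nrow(B)
      if (nbm > 0) any_b <- TRUE
      neff <- nbm - as.integer(self_pair)
      if (na == 0 || neff <= 0) next
      d <- pair_distances(A, B, s$box, lateral)
      if (self_pair) d <- d[upper.tri(d) | lower.tri(d)] else d <- as.vector(d)
      d <- d[d < r_max]
      counts <- counts + tabulate(findInterval(d, edges, left.open = TRUE), nbins = nb)
      expected <- expected + na * neff / area * ann
      dens_acc <- dens_acc + neff / area
      dens_n <- dens_n + 1L
    }
  }
  if (!any_b) {
    so_stop(sprintf("no molecules of target species '%s' found", species_b),
            "sterolorder_input_error")
  }
  g_r <- ifelse(expected > 0, counts / expected, NA_real_)
  out <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
                    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                    count = counts, g = g_r,
                    sem = ifelse(expected > 0, sqrt(counts) / expected, NA_real_))
  structure(out, class = c("radial_profile", "data.frame"),
            pair = c(species_a, species_b), n_frames = length(snapshots),
            mean_density = if (dens_n) dens_acc / dens_n else NA_real_,
            bin_width = bin_width, lateral = lateral)
}

pair_distances <- function(A, B, box, lateral = TRUE) {
  dx <- min_image_1d(outer(A$x, B$x, "-"), box[["x"]])
  dy <- min_image_1d(outer(A$y, B$y, "-"), box[["y"]])
  if (lateral) return(sqrt(dx^2 + dy^2))
  dz <- min_image_1d(outer(A$z, B$z, "-"), box[["z"]])
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Coordination-shell density ratios
#'
#' Ratio of the target-species density averaged inside radial shells around
#' the reference species to the leaflet's total mean target density
#' (Table-1-style statistic). Defaults to the first (0.4-0.8 nm) and second
#' (0.8-1.1 nm) coordination shells. Equals the annulus-area-weighted mean
#' of [lateral_rdf()] over the same range when bin edges align.
#'
#' @inheritParams lateral_rdf
#' @param shells Named list of `c(lo, hi)` shell ranges in nm;
#'   non-overlapping and increasing.
#' @return A `shell_occupancy` data.frame: shell name, range, ordered-pair
#'   count and density ratio.
#' @export
shell_density_ratio <- function(snapshots, species_a, species_b, species_map,
                                shells = list(first = c(0.4, 0.8),
                                              second = c(0.8, 1.1)),
                                com_atoms = c("all", "ring"), lateral = TRUE) {
  snapshots <- as_snapshot_list(snapshots)
  com_atoms <- match.arg(com_atoms)
  check_species_known(species_map, species_a)
  check_species_known(species_map, species_b)
  validate_shells(shells)
  lo <- vapply(shells, `[`, numeric(1), 1)
  hi <- vapply(shells, `[`, numeric(1), 2)
  counts <- numeric(length(shells))
  expected <- numeric(length(shells))
  ann <- pi * (hi^2 - lo^2)
  self_pair <- identical(species_a, species_b)
  any_b <- FALSE
  for (g in rdf_groups(snapshots, species_a, species_b, species_map, com_atoms)) {
    s <- g$snap
    area <- s$box[["x"]] * s$box[["y"]]
    for (lf in unique(g$ca$leaflet)) {
      A <- g$ca[g$ca$leaflet == lf, , drop = FALSE]
      B <- g$cb[g$cb$leaflet == lf, , drop = FALSE]
      na <- nrow(A); nbm <- nrow(B)
      if (nbm > 0) any_b <- TRUE
      neff <- nbm - as.integer(self_pair)
      if (na == 0 || neff <= 0) next
      d <- pair_distances(A, B, s$box, lateral)
      if (self_pair) d <- d[upper.tri(d) | lower.tri(d)] else d <- as.vector(d)
      for (k in seq_along(shells)) {
        counts[k] <- counts[k] + sum(d > lo[k] & d <= hi[k])
      }
      expected <- expected + na * neff / area * ann
    }
  }
  if (!any_b) {
    so_stop(sprintf("no molecules of target species '%s' found", species_b),
            "sterolorder_input_error")
  }
  out <- data.frame(shell = names(shells), r_lo = lo, r_hi = hi,
                    count = counts,
                    ratio = ifelse(expected > 0, counts / expected, NA_real_),
                    row.names = NULL)
  structure(out, class = c("shell_occupancy", "data.frame"),
            pair = c(species_a, species_b), n_frames = length(snapshots))
}

validate_shells <- function(shells) {
  if (!is.list(shells) || !length(shells)) {
    so_stop("shells must be a non-empty list of c(lo, hi) ranges",
            "sterolorder_input_error")
  }
  m <- t(vapply(shells, function(s) as.numeric(s[1:2]), numeric(2)))
  if (any(!is.finite(m)) || any(m[, 2] <= m[, 1])) {
    so_stop("each shell range must be increasing: c(lo, hi) with hi > lo",
            "sterolorder_input_error")
  }
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2] - 1e-12)) {
    so_stop("shell ranges must not overlap", "sterolorder_input_error")
  }
  invisible(TRUE)
}

#' @export
print.radial_profile <- function(x, ...) {
  p <- attr(x, "pair")
  cat(sprintf("Lateral g(r) for %s-%s over %d frame(s), bin %.3g nm\n",
              p[1], p[2], attr(x, "n_frames"), attr(x, "bin_width")))
  NextMethod()
}

#' @export
print.shell_occupancy <- function(x, ...) {
  p <- attr(x, "pair")
  cat(sprintf("Coordination-shell density ratios for %s-%s over %d frame(s)\n",
              p[1], p[2], attr(x, "n_frames")))
  NextMethod()
}
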