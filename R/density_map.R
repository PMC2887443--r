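# Two-dimensional neighbor density maps in the sterol molecular frame.

#' Accumulate a molecular-frame 2D density map
#'
#' For every reference sterol in every frame, the selected target atoms in
#' the same leaflet are expressed in that sterol's molecular frame (origin
#' C13, x toward the off-plane methyl) and their (x, y) projections binned
#' on a square grid. The minimum-image displacement is taken in the lab
#' frame first, then rotated into the molecular frame; no cut is applied on
#' the frame z coordinate (full projection). Values are total densities in
#' atoms per nm^2, averaged per reference sterol per frame; the reference's
#' own atoms are excluded.
#'
#' @param snapshots List of `mem_snapshot` objects.
#' @param reference_species Sterol species providing the reference frames.
#' @param target_species Species whose atoms are mapped.
#' @param species_map A `species_map`.
#' @param target_atoms Atom selection for the target species: `"ring"`
#'   (sterol ring atoms; default for sterol targets), `"chains"` (all
#'   united-atom acyl-chain carbons of both chains; default for
#'   phospholipid targets), `"terminal_methyl"` (last atom of each chain),
#'   `"all"`, or an explicit character vector of atom names.
#' @param extent Half-width of the square window in nm (default 2.5).
#' @param bin Bin size in nm (default 0.05).
#' @return A `density_map2d`: list with the value matrix (rows = x bins,
#'   columns = y bins), bin midpoints, and bookkeeping counts.
#' @export
accumulate_density_map <- function(snapshots, reference_species, target_species,
                                   species_map,
                                   target_atoms = NULL,
                                   extent = 2.5, bin = 0.05) {
  snapshots <- as_snapshot_list(snapshots)
  check_species_known(species_map, reference_species)
  check_species_known(species_map, target_species)
  if (species_map[[reference_species]]$kind != "sterol") {
    so_stop("reference species must be a sterol", "sterolorder_input_error")
  }
  stopifnot(extent > 0, bin > 0, bin < extent)
  tsel <- resolve_target_atoms(species_map[[target_species]], target_atoms)
  half <- min(vapply(snapshots, function(s) min(s$box[1:2]), numeric(1))) / 2
  if (extent > half) {
    warning(sprintf("grid extent %.2f nm exceeds half the smallest lateral box length (%.2f nm); periphery is aliased by periodic images",
                    extent, half), call. = FALSE)
  }
  edges <- seq(-extent, extent, by = bin)
  ng <- length(edges) - 1L
  acc <- matrix(0, ng, ng)
  n_ref_frames <- 0
  n_frames <- 0L
  for (s in snapshots) {
    n_frames <- n_frames + 1L
    frames <- sterol_frames(s, species_map, reference_species)
    if (!length(frames)) next
    a <- s$atoms
    ta <- a[a$species == target_species & a$name %in% tsel, , drop = FALSE]
    lf_of <- stats::setNames(s$molecules$leaflet, s$molecules$molid)
    ref_ids <- as.integer(names(frames))
    for (k in seq_along(frames)) {
      fr <- frames[[k]]
      rid <- ref_ids[k]
      tt <- ta[ta$molid != rid & lf_of[as.character(ta$molid)] == lf_of[as.character(rid)], ,
               drop = FALSE]
      n_ref_frames <- n_ref_frames + 1
      if (!nrow(tt)) next
      d <- cbind(tt$x - fr$origin[1], tt$y - fr$origin[2], tt$z - fr$origin[3])
      d <- min_image_disp(d, s$box)
      fx <- d %*% cbind(fr$ex, fr$ey)
      ix <- findInterval(fx[, 1], edges, left.open = TRUE, rightmost.closed = TRUE)
      iy <- findInterval(fx[, 2], edges, left.open = TRUE, rightmost.closed = TRUE)
      ok <- ix >= 1L & ix <= ng & iy >= 1L & iy <= ng
      if (any(ok)) {
        lin <- ix[ok] + (iy[ok] - 1L) * ng
        acc <- acc + matrix(tabulate(lin, nbins = ng * ng), ng, ng)
      }
    }
  }
  if (n_ref_frames == 0) {
    so_stop(sprintf("no reference molecules of species '%s' found", reference_species),
            "sterolorder_input_error")
  }
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(values = acc / (bin^2 * n_ref_frames),
                 counts = acc, x_mid = mids, y_mid = mids, bin = bin,
                 extent = extent, n_references = n_ref_frames,
                 n_frames = n_frames,
                 selection = sprintf("%s atoms of %s around %s",
                                     paste(utils::head(tsel, 3), collapse = ","),
                                     target_species, reference_species)),
            class = "density_map2d")
}

resolve_target_atoms <- function(entry, target_atoms) {
  if (is.character(target_atoms) && length(target_atoms) > 1) return(target_atoms)
  mode <- target_atoms
  if (is.null(mode)) mode <- if (entry$kind == "sterol") "ring" else "chains"
  switch(mode,
         ring = {
           if (is.null(entry$ring_atoms)) {
             so_stop("'ring' selection requires a sterol target", "sterolorder_input_error")
           }
           recon <- if (!is.null(entry$reconstruct)) names(entry$reconstruct) else character(0)
           setdiff(entry$ring_atoms, recon)
         },
         chains = {
           if (is.null(entry$sn1_chain_atoms)) {
             so_stop("'chains' selection requires a phospholipid target",
                     "sterolorder_input_error")
           }
           c(entry$sn1_chain_atoms, entry$sn2_chain_atoms)
         },
         terminal_methyl = {
           if (is.null(entry$sn1_chain_atoms)) {
             so_stop("'terminal_methyl' selection requires a phospholipid target",
                     "sterolorder_input_error")
           }
           c(utils::tail(entry$sn1_chain_atoms, 1), utils::tail(entry$sn2_chain_atoms, 1))
         },
         all = names(entry$atom_masses),
         # single explicit atom name
         mode)
}

#' @export
print.density_map2d <- function(x, ...) {
  cat(sprintf("2D molecular-frame density map: %s\n", x$selection))
  cat(sprintf("  grid [%.2f, %.2f] nm, bin %.3g nm, %d reference-frames over %d frame(s)\n",
              -x$extent, x$extent, x$bin, x$n_references, x$n_frames))
  cat(sprintf("  mean density %.4g atoms/nm^2, max %.4g\n",
              mean(x$values), max(x$values)))
  invisible(x)
}

#' Plot a molecular-frame density map
#'
#' @param x A `density_map2d`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.density_map2d <- function(x, ...) {
  graphics::image(x$x_mid, x$y_mid, x$values, xlab = "frame x (nm)",
                  ylab = "frame y (nm)", asp = 1,
                  main = x$selection, useRaster = TRUE, ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey40")
  invisible(x)
}

#' Write a density map as a plain-text matrix with a metadata header
#'
#' @param map A `density_map2d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# selection: %s", map$selection),
               sprintf("# extent_nm: %g", map$extent),
               sprintf("# bin_nm: %g", map$bin),
               sprintf("# n_references: %g", map$n_references),
               sprintf("# n_frames: %d", map$n_frames),
               "# rows are x bins (ascending), columns y bins (ascending)"), con)
  utils::write.table(map$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Find peaks in a molecular-frame density map
#'
#' Local maxima above a mean-relative threshold inside a radial band,
#' greedily pruned so that no two reported peaks are closer than
#' `min_separation` (highest kept first). Each peak is annotated with its
#' frame angle, radius and angular sector.
#'
#' @param map A `density_map2d`.
#' @param threshold Multiplier over the mean in-band density (default 2).
#' @param min_separation Minimum peak separation in nm (default 0.2).
#' @param radial_band `c(lo, hi)` radial band in nm to search (default the
#'   whole map).
#' @return A `peak_set` data.frame: `x`, `y`, `r`, `phi`, `height`,
#'   `sector`, ordered by decreasing height. Empty band yields zero rows.
#' @export
find_peaks <- function(map, threshold = 2, min_separation = 0.2,
                       radial_band = c(0, Inf)) {
  stopifnot(inherits(map, "density_map2d"))
  v <- map$values
  ng <- nrow(v)
  r <- sqrt(outer(map$x_mid^2, map$y_mid^2, "+"))
  in_band <- r >= radial_band[1] & r <= radial_band[2]
  empty <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                      phi = numeric(0), height = numeric(0),
                      sector = character(0))
  if (!any(in_band)) return(structure(empty, class = c("peak_set", "data.frame")))
  thr <- threshold * mean(v[in_band])
  # strict-on-the-boundary local maximum over the 8-neighborhood
  pad <- matrix(-Inf, ng + 2, ng + 2)
  pad[2:(ng + 1), 2:(ng + 1)] <- v
  is_max <- matrix(TRUE, ng, ng)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (v >= pad[(2 + di):(ng + 1 + di), (2 + dj):(ng + 1 + dj)])
  }
  cand <- which(is_max & in_band & v > thr & v > 0, arr.ind = TRUE)
  if (!nrow(cand)) return(structure(empty, class = c("peak_set", "data.frame")))
  px <- map$x_mid[cand[, 1]]
  py <- map$y_mid[cand[, 2]]
  ph <- v[cand]
  o <- order(-ph, px, py)
  px <- px[o]; py <- py[o]; ph <- ph[o]
  keep <- logical(length(ph))
  for (i in seq_along(ph)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt((px[i] - px[keep])^2 + (py[i] - py[keep])^2)
    if (all(dd >= min_separation)) keep[i] <- TRUE
  }
  px <- px[keep]; py <- py[keep]; ph <- ph[keep]
  phi <- wrap360(rad2deg(atan2(py, px)))
  out <- data.frame(x = px, y = py, r = sqrt(px^2 + py^2), phi = phi,
                    height = ph, sector = sector_of(phi),
                    stringsAsFactors = FALSE)
  structure(out, class = c("peak_set", "data.frame"),
            threshold = thr, min_separation = min_separation)
}
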