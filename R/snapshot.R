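# Snapshot container: one time frame of a membrane configuration.

#' Construct a membrane snapshot
#'
#' A snapshot holds one time frame: the periodic box (lateral lengths Lx, Ly
#' and normal extent Lz, all nm) and an atom table with one row per atom
#' (`molid`, `species`, `name`, `x`, `y`, `z` in nm). Molecules carry a
#' leaflet label in `upper`, `lower` or `unassigned` (see
#' [assign_leaflets()]).
#'
#' @param atoms data.frame with columns `molid` (integer), `species`
#'   (character), `name` (character), `x`, `y`, `z` (numeric, nm).
#' @param box numeric length-3, box lengths (nm), all > 0.
#' @param frame_index integer frame number.
#' @param time time in ps (NA if unknown).
#' @param leaflet optional named character vector of leaflet labels keyed by
#'   molecule id.
#' @return An object of class `mem_snapshot`.
#' @export
snapshot <- function(atoms, box, frame_index = 1L, time = NA_real_,
                     leaflet = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("molid", "species", "name", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    so_stop(sprintf("atom table must have columns: %s",
                    paste(need, collapse = ", ")), "sterolorder_input_error")
  }
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    so_stop("box must be three positive finite lengths (nm)",
            "sterolorder_input_error")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) {
    so_stop("all atom positions must be finite", "sterolorder_input_error")
  }
  atoms$molid <- as.integer(atoms$molid)
  atoms$name <- trimws(as.character(atoms$name))
  atoms$species <- trimws(as.character(atoms$species))
  mol <- unique(atoms[, c("molid", "species")])
  if (anyDuplicated(mol$molid)) {
    so_stop("a molecule id maps to more than one species",
            "sterolorder_input_error")
  }
  lab <- rep("unassigned", nrow(mol))
  names(lab) <- mol$molid
  if (!is.null(leaflet)) lab[names(leaflet)] <- leaflet
  molecules <- data.frame(molid = mol$molid, species = mol$species,
                          leaflet = unname(lab[as.character(mol$molid)]),
                          stringsAsFactors = FALSE)
  structure(list(frame_index = as.integer(frame_index), time = time,
                 box = c(x = box[1], y = box[2], z = box[3]),
                 atoms = atoms[, need], molecules = molecules),
            class = "mem_snapshot")
}

#' @export
print.mem_snapshot <- function(x, ...) {
  cat(sprintf("Snapshot %d (t = %s ps): %d molecules, %d atoms, box %.3f x %.3f x %.3f nm\n",
              x$frame_index, format(x$time), nrow(x$molecules),
              nrow(x$atoms), x$box[1], x$box[2], x$box[3]))
  tab <- table(x$molecules$species)
  cat("  composition:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  invisible(x)
}

# check that each molecule of a known species carries all its role atoms;
# molecules of species absent from the map are dropped with a warning
conform_snapshot <- function(snap, species_map) {
  known <- snap$molecules$species %in% names(species_map)
  if (!all(known)) {
    drop_sp <- unique(snap$molecules$species[!known])
    warning(sprintf("dropping molecules of species not in the species map: %s",
                    paste(drop_sp, collapse = ", ")), call. = FALSE)
    keep_ids <- snap$molecules$molid[known]
    snap$atoms <- snap$atoms[snap$atoms$molid %in% keep_ids, , drop = FALSE]
    snap$molecules <- snap$molecules[known, , drop = FALSE]
  }
  for (sp in unique(snap$molecules$species)) {
    e <- species_map[[sp]]
    required <- required_atoms(e)
    ids <- snap$molecules$molid[snap$molecules$species == sp]
    present <- split(snap$atoms$name[snap$atoms$molid %in% ids],
                     snap$atoms$molid[snap$atoms$molid %in% ids])
    for (id in ids) {
      missing <- setdiff(required, present[[as.character(id)]])
      if (length(missing)) {
        so_stop(sprintf("molecule %d (%s) is missing role atom(s): %s",
                        id, sp, paste(missing, collapse = ", ")),
                "sterolorder_input_error")
      }
    }
  }
  snap
}

required_atoms <- function(entry) {
  recon <- if (!is.null(entry$reconstruct)) names(entry$reconstruct) else character(0)
  recon_needed <- if (!is.null(entry$reconstruct)) {
    unique(unlist(lapply(entry$reconstruct, function(rc) c(rc$center, rc$neighbors))))
  } else character(0)
  out <- if (entry$kind == "sterol") {
    c(entry$frame_atoms, entry$orientation_atoms, entry$ring_atoms,
      entry$headgroup_anchor, recon_needed)
  } else {
    c(entry$sn1_chain_atoms, entry$sn2_chain_atoms, entry$headgroup_anchor)
  }
  setdiff(unique(out), recon)
}

# make molecules whole across the periodic boundary by nearest-image
# chaining along the stored atom order within each molecule
unwrap_snapshot <- function(snap) {
  a <- snap$atoms
  n <- nrow(a)
  if (n < 2) return(snap)
  first <- c(TRUE, a$molid[-1] != a$molid[-n])
  for (ax in c("x", "y", "z")) {
    L <- snap$box[[substr(ax, 1, 1)]]
    d <- c(0, diff(a[[ax]]))
    d[first] <- 0
    corr <- stats::ave(-L * round(d / L), a$molid, FUN = cumsum)
    a[[ax]] <- a[[ax]] + corr
  }
  snap$atoms <- a
  snap
}

# mass lookup vector for an atom table: "species|name" -> amu
atom_masses_for <- function(atoms, species_map) {
  key <- paste(atoms$species, atoms$name, sep = "|")
  lut <- unlist(lapply(names(species_map), function(sp) {
    m <- species_map[[sp]]$atom_masses
    stats::setNames(as.numeric(m), paste(sp, names(m), sep = "|"))
  }))
  w <- lut[key]
  w[is.na(w)] <- 0  # atoms without a configured mass carry no weight
  unname(w)
}

#' Center of mass of one molecule
#'
#' Computes the (by default mass-weighted) mean position of an atom subset of
#' one molecule, on whole-molecule coordinates: the molecule is re-chained
#' across the periodic boundary before averaging, so the result lies inside
#' the molecular envelope rather than mid-box when the molecule straddles an
#' edge.
#'
#' @param snap A `mem_snapshot`.
#' @param molid Molecule id.
#' @param species_map Species map (for masses).
#' @param atoms Optional character vector of atom names; default all atoms of
#'   the molecule.
#' @param mass_weighted If `FALSE`, the unweighted geometric mean is used.
#' @return Numeric length-3 position (nm).
#' @export
center_of_mass <- function(snap, molid, species_map, atoms = NULL,
                           mass_weighted = TRUE) {
  sel <- snap$atoms$molid == molid
  if (!any(sel)) {
    so_stop(sprintf("no molecule with id %s", molid), "sterolorder_input_error")
  }
  sub <- snap$atoms[sel, , drop = FALSE]
  if (!is.null(atoms)) {
    if (!length(atoms)) so_stop("atom subset is empty", "sterolorder_input_error")
    miss <- setdiff(atoms, sub$name)
    if (length(miss)) {
      so_stop(sprintf("molecule %d lacks atom(s): %s", molid,
                      paste(miss, collapse = ", ")), "sterolorder_input_error")
    }
    sub <- sub[sub$name %in% atoms, , drop = FALSE]
  }
  tmp <- snap
  tmp$atoms <- sub
  tmp <- unwrap_snapshot(tmp)
  sub <- tmp$atoms
  w <- if (mass_weighted) atom_masses_for(sub, species_map) else rep(1, nrow(sub))
  if (sum(w) <= 0) w <- rep(1, nrow(sub))
  c(x = sum(w * sub$x), y = sum(w * sub$y), z = sum(w * sub$z)) / sum(w)
}

# Vectorized per-molecule COM table. `subset` selects role atoms:
#   all | ring | sn1 | sn2. Assumes coordinates are already whole
# (read_snapshots and generate_leaflet both guarantee this).
com_table <- function(snap, species_map, species = NULL,
                      subset = c("all", "ring", "sn1", "sn2"),
                      mass_weighted = TRUE) {
  subset <- match.arg(subset)
  a <- snap$atoms
  if (!is.null(species)) a <- a[a$species %in% species, , drop = FALSE]
  if (subset != "all") {
    keep <- rep(FALSE, nrow(a))
    for (sp in unique(a$species)) {
      e <- species_map[[sp]]
      nm <- switch(subset,
                   ring = e$ring_atoms,
                   sn1 = e$sn1_chain_atoms,
                   sn2 = e$sn2_chain_atoms)
      if (is.null(nm)) next
      keep <- keep | (a$species == sp & a$name %in% nm)
    }
    a <- a[keep, , drop = FALSE]
  }
  if (!nrow(a)) {
    return(data.frame(molid = integer(0), species = character(0),
                      leaflet = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  }
  w <- if (mass_weighted) atom_masses_for(a, species_map) else rep(1, nrow(a))
  g <- factor(a$molid)
  sw <- rowsum(w, g)
  com <- rowsum(cbind(w * a$x, w * a$y, w * a$z), g) / as.vector(sw)
  ids <- as.integer(levels(g))
  mi <- match(ids, snap$molecules$molid)
  data.frame(molid = ids, species = snap$molecules$species[mi],
             leaflet = snap$molecules$leaflet[mi],
             x = com[, 1], y = com[, 2], z = com[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign leaflet labels
#'
#' Labels each molecule `upper` or `lower` by the sign of its headgroup
#' anchor's z position relative to the mass-weighted z-centroid of all
#' lipids in the frame. Assignment is per frame; flip-flop events are not
#' tracked. A single-leaflet configuration yields one populated label.
#'
#' @param snap A `mem_snapshot`.
#' @param species_map Species map naming each species' headgroup anchor.
#' @return The snapshot with leaflet labels filled in.
#' @export
assign_leaflets <- function(snap, species_map) {
  if (!nrow(snap$molecules)) {
    so_stop("snapshot has no molecules", "sterolorder_input_error")
  }
  w <- atom_masses_for(snap$atoms, species_map)
  if (sum(w) <= 0) w <- rep(1, nrow(snap$atoms))
  z0 <- sum(w * snap$atoms$z) / sum(w)
  anchors <- vapply(names(species_map), function(sp) species_map[[sp]]$headgroup_anchor,
                    character(1))
  anchor_of <- anchors[snap$atoms$species]
  sel <- !is.na(anchor_of) & snap$atoms$name == anchor_of
  az <- snap$atoms$z[sel]
  aid <- snap$atoms$molid[sel]
  lab <- ifelse(az >= z0, "upper", "lower")
  mi <- match(snap$molecules$molid, aid)
  snap$molecules$leaflet <- ifelse(is.na(mi), "unassigned", lab[mi])
  snap
}

#' Mean lateral box area over frames
#'
#' @param snapshots A list of `mem_snapshot` objects (or a single snapshot).
#' @return An `area_summary`: mean and per-frame (population) SD of
#'   Lx*Ly in nm^2, and the number of frames.
#' @export
mean_lateral_area <- function(snapshots) {
  snapshots <- as_snapshot_list(snapshots)
  areas <- vapply(snapshots, function(s) s$box[["x"]] * s$box[["y"]], numeric(1))
  n <- length(areas)
  m <- mean(areas)
  s <- sqrt(mean((areas - m)^2))
  structure(list(mean = m, sd = s, n_frames = n), class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf("Mean lateral area: %.3f +/- %.3f nm^2 over %d frame(s)\n",
              x$mean, x$sd, x$n_frames))
  invisible(x)
}

as_snapshot_list <- function(snapshots) {
  if (inherits(snapshots, "mem_snapshot")) return(list(snapshots))
  if (!is.list(snapshots) || !length(snapshots) ||
      !all(vapply(snapshots, inherits, logical(1), "mem_snapshot"))) {
    so_stop("expected a mem_snapshot or a non-empty list of them",
            "sterolorder_input_error")
  }
  snapshots
}
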