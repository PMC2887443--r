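# Species-map configuration: semantic atom roles per molecule type.

.species_keys <- c("kind", "frame_atoms", "orientation_atoms", "ring_atoms",
                   "sn1_chain_atoms", "sn2_chain_atoms", "headgroup_anchor",
                   "atom_masses", "reconstruct", "aliases")

#' Load and validate a species map
#'
#' A species map names the role atoms of every molecule type used in an
#' analysis: for sterols the frame atoms (C13/C18/C10), the orientation
#' atoms (C6/C11) and the ordered ring-atom list (17 sites for cholesterol,
#' 15 for the flat analogue whose off-plane methyls are rebuilt by
#' tetrahedral reconstruction); for phospholipids the ordered sn-1/sn-2
#' acyl-chain atom lists; for every species a headgroup anchor used for
#' leaflet assignment and a table of united-atom masses in amu.
#'
#' @param config_path Path to a YAML species-map file. The default is the
#'   configuration bundled with the package (species `CHOL`, `DCHL`,
#'   `DSPC`, `DOPC`).
#' @return An object of class `species_map`: a named list of validated
#'   species entries.
#' @examples
#' sm <- load_species_map()
#' length(sm$CHOL$ring_atoms)  # 17
#' length(sm$DCHL$ring_atoms)  # 15
#' @export
load_species_map <- function(config_path = default_species_map_path()) {
  if (!file.exists(config_path)) {
    so_stop(sprintf("species map file not found: %s", config_path),
            "sterolorder_config_error")
  }
  raw <- yaml::read_yaml(config_path)
  if (!is.list(raw) || is.null(raw$species) || !length(raw$species)) {
    so_stop("species map must contain a non-empty 'species' mapping",
            "sterolorder_config_error")
  }
  extra_top <- setdiff(names(raw), "species")
  if (length(extra_top)) {
    so_stop(sprintf("unknown top-level keys in species map: %s",
                    paste(extra_top, collapse = ", ")),
            "sterolorder_config_error")
  }
  sm <- lapply(names(raw$species), function(nm) {
    validate_species_entry(nm, raw$species[[nm]])
  })
  names(sm) <- names(raw$species)
  structure(sm, class = "species_map")
}

#' @rdname load_species_map
#' @export
default_species_map_path <- function() {
  system.file("extdata", "species_map.yaml", package = "sterolorder",
              mustWork = TRUE)
}

validate_species_entry <- function(name, entry) {
  if (!is.list(entry)) {
    so_stop(sprintf("species '%s': entry must be a mapping", name),
            "sterolorder_config_error")
  }
  unknown <- setdiff(names(entry), .species_keys)
  if (length(unknown)) {
    so_stop(sprintf("species '%s': unknown keys: %s", name,
                    paste(unknown, collapse = ", ")),
            "sterolorder_config_error")
  }
  kind <- entry$kind
  if (is.null(kind) || !kind %in% c("sterol", "phospholipid")) {
    so_stop(sprintf("species '%s': 'kind' must be 'sterol' or 'phospholipid'",
                    name), "sterolorder_config_error")
  }
  req <- function(role) {
    if (is.null(entry[[role]]) || !length(entry[[role]])) {
      so_stop(sprintf("species '%s': missing role atom list '%s'", name, role),
              "sterolorder_config_error")
    }
  }
  masses <- unlist(entry$atom_masses)
  if (is.null(masses) || !length(masses)) {
    so_stop(sprintf("species '%s': missing role atom list 'atom_masses'", name),
            "sterolorder_config_error")
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    so_stop(sprintf("species '%s': all atom masses must be > 0", name),
            "sterolorder_config_error")
  }
  entry$atom_masses <- masses
  # strip stray whitespace from every atom name; matching is then exact
  strip <- function(x) trimws(as.character(x))
  recon_sites <- character(0)
  if (!is.null(entry$reconstruct)) {
    for (site in names(entry$reconstruct)) {
      rc <- entry$reconstruct[[site]]
      if (is.null(rc$center) || is.null(rc$neighbors) ||
          length(rc$neighbors) != 3) {
        so_stop(sprintf(
          "species '%s': reconstruction of '%s' needs a center and 3 neighbors",
          name, site), "sterolorder_config_error")
      }
      entry$reconstruct[[site]]$center <- strip(rc$center)
      entry$reconstruct[[site]]$neighbors <- strip(rc$neighbors)
      if (is.null(rc$bond_length)) {
        entry$reconstruct[[site]]$bond_length <- 0.153
      }
    }
    recon_sites <- strip(names(entry$reconstruct))
  }
  if (kind == "sterol") {
    req("frame_atoms"); req("orientation_atoms"); req("ring_atoms")
    fa <- strip(unlist(entry$frame_atoms))
    if (length(fa) != 3 || !all(c("c13", "c18", "c10") %in%
                                tolower(names(entry$frame_atoms)))) {
      so_stop(sprintf(
        "species '%s': frame_atoms must name the c13, c18 and c10 sites",
        name), "sterolorder_config_error")
    }
    oa <- strip(unlist(entry$orientation_atoms))
    if (length(oa) != 2 || !all(c("c6", "c11") %in%
                                tolower(names(entry$orientation_atoms)))) {
      so_stop(sprintf(
        "species '%s': orientation_atoms must name the c6 and c11 sites",
        name), "sterolorder_config_error")
    }
    entry$ring_atoms <- strip(unlist(entry$ring_atoms))
    ok_home <- c(entry$ring_atoms, recon_sites)
    bad <- setdiff(c(fa, oa), ok_home)
    if (length(bad)) {
      so_stop(sprintf(
        "species '%s': frame/orientation atoms not in ring_atoms (or reconstructed): %s",
        name, paste(bad, collapse = ", ")), "sterolorder_config_error")
    }
    names(fa) <- tolower(names(entry$frame_atoms))
    names(oa) <- tolower(names(entry$orientation_atoms))
    entry$frame_atoms <- fa
    entry$orientation_atoms <- oa
  } else {
    req("sn1_chain_atoms"); req("sn2_chain_atoms"); req("headgroup_anchor")
    entry$sn1_chain_atoms <- strip(unlist(entry$sn1_chain_atoms))
    entry$sn2_chain_atoms <- strip(unlist(entry$sn2_chain_atoms))
    if (length(intersect(entry$sn1_chain_atoms, entry$sn2_chain_atoms))) {
      so_stop(sprintf("species '%s': sn-1 and sn-2 chain atoms must be disjoint",
                      name), "sterolorder_config_error")
    }
  }
  req("headgroup_anchor")
  entry$headgroup_anchor <- strip(entry$headgroup_anchor)
  entry
}

#' @export
print.species_map <- function(x, ...) {
  cat("Species map with", length(x), "species:\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    extra <- if (e$kind == "sterol") {
      sprintf("%d ring atoms", length(e$ring_atoms))
    } else {
      sprintf("%d+%d chain atoms", length(e$sn1_chain_atoms),
              length(e$sn2_chain_atoms))
    }
    cat(sprintf("  %-6s %-13s %s, anchor %s, %d masses\n", nm, e$kind, extra,
                e$headgroup_anchor, length(e$atom_masses)))
  }
  invisible(x)
}

# species of a given kind present in a map
species_of_kind <- function(species_map, kind) {
  names(species_map)[vapply(species_map, function(e) e$kind == kind, logical(1))]
}

check_species_known <- function(species_map, species) {
  if (!species %in% names(species_map)) {
    so_stop(sprintf("species '%s' not present in the species map", species),
            "sterolorder_input_error")
  }
}
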