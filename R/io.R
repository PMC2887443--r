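# Coordinate snapshot I/O: GRO (fixed columns) and PDB (via bio3d) dialects.
#
# Coordinates are nm internally; the PDB dialect is converted from/to
# Angstrom on the fly. Multi-frame input is either one file with
# concatenated frames (GRO) / MODEL blocks (PDB), or a list of files.

#' Read coordinate snapshots
#'
#' Reads one or more GRO or PDB files into a list of snapshots. Molecules
#' are grouped by residue id, atoms matched by (whitespace-stripped, exact)
#' name, each molecule's presence of its role atoms is verified against the
#' species map, and molecules are made whole across the periodic boundary
#' before any downstream use. Molecules whose residue name is not a species
#' in the map (e.g. solvent) are dropped with a warning.
#'
#' @param paths Character vector of file paths.
#' @param species_map A `species_map` (see [load_species_map()]).
#' @param dialect `"gro"`, `"pdb"`, or `NULL` to infer from the extension.
#' @param partial If `TRUE`, a truncated trailing frame is discarded and the
#'   complete frames are returned; if `FALSE` (default) truncation is an
#'   error.
#' @return List of `mem_snapshot` objects, frame indices sequential across
#'   files.
#' @export
read_snapshots <- function(paths, species_map, dialect = NULL, partial = FALSE) {
  stopifnot(is.character(paths), length(paths) >= 1)
  out <- list()
  for (p in paths) {
    dia <- dialect
    if (is.null(dia)) {
      dia <- switch(tolower(tools::file_ext(p)), gro = "gro", pdb = "pdb",
                    so_stop(sprintf("cannot infer dialect from '%s'; pass dialect=", p),
                            "sterolorder_format_error"))
    }
    frames <- switch(dia,
                     gro = read_gro_frames(p, partial = partial),
                     pdb = read_pdb_frames(p),
                     so_stop(sprintf("unsupported dialect '%s'", dia),
                             "sterolorder_format_error"))
    out <- c(out, frames)
  }
  for (i in seq_along(out)) {
    out[[i]]$frame_index <- i
    out[[i]] <- conform_snapshot(out[[i]], species_map)
    out[[i]] <- unwrap_snapshot(out[[i]])
  }
  out
}

read_gro_frames <- function(path, partial = FALSE) {
  if (!file.exists(path)) {
    so_stop(sprintf("file not found: %s", path), "sterolorder_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  trunc_err <- function(ln) {
    so_stop(sprintf("%s: truncated frame at line %d", path, ln),
            "sterolorder_format_error")
  }
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) { if (partial) break else trunc_err(i + 1L) }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0) {
      so_stop(sprintf("%s: line %d: expected an atom count, got '%s'",
                      path, i + 1L, lines[i + 1L]), "sterolorder_format_error")
    }
    last <- i + 1L + nat + 1L
    if (last > length(lines)) { if (partial) break else trunc_err(length(lines) + 1L) }
    al <- lines[(i + 2L):(i + 1L + nat)]
    molid <- suppressWarnings(as.integer(substr(al, 1, 5)))
    species <- trimws(substr(al, 6, 10))
    name <- trimws(substr(al, 11, 15))
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    bad <- which(is.na(molid) | is.na(x) | is.na(y) | is.na(z) | !nzchar(name))
    if (length(bad)) {
      so_stop(sprintf("%s: unparseable atom line %d: '%s'",
                      path, i + 1L + bad[1], al[bad[1]]),
              "sterolorder_format_error")
    }
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]]))
    if (length(boxv) < 3 || any(is.na(boxv[1:3]))) {
      so_stop(sprintf("%s: line %d: expected a box line with 3 lengths", path, last),
              "sterolorder_format_error")
    }
    tm <- NA_real_
    mt <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(mt)) tm <- as.numeric(sub("t=\\s*", "", mt))
    atoms <- data.frame(molid = molid, species = species, name = name,
                        x = x, y = y, z = z, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- snapshot(atoms, boxv[1:3],
                                              frame_index = length(frames) + 1L,
                                              time = tm)
    i <- last + 1L
  }
  if (!length(frames)) {
    so_stop(sprintf("%s: no complete frame found", path), "sterolorder_format_error")
  }
  frames
}

read_pdb_frames <- function(path) {
  if (!file.exists(path)) {
    so_stop(sprintf("file not found: %s", path), "sterolorder_format_error")
  }
  box <- c(NA_real_, NA_real_, NA_real_)
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl)) {
    box <- c(as.numeric(substr(cl[1], 7, 15)), as.numeric(substr(cl[1], 16, 24)),
             as.numeric(substr(cl[1], 25, 33))) / 10
  }
  if (any(is.na(box))) {
    so_stop(sprintf("%s: missing or unparseable CRYST1 box record", path),
            "sterolorder_format_error")
  }
  p <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                error = function(e) {
                  so_stop(sprintf("%s: PDB parse failure: %s", path,
                                  conditionMessage(e)), "sterolorder_format_error")
                })
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(k) {
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
    atoms <- data.frame(molid = as.integer(p$atom$resno),
                        species = trimws(p$atom$resid),
                        name = trimws(p$atom$elety),
                        x = m[, 1], y = m[, 2], z = m[, 3],
                        stringsAsFactors = FALSE)
    snapshot(atoms, box, frame_index = k)
  })
}

#' Write coordinate snapshots
#'
#' Writes a list of snapshots to a single GRO file (concatenated frames) or
#' a single PDB file (MODEL blocks, one CRYST1 record). Output is readable
#' by [read_snapshots()] with lossless round-trip at format precision
#' (0.001 nm for GRO, 0.0001 nm for PDB).
#'
#' @param snapshots List of `mem_snapshot` objects.
#' @param path Output file path.
#' @param dialect `"gro"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(snapshots, path, dialect = c("gro", "pdb")) {
  snapshots <- as_snapshot_list(snapshots)
  if (!is.character(dialect) || !all(dialect %in% c("gro", "pdb"))) {
    so_stop(sprintf("unsupported dialect '%s'", paste(dialect, collapse = ",")),
            "sterolorder_format_error")
  }
  dialect <- match.arg(dialect)
  if (dialect == "gro") write_gro(snapshots, path) else write_pdb_frames(snapshots, path)
  invisible(path)
}

write_gro <- function(snapshots, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (s in snapshots) {
    a <- s$atoms
    tm <- if (is.na(s$time)) s$frame_index else s$time
    writeLines(sprintf("membrane snapshot, t= %.3f", tm), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$molid %% 100000L, substr(a$species, 1, 5),
                       substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
                       a$x, a$y, a$z), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", s$box[1], s$box[2], s$box[3]), con)
  }
}

# ATOM records are emitted here with the widespread 4-character residue-name
# extension (resName in columns 18-21, as GROMACS writes it); bio3d's writer
# only formats 3-character residue names so it cannot carry CHOL/DSPC.
write_pdb_frames <- function(snapshots, path) {
  boxes <- vapply(snapshots, function(s) s$box, numeric(3))
  if (length(snapshots) > 1 && any(apply(boxes, 1, function(v) diff(range(v))) > 1e-9)) {
    warning("PDB carries a single CRYST1 record; using the first frame's box",
            call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     snapshots[[1]]$box[1] * 10, snapshots[[1]]$box[2] * 10,
                     snapshots[[1]]$box[3] * 10, 90, 90, 90), con)
  for (k in seq_along(snapshots)) {
    s <- snapshots[[k]]
    a <- s$atoms
    name4 <- substr(a$name, 1, 4)
    # short names start in column 14 by PDB convention
    name4 <- ifelse(nchar(name4) < 4, sprintf(" %-3s", name4), name4)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("ATOM  %5d %4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       seq_len(nrow(a)) %% 100000L, name4,
                       substr(a$species, 1, 4), a$molid %% 10000L,
                       a$x * 10, a$y * 10, a$z * 10, 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
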