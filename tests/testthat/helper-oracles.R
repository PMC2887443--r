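# Independent brute-force oracles and small fixture builders. Everything
# here uses plain loops and explicit arithmetic, deliberately avoiding the
# package's vectorized code paths.

SM <- load_species_map()

or_mass <- function(species, name) {
  m <- unname(SM[[species]]$atom_masses[name])
  if (is.na(m)) 0 else m
}

# mass-weighted COM of one molecule (atom subset optional); assumes whole
# (already unwrapped) coordinates, as produced by the generator
or_com <- function(snap, molid, atoms = NULL) {
  a <- snap$atoms[snap$atoms$molid == molid, ]
  if (!is.null(atoms)) a <- a[a$name %in% atoms, ]
  w <- mapply(or_mass, a$species, a$name)
  c(sum(w * a$x), sum(w * a$y), sum(w * a$z)) / sum(w)
}

or_min_image <- function(d, L) d - L * round(d / L)

or_lat_dist <- function(p, q, box) {
  sqrt(or_min_image(p[1] - q[1], box[1])^2 + or_min_image(p[2] - q[2], box[2])^2)
}

# O(N^2) ordered-pair histogram of lateral COM distances per leaflet
oracle_rdf_counts <- function(snapshots, species_a, species_b, edges) {
  counts <- integer(length(edges) - 1)
  for (s in snapshots) {
    mols <- s$molecules
    ids_a <- mols$molid[mols$species == species_a]
    ids_b <- mols$molid[mols$species == species_b]
    coms <- lapply(stats::setNames(union(ids_a, ids_b), union(ids_a, ids_b)),
                   function(id) or_com(s, id))
    lf <- stats::setNames(mols$leaflet, mols$molid)
    for (i in ids_a) for (j in ids_b) {
      if (i == j) next
      if (lf[[as.character(i)]] != lf[[as.character(j)]]) next
      d <- or_lat_dist(coms[[as.character(i)]], coms[[as.character(j)]], s$box)
      for (b in seq_len(length(edges) - 1)) {
        if (d > edges[b] && d <= edges[b + 1]) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# brute-force theta90 histogram counts over (sterol, first-shell lipid) pairs
oracle_theta90_counts <- function(snapshots, sterol_species, lipid_species,
                                  edges, cutoff = 0.75) {
  counts <- integer(length(edges) - 1)
  thetas <- c()
  for (s in snapshots) {
    mols <- s$molecules
    st <- mols$molid[mols$species == sterol_species]
    li <- mols$molid[mols$species == lipid_species]
    lf <- stats::setNames(mols$leaflet, mols$molid)
    e <- SM[[sterol_species]]
    ring <- setdiff(e$ring_atoms,
                    if (!is.null(e$reconstruct)) names(e$reconstruct) else NULL)
    for (i in st) {
      p <- or_com(s, i, ring)
      for (j in li) {
        if (lf[[as.character(i)]] != lf[[as.character(j)]]) next
        c1 <- or_com(s, j, SM[[lipid_species]]$sn1_chain_atoms)
        c2 <- or_com(s, j, SM[[lipid_species]]$sn2_chain_atoms)
        d1 <- c(or_min_image(c1[1] - p[1], s$box[1]),
                or_min_image(c1[2] - p[2], s$box[2]))
        d2 <- c(or_min_image(c2[1] - p[1], s$box[1]),
                or_min_image(c2[2] - p[2], s$box[2]))
        if (min(sqrt(sum(d1^2)), sqrt(sum(d2^2))) > cutoff) next
        vc <- d2 - d1
        vr <- (d1 + d2) / 2
        th <- acos(max(-1, min(1, sum(vc * vr) /
                                  (sqrt(sum(vc^2)) * sqrt(sum(vr^2)))))) * 180 / pi
        t90 <- 90 - abs(90 - th)
        thetas <- c(thetas, t90)
        b <- min(max(findInterval(t90, edges, rightmost.closed = TRUE), 1),
                 length(edges) - 1)
        counts[b] <- counts[b] + 1L
      }
    }
  }
  list(counts = counts, thetas = thetas)
}

# brute-force sector-resolved relative-orientation counts (ordered pairs)
oracle_sector_orientation <- function(snapshots, sterol_species,
                                      r_range = c(0.8, 1.1), bin_width = 5) {
  secs <- sector_labels()
  nb <- 360 / bin_width
  out <- stats::setNames(rep(list(integer(nb)), 8), secs)
  for (s in snapshots) {
    mols <- s$molecules
    st <- mols$molid[mols$species == sterol_species]
    lf <- stats::setNames(mols$leaflet, mols$molid)
    e <- SM[[sterol_species]]
    ring <- setdiff(e$ring_atoms,
                    if (!is.null(e$reconstruct)) names(e$reconstruct) else NULL)
    coms <- lapply(stats::setNames(st, st), function(id) or_com(s, id, ring))
    apos <- function(id, nm) {
      a <- s$atoms[s$atoms$molid == id & s$atoms$name == nm, ]
      c(a$x, a$y, a$z)
    }
    for (i in st) {
      c13 <- apos(i, e$frame_atoms[["c13"]])
      c18 <- apos(i, e$frame_atoms[["c18"]])
      c10 <- apos(i, e$frame_atoms[["c10"]])
      ex <- (c18 - c13) / sqrt(sum((c18 - c13)^2))
      v <- c10 - c13
      ez <- v - sum(v * ex) * ex
      ez <- ez / sqrt(sum(ez^2))
      ey <- c(ez[2] * ex[3] - ez[3] * ex[2], ez[3] * ex[1] - ez[1] * ex[3],
              ez[1] * ex[2] - ez[2] * ex[1])
      u6 <- apos(i, e$orientation_atoms[["c6"]])
      u11 <- apos(i, e$orientation_atoms[["c11"]])
      ui <- (u11 - u6)[1:2]; ui <- ui / sqrt(sum(ui^2))
      for (j in st) {
        if (i == j || lf[[as.character(i)]] != lf[[as.character(j)]]) next
        d <- coms[[as.character(j)]] - coms[[as.character(i)]]
        d <- c(or_min_image(d[1], s$box[1]), or_min_image(d[2], s$box[2]),
               or_min_image(d[3], s$box[3]))
        fx <- sum(d * ex); fy <- sum(d * ey)
        r <- sqrt(fx^2 + fy^2)
        if (r < r_range[1] || r > r_range[2]) next
        phi <- (atan2(fy, fx) * 180 / pi) %% 360
        sec <- sector_of(phi)
        w6 <- apos(j, e$orientation_atoms[["c6"]])
        w11 <- apos(j, e$orientation_atoms[["c11"]])
        uj <- (w11 - w6)[1:2]; uj <- uj / sqrt(sum(uj^2))
        ang <- (atan2(ui[1] * uj[2] - ui[2] * uj[1],
                      ui[1] * uj[1] + ui[2] * uj[2]) * 180 / pi) %% 360
        b <- min(max(floor(ang / bin_width) + 1, 1), nb)
        out[[sec]][b] <- out[[sec]][b] + 1L
      }
    }
  }
  out
}

# rotate all atoms of every snapshot about the lab z-axis through `center`
rotate_snapshots_z <- function(snapshots, angle_deg, center = c(0, 0)) {
  th <- angle_deg * pi / 180
  lapply(snapshots, function(s) {
    x <- s$atoms$x - center[1]; y <- s$atoms$y - center[2]
    s$atoms$x <- center[1] + cos(th) * x - sin(th) * y
    s$atoms$y <- center[2] + sin(th) * x + cos(th) * y
    s
  })
}

# re-center a snapshot inside a much larger box so that minimum-image wrap
# never activates (all content within the central region)
embed_in_large_box <- function(snap, big = 48) {
  shift <- big / 2 - snap$box[1:2] / 2
  snap$atoms$x <- snap$atoms$x + shift[1]
  snap$atoms$y <- snap$atoms$y + shift[2]
  snap$box <- c(x = big, y = big, z = unname(snap$box[3]))
  snap
}

# build a snapshot from an explicit placement table (species, x, y, psi)
# using the rigid templates, mirroring the generator's construction
place_snapshot <- function(tab, box, frame_index = 1L) {
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    tm <- if (SM[[tab$species[i]]]$kind == "sterol") {
      sterol_template(tab$species[i])
    } else phospholipid_template(tab$species[i])
    th <- tab$psi[i] * pi / 180
    data.frame(molid = i, species = tab$species[i], name = rownames(tm),
               x = tab$x[i] + cos(th) * tm[, 1] - sin(th) * tm[, 2],
               y = tab$y[i] + sin(th) * tm[, 1] + cos(th) * tm[, 2],
               z = 5 + tm[, 3], stringsAsFactors = FALSE)
  }))
  snapshot(rows, box, frame_index = frame_index,
           leaflet = stats::setNames(rep("upper", nrow(tab)), seq_len(nrow(tab))))
}

circ_mean <- function(x) {
  (atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi) %% 360
}
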