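# Rigid molecular templates used by the synthetic leaflet generator.
#
# These are stylized united-atom geometries (synthetic, not force-field
# coordinates): the sterol ring is a planar ladder in its own y-z plane
# with the two off-plane methyls displaced along +x, bond-scale spacings
# (~0.13-0.15 nm), the origin at C13 and the headgroup toward +z. The
# template satisfies the frame conventions exactly: C18 sits at
# (0.153, 0, 0) and C10/C19 lie in the template xz-plane. The three
# substituents of C13 that are used for tetrahedral reconstruction of C18
# (C12, C14, C17) are placed at exact tetrahedral directions, so the
# reconstructed site coincides with the template C18.

#' Rigid sterol template
#'
#' @param species `"CHOL"` (all 17 ring sites incl. the off-plane methyls)
#'   or `"DCHL"` (the flat analogue: same geometry with C18/C19 removed).
#' @return n x 3 matrix of positions (nm) with atom-name rownames; C13 at
#'   the origin, ring plane x = 0, head toward +z.
#' @export
sterol_template <- function(species = c("CHOL", "DCHL")) {
  species <- match.arg(species)
  # C12/C14/C17 sit at exact tetrahedral directions around C13 (the fourth
  # vertex being C18 at +x), so tetrahedral reconstruction of C18 is exact.
  tet <- 0.15 * cbind(-1 / 3, sqrt(8) / 3 * cos(deg2rad(c(20, 140, 260))),
                      sqrt(8) / 3 * sin(deg2rad(c(20, 140, 260))))
  m <- rbind(
    C13 = c(0, 0, 0),
    C12 = tet[1, ],
    C14 = tet[2, ],
    C17 = tet[3, ],
    C15 = c(0.13, -0.21, -0.13),
    C16 = c(0.10, -0.05, -0.21),
    C11 = c(0.06, 0.21, 0.22),
    C9  = c(0.00, 0.00, 0.28),     # C13/C9/C10/C5/C3 stack on the long axis
    C8  = c(-0.16, -0.13, 0.22),
    C7  = c(0.14, -0.08, 0.36),
    C6  = c(0.05, -0.13, 0.50),
    C10 = c(0.00, 0.00, 0.42),
    C5  = c(0.00, 0.00, 0.56),
    C1  = c(-0.13, 0.10, 0.50),
    C2  = c(-0.04, 0.26, 0.64),
    C3  = c(0.00, 0.00, 0.70),
    C4  = c(-0.09, -0.18, 0.64),
    C18 = c(0.153, 0, 0),          # off-plane methyls, +x
    C19 = c(0.208, 0, 0.42),
    O3  = c(0, 0.00, 0.84),
    C20 = c(-0.05, 0.071, -0.26),  # short stylized tail below C17
    C22 = c(-0.05, 0.071, -0.40),
    C25 = c(-0.05, 0.071, -0.54))
  colnames(m) <- c("x", "y", "z")
  if (species == "DCHL") m <- m[!rownames(m) %in% c("C18", "C19"), ]
  m
}

#' Rigid phospholipid template
#'
#' Two straight 18-carbon united-atom acyl chains hanging at lateral
#' offsets of +/- 0.35 nm along the template x-axis (chain-COM separation
#' 0.70 nm), with the headgroup anchor P and choline N on the molecular
#' axis above. Rotating the template about z by psi sets the sn-1 -> sn-2
#' chain axis to lab angle psi.
#'
#' @param species `"DSPC"` or `"DOPC"` (same rigid geometry; they differ
#'   only in configured masses).
#' @return n x 3 matrix of positions (nm) with atom-name rownames.
#' @export
phospholipid_template <- function(species = c("DSPC", "DOPC")) {
  species <- match.arg(species)
  z <- 1.25 - 0.125 * (1:18)
  sn1 <- cbind(-0.35, 0, z)
  rownames(sn1) <- paste0("C", 1:18, "A")
  sn2 <- cbind(0.35, 0, z)
  rownames(sn2) <- paste0("C", 1:18, "B")
  head <- rbind(P = c(0, 0, 1.45), N = c(0, 0, 1.60))
  m <- rbind(sn1, sn2, head)
  colnames(m) <- c("x", "y", "z")
  m
}

template_for <- function(species) {
  switch(species,
         CHOL = sterol_template("CHOL"),
         DCHL = sterol_template("DCHL"),
         DSPC = phospholipid_template("DSPC"),
         DOPC = phospholipid_template("DOPC"),
         so_stop(sprintf("no rigid template for species '%s'", species),
                 "sterolorder_input_error"))
}
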