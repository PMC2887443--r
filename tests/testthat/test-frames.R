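rotmat_z <- function(a) {
  t <- a * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}
random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("frame construction follows the C13/C18/C10 conventions", {
  fr <- build_sterol_frame(c(0, 0, 0), c(0.15, 0, 0), c(0.1, 0, 0.5))
  expect_equal(fr$ex, c(1, 0, 0))
  expect_equal(fr$ez, c(0, 0, 1))
  expect_equal(fr$ey, c(0, 1, 0))
  expect_error(build_sterol_frame(c(0, 0, 0), c(0.15, 0, 0), c(0.3, 0, 0)),
               class = "sterolorder_degenerate_geometry")
  expect_error(build_sterol_frame(c(0, 0, 0), c(0, 0, 0), c(0.1, 0, 0.5)),
               class = "sterolorder_degenerate_geometry")
})

test_that("frames are orthonormal, right-handed and rotation-equivariant", {
  set.seed(31)
  for (i in 1:25) {
    c13 <- rnorm(3); c18 <- c13 + rnorm(3); c10 <- c13 + rnorm(3)
    fr <- build_sterol_frame(c13, c18, c10)
    B <- cbind(fr$ex, fr$ey, fr$ez)
    expect_lt(max(abs(t(B) %*% B - diag(3))), 1e-9)
    cross <- c(fr$ex[2] * fr$ey[3] - fr$ex[3] * fr$ey[2],
               fr$ex[3] * fr$ey[1] - fr$ex[1] * fr$ey[3],
               fr$ex[1] * fr$ey[2] - fr$ex[2] * fr$ey[1])
    expect_lt(max(abs(cross - fr$ez)), 1e-9)
    # C10 lies in the xz-plane at positive z
    fc <- to_frame_coords(fr, matrix(c10, 1))
    expect_lt(abs(fc$y), 1e-9)
    expect_gt(fc$z, 0)
    R <- random_rotation(); t0 <- rnorm(3)
    fr2 <- build_sterol_frame(R %*% c13 + t0, R %*% c18 + t0, R %*% c10 + t0)
    expect_lt(max(abs(cbind(fr2$ex, fr2$ey, fr2$ez) - R %*% B)), 1e-9)
  }
})

test_that("tetrahedral reconstruction satisfies the geometric identities", {
  p <- reconstruct_tetrahedral_substituent(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                           c(0, 0, 1), bond_length = 0.153)
  expect_equal(p, 0.153 * c(-1, -1, -1) / sqrt(3), tolerance = 1e-12)
  # methane minus one vertex: reconstructed bond makes 109.47 deg with each
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  q <- reconstruct_tetrahedral_substituent(c(0, 0, 0), tet[1, ], tet[2, ],
                                           tet[3, ], bond_length = 0.153)
  for (k in 1:3) {
    ang <- acos(sum(q * tet[k, ]) / sqrt(sum(q^2))) * 180 / pi
    expect_equal(ang, 109.4712, tolerance = 0.01)
  }
  # coplanar neighbors at 120 deg spacing: zero bond-vector sum
  cop <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  expect_error(reconstruct_tetrahedral_substituent(c(0, 0, 0), cop[1, ],
                                                   cop[2, ], cop[3, ]),
               class = "sterolorder_degenerate_geometry")
})

test_that("frame coordinates and phi follow the stated conventions", {
  fr <- build_sterol_frame(c(1, 2, 3), c(1.15, 2, 3), c(1.1, 2, 3.5))
  at_origin <- to_frame_coords(fr, c(1, 2, 3))
  expect_equal(unlist(at_origin), c(x = 0, y = 0, z = 0, r_xy = 0, phi = 0))
  ey_pt <- to_frame_coords(fr, c(1, 2, 3) + fr$ey)
  expect_equal(ey_pt$phi, 90)
  expect_equal(c(ey_pt$x, ey_pt$y, ey_pt$z), c(0, 1, 0), tolerance = 1e-12)
  # rigid rotation + translation of everything leaves frame coords unchanged
  set.seed(5)
  pts <- matrix(rnorm(30), 10, 3)
  base <- to_frame_coords(fr, pts)
  R <- random_rotation(); t0 <- rnorm(3)
  fr2 <- build_sterol_frame(R %*% c(1, 2, 3) + t0, R %*% c(1.15, 2, 3) + t0,
                            R %*% c(1.1, 2, 3.5) + t0)
  moved <- to_frame_coords(fr2, t(R %*% t(pts) + t0))
  expect_lt(max(abs(as.matrix(base) - as.matrix(moved))), 1e-9)
})

test_that("sectors tile the circle with the printed half-open ranges", {
  expect_identical(sector_of(45), "NE")
  expect_identical(sector_of(0), "E")
  expect_identical(sector_of(350), "E")
  expect_identical(sector_of(22.5), "NE")   # boundary goes anticlockwise-later
  expect_identical(sector_of(67.5), "N")
  expect_identical(sector_of(122.5), "NW")
  expect_identical(sector_of(157.5), "W")
  expect_identical(sector_of(337.5), "E")
  phi <- seq(0, 359.75, by = 0.25)
  expect_identical(sector_of(phi), sector_of(phi + 360))
  expect_setequal(unique(sector_of(phi)), sector_labels())
  # printed ranges: N spans 55 deg, NW 35 deg, the rest 45 deg
  tab <- table(sector_of(phi))
  expect_equal(unname(tab[["N"]] / 4), 220 / 4 * 1)
  expect_equal(unname(tab[["NW"]]), 35 * 4)
  expect_error(sector_of(NaN), class = "sterolorder_input_error")
})

test_that("rigid templates satisfy the frame and chain-geometry invariants", {
  tm <- sterol_template("CHOL")
  fr <- build_sterol_frame(tm["C13", ], tm["C18", ], tm["C10", ])
  fc18 <- to_frame_coords(fr, tm["C18", , drop = FALSE])
  expect_equal(c(fc18$x, fc18$y, fc18$z), c(0.153, 0, 0), tolerance = 1e-9)
  fc19 <- to_frame_coords(fr, tm["C19", , drop = FALSE])
  expect_lt(abs(fc19$y), 1e-9)
  # Dchol reconstruction of C18 lands on the template C18 position
  td <- sterol_template("DCHL")
  rec <- reconstruct_tetrahedral_substituent(td["C13", ], td["C12", ],
                                             td["C14", ], td["C17", ], 0.153)
  expect_equal(unname(rec), unname(tm["C18", ]), tolerance = 1e-9)
  # phospholipid chain COM separation within the observed 0.55-0.85 nm range
  pt <- phospholipid_template("DSPC")
  sn1 <- colMeans(pt[paste0("C", 1:18, "A"), ])
  sn2 <- colMeans(pt[paste0("C", 1:18, "B"), ])
  sep <- sqrt(sum((sn1[1:2] - sn2[1:2])^2))
  expect_gte(sep, 0.55)
  expect_lte(sep, 0.85)
})
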