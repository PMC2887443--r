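test_that("mole fractions map to the study compositions", {
  expect_identical(mole_fraction_to_counts(128, 0.20), 32L)
  expect_identical(mole_fraction_to_counts(128, 0.10), 14L)
  expect_identical(mole_fraction_to_counts(128, 0), 0L)
  expect_error(mole_fraction_to_counts(128, 1), class = "sterolorder_input_error")
})

test_that("identical parameters and seed reproduce byte-identical output", {
  p <- generator_params(n_lipids = 6, n_sterols = 8, mode = "triangular",
                        box = c(14, 14, 10), n_frames = 2, seed = 42)
  g1 <- generate_leaflet(p)
  g2 <- generate_leaflet(p)
  expect_identical(g1$snapshots, g2$snapshots)
  expect_identical(g1$ground_truth, g2$ground_truth)
  f1 <- tempfile(fileext = ".gro"); f2 <- tempfile(fileext = ".gro")
  write_snapshots(g1$snapshots, f1, "gro")
  write_snapshots(g2$snapshots, f2, "gro")
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the configuration
  g3 <- generate_leaflet(generator_params(n_lipids = 6, n_sterols = 8,
                                          mode = "triangular",
                                          box = c(14, 14, 10), n_frames = 2,
                                          seed = 43))
  expect_false(identical(g1$snapshots, g3$snapshots))
})

test_that("composition is conserved across frames and matches parameters", {
  gen <- generate_leaflet(generator_params(n_lipids = 10, n_sterols = 8,
                                           mode = "triangular",
                                           box = c(14, 14, 10), n_frames = 3,
                                           seed = 2))
  for (s in gen$snapshots) {
    tab <- table(s$molecules$species)
    expect_equal(unname(tab[["CHOL"]]), 8)
    expect_equal(unname(tab[["DSPC"]]), 10)
  }
  gt <- gen$ground_truth
  expect_setequal(unique(gt$role[gt$species == "CHOL"]),
                  c("center", "satellite"))
})

test_that("hard-disk mode respects the exclusion radius", {
  gen <- generate_leaflet(generator_params(n_lipids = 0, n_sterols = 30,
                                           mode = "hard_disk", hard_core = 0.8,
                                           box = c(10, 10, 10), n_frames = 2,
                                           seed = 5))
  for (s in gen$snapshots) {
    gt <- gen$ground_truth[gen$ground_truth$frame == s$frame_index, ]
    d <- as.matrix(stats::dist(cbind(gt$x, gt$y)))
    # periodic check via the package-independent image enumeration
    for (i in 1:(nrow(gt) - 1)) for (j in (i + 1):nrow(gt)) {
      expect_gte(or_lat_dist(c(gt$x[i], gt$y[i]), c(gt$x[j], gt$y[j]), s$box),
                 0.8)
    }
  }
})

test_that("infeasible packings raise a packing error with the achieved state", {
  err <- expect_error(
    generate_leaflet(generator_params(n_lipids = 0, n_sterols = 60,
                                      mode = "hard_disk", hard_core = 0.9,
                                      box = c(5, 5, 10), n_frames = 1,
                                      seed = 1)),
    class = "sterolorder_packing_error")
  expect_match(conditionMessage(err), "density")
})

test_that("motif ground truth reproduces the placed geometry", {
  gen <- generate_leaflet(generator_params(n_lipids = 0, n_sterols = 12,
                                           mode = "triangular",
                                           box = c(16, 16, 10),
                                           spacing = 1.0, angular_jitter = 5,
                                           n_frames = 2, seed = 31))
  gt <- gen$ground_truth
  sat <- gt[gt$role == "satellite", ]
  expect_true(all(abs(sat$place_radius - 1.0) < 1e-9))  # no radial jitter
  # recorded placement angle is the jittered frame angle: positions rebuild
  for (k in seq_len(nrow(sat))) {
    ctr <- gt[gt$frame == sat$frame[k] & gt$role == "center" &
                gt$motif == sat$motif[k], ]
    lab <- (ctr$psi + sat$place_angle[k]) * pi / 180
    ex <- (ctr$x + sat$place_radius[k] * cos(lab)) %% 16
    ey <- (ctr$y + sat$place_radius[k] * sin(lab)) %% 16
    expect_equal(c(ex, ey), c(sat$x[k], sat$y[k]), tolerance = 1e-9)
  }
  # jittered angles concentrate around the set motif angles
  dev <- vapply(seq_len(nrow(sat)), function(k) {
    min(abs((sat$place_angle[k] - c(180, 45, 315) + 180) %% 360 - 180))
  }, numeric(1))
  expect_lt(max(dev), 25)
  # satellites are anti-aligned with their centers by default
  expect_true(all(sat$orient_offset == 180))
  # C13 sits at the recorded placement point
  s <- gen$snapshots[[1]]
  g1 <- gt[gt$frame == 1, ]
  c13 <- s$atoms[s$atoms$name == "C13", ]
  expect_equal(c13$x[match(g1$molid, c13$molid)], g1$x, tolerance = 1e-9)
})

test_that("generated boxes and coordinates survive the I/O round trip", {
  gen <- generate_leaflet(generator_params(n_lipids = 3, n_sterols = 2,
                                           mode = "csr", box = c(6.5, 5.5, 9),
                                           n_frames = 2, seed = 3))
  for (dia in c("gro", "pdb")) {
    f <- tempfile(fileext = paste0(".", dia))
    write_snapshots(gen$snapshots, f, dia)
    back <- read_snapshots(f, SM)
    expect_length(back, 2)
    expect_equal(unname(back[[1]]$box), c(6.5, 5.5, 9), tolerance = 1e-6)
    tol <- if (dia == "gro") 5.01e-4 else 5.01e-5
    expect_lt(max(abs(back[[2]]$atoms$x - gen$snapshots[[2]]$atoms$x)), tol)
  }
  expect_error(write_snapshots(gen$snapshots, tempfile(), "xtc"),
               class = "sterolorder_format_error")
})
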