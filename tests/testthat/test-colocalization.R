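# place a sterol at the box center and one lipid whose nearest chain COM
# sits at exactly `d` nm from the sterol ring COM, chains aligned radially
sterol_lipid_snapshot <- function(d, box = c(12, 12, 10)) {
  s0 <- place_snapshot(data.frame(species = "CHOL", x = 6, y = 6, psi = 0),
                       box)
  rc <- or_com(s0, 1, SM$CHOL$ring_atoms)
  # lipid psi = 0: chains at x -/+ 0.35 of its center; put sn-1 nearer
  tab <- data.frame(species = c("CHOL", "DSPC"),
                    x = c(6, rc[1] + d + 0.35), y = c(6, rc[2]), psi = 0)
  place_snapshot(tab, box)
}

test_that("first-shell selection applies the 0.75 nm chain-COM cutoff", {
  s_in <- sterol_lipid_snapshot(0.70)
  expect_identical(select_first_shell_lipids(s_in, 1, SM), 2L)
  s_out <- sterol_lipid_snapshot(0.80)
  expect_identical(select_first_shell_lipids(s_out, 1, SM), integer(0))
  # both chains within the shell: the lipid is reported once
  s_both <- sterol_lipid_snapshot(0.3)
  expect_identical(select_first_shell_lipids(s_both, 1, SM), 2L)
  expect_error(select_first_shell_lipids(s_in, 2, SM),
               class = "sterolorder_input_error")
})

test_that("co-localization angle distinguishes collinear and facing pairs", {
  expect_equal(colocalization_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(colocalization_angle(c(0, 0, 0), c(1, 0.4, 0), c(1, -0.4, 0)),
               90)
  expect_error(colocalization_angle(c(0, 0, 0), c(1, 0, 0), c(1, 0, 5)),
               class = "sterolorder_degenerate_geometry")
  # chain-label swap maps theta -> 180 - theta
  set.seed(41)
  for (i in 1:20) {
    st <- c(rnorm(2), 0); a <- c(rnorm(2), 0); b <- c(rnorm(2), 0)
    th1 <- colocalization_angle(st, a, b)
    th2 <- colocalization_angle(st, b, a)
    expect_equal(th1, 180 - th2, tolerance = 1e-9)
  }
})

test_that("theta-90 folding follows 90 - |90 - theta| and its fixed points", {
  expect_identical(fold_theta90(120), 60)
  expect_identical(fold_theta90(180), 0)
  expect_identical(fold_theta90(90), 90)
  th <- seq(0, 180, by = 0.5)
  expect_equal(fold_theta90(th), 90 - abs(90 - th))
  expect_equal(fold_theta90(th), fold_theta90(180 - th))
  expect_error(fold_theta90(190), class = "sterolorder_input_error")
  expect_error(fold_theta90(-1), class = "sterolorder_input_error")
})

test_that("facing-only placements put all mass in the top theta-90 bin", {
  gen <- generate_leaflet(generator_params(
    n_lipids = 40, n_sterols = 8, mode = "hard_disk", hard_core = 1.6,
    spacing = 2, box = c(12, 12, 10),
    lipid_placement = list(rule = "shell", orientation = "facing"),
    n_frames = 2, seed = 14))
  d <- theta90_distribution(gen$snapshots, "CHOL", "DSPC", SM)
  expect_gt(attr(d, "n_pairs"), 0)
  expect_equal(d$freq[nrow(d)], 1)
  expect_equal(sum(d$freq), 1, tolerance = 1e-9)
})

test_that("theta-90 histograms equal the brute-force pair enumeration", {
  gen <- generate_leaflet(generator_params(n_lipids = 14, n_sterols = 6,
                                           mode = "csr", box = c(5, 5, 10),
                                           n_frames = 2, seed = 19))
  d <- theta90_distribution(gen$snapshots, "CHOL", "DSPC", SM, bin_width = 5)
  oracle <- oracle_theta90_counts(gen$snapshots, "CHOL", "DSPC",
                                  seq(0, 90, by = 5))
  expect_identical(as.integer(d$count), oracle$counts)
  expect_equal(attr(d, "n_pairs"), length(oracle$thetas))
  # sector split conserves the total count
  secs <- theta90_distribution(gen$snapshots, "CHOL", "DSPC", SM,
                               bin_width = 5, sector_resolved = TRUE)
  expect_equal(sum(vapply(secs, function(x) sum(x$count), numeric(1))),
               sum(d$count))
  # global chain relabeling leaves the folded histogram unchanged
  swapped <- lapply(gen$snapshots, function(s) {
    nm <- s$atoms$name
    a_chain <- grepl("^C[0-9]+A$", nm)
    b_chain <- grepl("^C[0-9]+B$", nm)
    s$atoms$name[a_chain] <- sub("A$", "B", nm[a_chain])
    s$atoms$name[b_chain] <- sub("B$", "A", nm[b_chain])
    s
  })
  d2 <- theta90_distribution(swapped, "CHOL", "DSPC", SM, bin_width = 5)
  expect_identical(d$count, d2$count)
})

test_that("empty neighborhoods yield a flagged empty distribution", {
  s <- place_snapshot(data.frame(species = c("CHOL", "DSPC"),
                                 x = c(2, 8), y = c(2, 8), psi = 0),
                      c(16, 16, 10))
  expect_identical(select_first_shell_lipids(s, 1, SM), integer(0))
  d <- theta90_distribution(list(s), "CHOL", "DSPC", SM)
  expect_true(attr(d, "empty"))
  expect_equal(attr(d, "n_pairs"), 0)
})

test_that("chain separation statistics are recovered", {
  s <- sterol_lipid_snapshot(0.5)
  cs <- chain_separation_summary(list(s), "DSPC", SM, sterol_species = "CHOL")
  expect_equal(cs$mean, 0.7, tolerance = 1e-9)
  expect_equal(cs$sd, 0)
  # Gaussian-separation molecules: mean/SD recovered within sampling error
  set.seed(33)
  seps <- pmax(rnorm(150, 0.7, 0.2), 0.05)
  tmpl <- phospholipid_template("DSPC")
  snaps <- lapply(1:3, function(f) {
    idx <- ((f - 1) * 50 + 1):(f * 50)
    rows <- do.call(rbind, lapply(seq_along(idx), function(i) {
      tm <- tmpl
      tm[grepl("A$", rownames(tm)), 1] <- -seps[idx[i]] / 2
      tm[grepl("B$", rownames(tm)), 1] <- seps[idx[i]] / 2
      cx <- ((i - 1) %% 7) * 2.6 + 1.5
      cy <- ((i - 1) %/% 7) * 2.6 + 1.5
      data.frame(molid = i, species = "DSPC", name = rownames(tm),
                 x = cx + tm[, 1], y = cy + tm[, 2], z = 5 + tm[, 3])
    }))
    snapshot(rows, c(22, 22, 10), frame_index = f)
  })
  cs2 <- chain_separation_summary(snaps, "DSPC", SM)
  expect_equal(cs2$mean, mean(seps), tolerance = 1e-9)
  expect_equal(cs2$sd, sd(seps), tolerance = 1e-9)
  expect_equal(cs2$mean, 0.7, tolerance = 0.06)
  expect_equal(cs2$sd, 0.2, tolerance = 0.06)
})
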