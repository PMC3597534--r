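test_that("centre-of-mass distances are exact and translation invariant", {
  s <- molecular_structure(data.frame(
    atom_name = "CA", residue_name = "ALA", residue_index = 1:2,
    chain_id = c("A", "B"), x = c(0, 50), y = 0, z = 0,
    stringsAsFactors = FALSE))
  fr <- static_frames(s, n_frames = 4)
  d <- com_distance(fr, 1, 2)
  expect_equal(d$distance_nm, rep(5, 4))
  expect_equal(com_distance(fr, 1:2, 1:2)$distance_nm, rep(0, 4))
  # rigid translation of every frame leaves the series unchanged
  fr2 <- fr
  fr2$coords <- fr2$coords + 123.4
  expect_equal(com_distance(fr2, 1, 2), d)
  expect_error(com_distance(fr, integer(0), 2), "empty selection")
})

test_that("mass weighting shifts the centre of mass as expected", {
  s <- molecular_structure(data.frame(
    atom_name = "CA", residue_name = "ALA", residue_index = 1:3,
    chain_id = c("A", "A", "B"), x = c(0, 10, 40), y = 0, z = 0,
    stringsAsFactors = FALSE))
  fr <- static_frames(s, 1)
  # masses 3:1 pull the A-group COM to x = 2.5 A
  d <- com_distance(fr, 1:2, 3, masses = c(3, 1, 1))
  expect_equal(d$distance_nm, 3.75)
})

test_that("window averaging is a truncated boxcar with exact edge behaviour", {
  # sample spacing 2^-7 keeps the boxcar windows exactly symmetric
  x <- seq(0, 4, by = 1 / 128)
  expect_equal(window_average(x, rep(7, length(x)))$smoothed,
               rep(7, length(x)))
  # linearity preserved in the interior; edge deviation <= slope * w / 4
  slope <- 3
  w <- 0.5
  sm <- window_average(x, slope * x, window = w)$smoothed
  interior <- x > w / 2 & x < max(x) - w / 2
  expect_equal(sm[interior], slope * x[interior], tolerance = 1e-9)
  expect_lte(max(abs(sm - slope * x)), slope * w / 4 + slope / 128)
  # single spike of height h averaged over the n points in the window
  y <- rep(0, 101); y[51] <- 10
  xs <- seq_len(101)  # spacing 1, window 5 -> 5 points in window
  sm2 <- window_average(xs, y, window = 4.5)
  expect_equal(sm2$smoothed[51], 10 / 5)
  expect_equal(sm2$smoothed[10], 0)
  # idempotent on constants, commutes with adding a constant
  base <- window_average(x, sin(x), window = w)$smoothed
  shifted <- window_average(x, sin(x) + 2, window = w)$smoothed
  expect_equal(shifted, base + 2)
  expect_error(window_average(numeric(0), numeric(0)), "empty")
})

test_that("work integration follows the guide coordinate exactly", {
  tr <- force_trace(seq(0, 100, length.out = 51),
                    seq(0, 2, length.out = 51), rep(100, 51))
  w <- integrate_work(tr)
  expect_equal(w$work_pN_nm[51], 200)
  expect_equal(w$work_kBT[51], 200 / kbt_pN_nm(310))
  # linear force ramp: a x over [0, L] -> a L^2 / 2 (trapezoid-exact)
  a <- 40; L <- 3
  x <- seq(0, L, length.out = 201)
  w2 <- integrate_work(force_trace(seq_along(x), x, a * x))
  expect_equal(w2$work_pN_nm[201], a * L^2 / 2, tolerance = 1e-10)
  expect_equal(integrate_work(force_trace(1:5, 1:5, rep(0, 5)))$work_pN_nm,
               rep(0, 5))
  expect_error(integrate_work(force_trace(1:4, c(0, 1, 0.5, 2), rep(1, 4))),
               "monotone")
  expect_error(integrate_work(force_trace(1, 1, 1)), "2 samples")
})

test_that("work integration matches fine-grid quadrature on a smooth trace", {
  x <- seq(0, 3, length.out = 5001)
  f <- function(z) 50 + 30 * sin(2 * z)
  w <- integrate_work(force_trace(seq_along(x), x, f(x)))
  ref <- stats::integrate(f, 0, 3, rel.tol = 1e-12)$value
  expect_equal(w$work_pN_nm[5001], ref, tolerance = 1e-6)
})

test_that("force traces round-trip through CSV and TSV", {
  tr <- force_trace(c(0, 1, 2), c(0, 0.1, 0.2), c(5, 6, 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_force_trace(tr, f)
  expect_equal(as.data.frame(read_force_trace(f)), as.data.frame(tr))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_force_trace(tr, fc, sep = ",")
  expect_equal(as.data.frame(read_force_trace(fc)), as.data.frame(tr))
  expect_error(force_trace(c(0, 0), c(0, 1), c(1, 1)), "increasing")
})

test_that("density profile recovers uniform and contrasted generating fields", {
  mp <- make_membrane_patch(monomer_x_nm = NULL, n_snapshots = 9, seed = 6)
  dp <- lipid_density_profile(mp$frames, mp$tails, c(0, 0, 0), c(10, 0, 0),
                              bin_width_nm = 0.5, half_width_nm = 1,
                              z_range_nm = c(-2, 0))
  counts <- attr(dp, "counts")
  # flat field: every bin within 3 Poisson SE of the baseline
  per_bin_se <- sqrt(rowMeans(counts)) / sqrt(ncol(counts))
  vol <- attr(dp, "bin_volume_nm3")
  expect_true(all(abs(dp$density_per_nm3 - 100) <= 3 * per_bin_se / vol + 1e-9))
  # conservation: per snapshot, binned counts equal the atoms in the slab
  xyz <- ang_to_nm(mp$frames$coords[mp$tails, , 1])
  inside <- xyz[, 1] >= 0 & xyz[, 1] <= max(dp$bin_center_nm) + 0.25 &
    abs(xyz[, 2]) <= 1 & xyz[, 3] >= -2 & xyz[, 3] <= 0
  expect_equal(sum(counts[, 1]), sum(inside))
  # empty region reports zero
  dp0 <- lipid_density_profile(mp$frames, mp$tails, c(0, 0, 30), c(10, 0, 30),
                               half_width_nm = 1, z_range_nm = c(28, 30))
  expect_true(all(dp0$density_per_nm3 == 0))
  expect_error(lipid_density_profile(mp$frames, mp$tails, c(0, 0, 0),
                                     c(10, 0, 0), half_width_nm = 0),
               "zero-volume")
  expect_error(lipid_density_profile(mp$frames, mp$tails, c(0, 0, 0),
                                     c(0, 0, 0)), "distinct")
})

test_that("an injected density contrast is recovered within 3 standard errors", {
  mp <- make_membrane_patch(contrast_x_range_nm = c(4, 6),
                            contrast_factor = 0.2, monomer_x_nm = NULL,
                            n_snapshots = 9, seed = 5)
  dp <- lipid_density_profile(mp$frames, mp$tails, c(0, 0, 0), c(10, 0, 0),
                              bin_width_nm = 0.5, half_width_nm = 1,
                              z_range_nm = c(-2, 0))
  counts <- attr(dp, "counts")
  inb <- dp$bin_center_nm > 4.25 & dp$bin_center_nm < 5.75
  outb <- dp$bin_center_nm < 3.75 | dp$bin_center_nm > 6.25
  per_snap <- colSums(counts[inb, ]) / sum(inb) /
    (colSums(counts[outb, ]) / sum(outb)) - 1
  se <- stats::sd(per_snap) / sqrt(length(per_snap))
  expect_lte(abs(mean(per_snap) - 0.2), 3 * se)
})

test_that("shell tracking distinguishes co-moving from stationary chains", {
  s <- molecular_structure(data.frame(
    atom_name = "C", residue_name = "POPC", residue_index = 1:3,
    chain_id = c("A", "L", "M"), x = c(0, 10, 20), y = 0, z = 0,
    stringsAsFactors = FALSE))
  n <- 6
  arr <- array(rep(coords(s), n), dim = c(3, 3, n))
  v_ang_ps <- 2
  for (m in seq_len(n)) {
    # monomer moves away from the stationary chain; chain L co-moves
    arr[1, 1, m] <- arr[1, 1, m] - v_ang_ps * (m - 1)
    arr[2, 1, m] <- arr[2, 1, m] - v_ang_ps * (m - 1)
  }
  fr <- trajectory_frames(s, arr, dt_ps = 1)
  ts <- track_shell(fr, 1, list(co = 2, still = 3))
  expect_equal(ts$co, rep(1, n))
  expect_equal(diff(ts$still)[n - 1], ang_to_nm(v_ang_ps), tolerance = 1e-9)
  expect_equal(track_shell(fr, 1, list(self = 1))$self, rep(0, n))
  expect_error(track_shell(fr, 1, list(bad = integer(0))), "empty")
})

test_that("membrane thickness profile reads the generated geometry", {
  mp <- make_membrane_patch(monomer_x_nm = NULL,
                            channel = list(x_range_nm = c(4, 6),
                                           thickness_nm = 3),
                            n_snapshots = 5, seed = 7)
  th <- membrane_thickness_profile(mp$frames, mp$heads_upper,
                                   mp$heads_lower, c(0, 0, 0), c(10, 0, 0),
                                   bin_width_nm = 0.5)
  centre <- which.min(abs(th$bin_center_nm - 5))
  edge <- which.min(abs(th$bin_center_nm - 1))
  expect_equal(th$thickness_nm[centre], 3, tolerance = 0.1)
  expect_equal(th$thickness_nm[edge], 4, tolerance = 0.1)
  # identical selections give zero gap; empty bins give NA, not zero
  th0 <- membrane_thickness_profile(mp$frames, mp$heads_upper,
                                    mp$heads_upper, c(0, 0, 0), c(10, 0, 0))
  expect_true(all(th0$thickness_nm == 0, na.rm = TRUE))
  thna <- membrane_thickness_profile(mp$frames, mp$heads_upper,
                                     mp$heads_lower, c(0, 0, 0),
                                     c(0, 0, -30))
  expect_true(anyNA(thna$thickness_nm))
})

test_that("group interaction energy reproduces Lennard-Jones landmarks", {
  par <- default_nonbonded_params()
  sig <- par$sigma_nm[par$atom_name == "C"]
  eps <- par$epsilon_kJ_mol[par$atom_name == "C"]
  rmin_ang <- nm_to_ang(2^(1 / 6) * sig)
  s <- molecular_structure(data.frame(
    atom_name = "C", residue_name = "POPC", residue_index = 1:2,
    chain_id = c("A", "B"), x = c(0, rmin_ang), y = 0, z = 0,
    stringsAsFactors = FALSE))
  fr <- static_frames(s, 1)
  e <- group_interaction_energy(fr, 1, 2)
  expect_equal(e$lj_kJ_mol, -eps, tolerance = 1e-12)
  # beyond the 1.2 nm cutoff both terms vanish exactly
  s2 <- s; s2$atoms$x[2] <- nm_to_ang(1.3)
  e2 <- group_interaction_energy(static_frames(s2, 1), 1, 2)
  expect_equal(e2$lj_kJ_mol, 0)
  expect_equal(e2$coulomb_kJ_mol, 0)
  # symmetry under swapping the groups
  mp <- make_membrane_patch(monomer_x_nm = c(2.5, 3.5), n_snapshots = 2,
                            box_nm = c(6, 3, 4), seed = 3,
                            baseline_density_per_nm3 = 5)
  selA <- select_atoms(mp$frames$struct, chain = "A")
  selB <- select_atoms(mp$frames$struct, chain = "B")
  eab <- group_interaction_energy(mp$frames, selA, selB)
  eba <- group_interaction_energy(mp$frames, selB, selA)
  expect_equal(eab, eba, tolerance = 1e-12)
  expect_error(group_interaction_energy(fr, 1:2, 2), "overlap")
  s3 <- s; s3$atoms$atom_name[2] <- "XX"
  expect_error(group_interaction_energy(static_frames(s3, 1), 1, 2), "XX")
})

test_that("Coulomb term uses the fixed-dielectric truncated form", {
  s <- molecular_structure(data.frame(
    atom_name = c("P", "N"), residue_name = "POPC", residue_index = 1:2,
    chain_id = c("A", "B"), x = c(0, 10), y = 0, z = 0,
    stringsAsFactors = FALSE))
  e <- group_interaction_energy(static_frames(s, 1), 1, 2, dielectric = 2)
  # q = -0.5 and +0.5 at 1 nm with eps_r = 2
  expect_equal(e$coulomb_kJ_mol, 138.935458 * (-0.25) / 2, tolerance = 1e-9)
})
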