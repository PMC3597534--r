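two_node_structure <- function(d) {
  molecular_structure(data.frame(
    atom_name = "CA", residue_name = "ALA", residue_index = 1:2,
    chain_id = "A", x = c(0, d), y = 0, z = 0, stringsAsFactors = FALSE))
}

test_that("two-node Hessian matches the analytic super-element", {
  H <- build_hessian(two_node_structure(5), cutoff = 8, k = 1)
  expect_equal(dim(H), c(6, 6))
  ev <- eigen(H, symmetric = TRUE)
  expect_equal(sort(ev$values), c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
  # eigenvector of the stretch mode is proportional to (u, -u), u = x-hat
  v <- ev$vectors[, 1]
  expect_equal(abs(v), c(1, 0, 0, 1, 0, 0) / sqrt(2), tolerance = 1e-12)
  expect_lt(v[1] * v[4], 0)
  # beyond the cutoff: no interaction at all
  expect_equal(build_hessian(two_node_structure(9)), matrix(0, 6, 6))
  expect_error(build_hessian(two_node_structure(1e-9)), "degenerate")
})

test_that("Hessian is symmetric PSD with orthonormal modes on random structures", {
  for (seed in 1:100) {
    s <- random_structure(6, seed = seed, box = 8)
    H <- build_hessian(s)
    expect_equal(H, t(H))
    expect_gte(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  m <- suppressWarnings(compute_modes(random_structure(6, seed = 1, box = 8)))
  G <- crossprod(m$vectors)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-8)
})

test_that("eigenvalues are invariant under rigid translation", {
  s <- random_structure(7, seed = 11, box = 7)
  s2 <- s
  s2$atoms$x <- s2$atoms$x + 13.7
  s2$atoms$y <- s2$atoms$y - 4.2
  s2$atoms$z <- s2$atoms$z + 0.9
  m1 <- suppressWarnings(compute_modes(s))
  m2 <- suppressWarnings(compute_modes(s2))
  expect_equal(m1$values, m2$values, tolerance = 1e-8)
})

test_that("connected non-collinear structures have exactly six zero modes", {
  expect_equal(compute_modes(helix_structure(10))$n_zero, 6)
  db <- make_dumbbell(40, 20, 4, seed = 2)
  expect_equal(compute_modes(db$structure)$n_zero, 6)
  # 2-node dimer: 5 zero modes and one nonzero eigenvalue 2k
  m <- suppressWarnings(compute_modes(two_node_structure(5), k = 1.5))
  expect_equal(m$n_zero, 5)
  expect_equal(m$values[6], 2 * 1.5, tolerance = 1e-10)
})

test_that("eigenvalues match a brute-force numerical Hessian of the Hookean energy", {
  for (seed in c(3, 9)) {
    s <- random_structure(8, seed = seed, box = 9)
    xyz <- coords(s)
    f <- hookean_energy_fn(xyz)
    Hnum <- numerical_hessian(f, as.vector(t(xyz)))
    ev_num <- sort(eigen(Hnum, symmetric = TRUE, only.values = TRUE)$values)
    ev_ana <- sort(eigen(build_hessian(s), symmetric = TRUE,
                         only.values = TRUE)$values)
    expect_equal(ev_ana, ev_num, tolerance = 1e-6)
  }
})

test_that("eigenvalue spectrum agrees with the bio3d ANM implementation", {
  s <- random_structure(8, seed = 9, box = 9)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)  # identical rounded coordinates for both codes
  nm <- suppressWarnings(bio3d::nma(bio3d::read.pdb(f), ff = "anm",
                                    cutoff = 8, mass = FALSE, temp = NULL))
  m <- suppressWarnings(compute_modes(s2))
  expect_equal(m$values, sort(nm$L), tolerance = 1e-5)
})

test_that("recorded links bridge components and remove zero modes", {
  a <- cluster_fragment("A", 0, seed = 1)
  b <- cluster_fragment("B", 20, seed = 2)  # ~12 A gap: beyond cutoff
  j0 <- join_chains(a, b)
  expect_warning(m0 <- compute_modes(j0), "2 connected components")
  expect_equal(m0$n_components, 2)
  expect_equal(m0$n_zero, 12)
  # one link spring joins the graph and constrains the inter-fragment
  # stretch; the remaining relative rigid motions stay free
  j1 <- join_chains(a, b, list(c("A", 8, "B", 1)))
  m1 <- suppressWarnings(compute_modes(j1))
  expect_equal(m1$n_components, 1)
  expect_lt(m1$n_zero, m0$n_zero)
  expect_equal(m1$n_zero, 11)
})

test_that("deformation energy is half the eigenvalue and non-decreasing", {
  db <- make_dumbbell(40, 20, 4, seed = 5)
  m <- compute_modes(db$structure)
  expect_equal(deformation_energy(m, 3), 0)          # rigid-body mode
  expect_equal(deformation_energy(m, 8), m$values[8] / 2)
  e <- vapply(seq_along(m$values), deformation_energy, numeric(1), m = m)
  expect_true(all(diff(e) >= -1e-12))
  expect_gte(deformation_energy(m, 8) / deformation_energy(m, 7), 1)
  expect_error(deformation_energy(m, 0), "out of range")
  expect_error(deformation_energy(m, length(m$values) + 1), "out of range")
})

test_that("hinge detection localises the linker of the dumbbell fixture", {
  hits <- 0
  for (seed in 1:20) {
    db <- make_dumbbell(40, 20, 12, seed = seed)
    m <- compute_modes(db$structure)
    h <- find_hinge_mode(m, db$structure)
    linker <- which(db$labels == "linker")
    ok <- h$has_hinge &&
      h$anticorrelation <= -0.5 &&
      all(h$hinge_residues >= min(linker) - 2 &
          h$hinge_residues <= max(linker) + 2)
    hits <- hits + ok
  }
  expect_equal(hits, 20)
})

test_that("hinge reports are well-formed and degenerate cases give no hinge", {
  db <- make_dumbbell(40, 20, 12, seed = 1)
  m <- compute_modes(db$structure)
  h <- find_hinge_mode(m, db$structure)
  expect_true(h$has_hinge)
  expect_length(h$domain_labels, nrow(m$nodes))
  expect_setequal(unique(h$domain_labels), c("domain1", "domain2", "hinge"))
  # hinge residues form one contiguous sequence segment
  expect_true(all(diff(h$hinge_residues) == 1))
  # a short rigid helix is a single block: no hinge, not an error
  s <- helix_structure(12)
  ms <- compute_modes(s)
  expect_false(detect_hinge(ms, s)$has_hinge)
  expect_false(find_hinge_mode(ms, s)$has_hinge)
  # rigid-body modes are rejected
  expect_error(detect_hinge(m, db$structure, mode_index = 3), "rigid-body")
  expect_error(detect_hinge(m, db$structure, mode_index = 1e6),
               "out of range")
})

test_that("mode TSV export carries one row per node and mode", {
  db <- make_dumbbell(40, 20, 4, seed = 1)
  m <- compute_modes(db$structure)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_modes_tsv(m, f, modes = 7:9)
  d <- read.delim(f)
  expect_equal(nrow(d), 3 * nrow(m$nodes))
  expect_equal(sort(unique(d$mode)), 7:9)
})
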