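# Shared fixture builders. Everything is generated in code; no data files.

# ideal alpha-helix of Calpha atoms (radius 2.3 A, rise 1.5 A, 100 deg/res)
helix_structure <- function(n = 10, chain = "A", first_residue = 1) {
  t <- seq_len(n)
  molecular_structure(data.frame(
    atom_name = "CA", residue_name = "ALA",
    residue_index = first_residue + t - 1, chain_id = chain,
    x = 2.3 * cos(t * 100 * pi / 180),
    y = 2.3 * sin(t * 100 * pi / 180),
    z = 1.5 * t, stringsAsFactors = FALSE))
}

# n random Calpha nodes in a box, guaranteed pairwise separation
random_structure <- function(n, seed, box = 10, min_sep = 1) {
  set.seed(seed)
  xyz <- matrix(numeric(0), 0, 3)
  while (nrow(xyz) < n) {
    p <- runif(3, 0, box)
    if (nrow(xyz) == 0 || min(sqrt(rowSums(sweep(xyz, 2, p)^2))) > min_sep)
      xyz <- rbind(xyz, p)
  }
  molecular_structure(data.frame(
    atom_name = "CA", residue_name = "ALA", residue_index = seq_len(n),
    chain_id = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# compact 8-node cluster fragment for join tests
cluster_fragment <- function(chain, x_offset = 0, seed = 1) {
  set.seed(seed)
  xyz <- as.matrix(expand.grid(1:2, 1:2, 1:2)) * 4 +
    matrix(runif(24, -0.3, 0.3), 8, 3)
  xyz[, 1] <- xyz[, 1] + x_offset
  molecular_structure(data.frame(
    atom_name = "CA", residue_name = "ALA", residue_index = 1:8,
    chain_id = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# static trajectory: same coordinates in every frame
static_frames <- function(s, n_frames = 3, dt_ps = 1) {
  arr <- array(rep(coords(s), n_frames),
               dim = c(n_atoms(s), 3, n_frames))
  trajectory_frames(s, arr, dt_ps = dt_ps)
}

# explicit Hookean network energy for the brute-force Hessian oracle
hookean_energy_fn <- function(xyz0, cutoff = 8, k = 1) {
  n <- nrow(xyz0)
  d0 <- as.matrix(stats::dist(xyz0))
  pairs <- which(d0 <= cutoff & upper.tri(d0), arr.ind = TRUE)
  function(v) {
    X <- matrix(v, n, 3, byrow = TRUE)  # interleaved x1,y1,z1,x2,...
    s <- 0
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      dd <- sqrt(sum((X[i, ] - X[j, ])^2))
      s <- s + 0.5 * k * (dd - d0[i, j])^2
    }
    s
  }
}

# central-difference numerical Hessian (interleaved coordinate ordering)
numerical_hessian <- function(f, v0, h = 1e-5) {
  m <- length(v0)
  H <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    vpp <- v0; vpp[i] <- vpp[i] + h; vpp[j] <- vpp[j] + h
    vpm <- v0; vpm[i] <- vpm[i] + h; vpm[j] <- vpm[j] - h
    vmp <- v0; vmp[i] <- vmp[i] - h; vmp[j] <- vmp[j] + h
    vmm <- v0; vmm[i] <- vmm[i] - h; vmm[j] <- vmm[j] - h
    H[i, j] <- H[j, i] <- (f(vpp) - f(vpm) - f(vmp) + f(vmm)) / (4 * h^2)
  }
  H
}

two_atom_pdb_text <- paste(
  "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2       4.500  -1.250   0.750  1.00  0.00           C",
  "END", sep = "\n")
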