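#' @name synthetic
#' @title Seeded generators with known ground truth
#'
#' @description
#' Stand-ins for the study's MD data with exactly known ground truth: a
#' hinged two-domain "dumbbell" structure for normal-mode/hinge tests, a
#' membrane patch with a controllable density contrast and thinning channel
#' for the profilers, and an overdamped-Langevin puller that produces
#' stochastic work traces from a prescribed 1-D free-energy profile for the
#' Jarzynski estimators. Every generator is a pure function of its seed.
NULL

# Evaluate code with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Prescribed 1-D free-energy profile
#'
#' Analytic profile mirroring the qualitative shape of a monomer-monomer
#' association free energy: a gentle downhill ramp, a Gaussian barrier
#' raised by the lipid pack between the monomers, and a deep Gaussian
#' contact well where the dimer forms. The coordinate is approach progress
#' in nm (guide position of a forward pull). Heights are in kBT; the
#' desk-scale default barrier is 4 kBT (the study-scale 400/800 kBT
#' barriers are used only in closed-form arithmetic -- sampling them is
#' impossible by design, which is the scientific point).
#'
#' @param range_nm coordinate interval (default 0..4 nm).
#' @param slope_kBT_nm downhill ramp slope (default 0.5 kBT/nm).
#' @param barrier_kBT Gaussian bump height (default 4).
#' @param bump_center_nm,bump_width_nm bump position / s.d. (2.5, 0.3 nm;
#'   the width is kept well above the guide spring's thermal spread
#'   `sqrt(kBT/k)` so the stiff-spring profile is not smeared away).
#' @param well_depth_kBT,well_center_nm,well_width_nm contact well
#'   (default 8 kBT deep at 3.5 nm, s.d. 0.25 nm).
#' @return a `PMFSpec`: functions `f(x)` and `df(x)` (kBT, kBT/nm), the
#'   range, and the parameter list.
#' @export
pmf_spec <- function(range_nm = c(0, 4), slope_kBT_nm = 0.5,
                     barrier_kBT = 4, bump_center_nm = 2.5,
                     bump_width_nm = 0.3, well_depth_kBT = 8,
                     well_center_nm = 3.5, well_width_nm = 0.25) {
  stopifnot(length(range_nm) == 2, range_nm[2] > range_nm[1])
  pars <- list(slope = slope_kBT_nm, h = barrier_kBT, xb = bump_center_nm,
               wb = bump_width_nm, d = well_depth_kBT, xw = well_center_nm,
               ww = well_width_nm)
  f <- function(x) {
    -pars$slope * (x - range_nm[1]) +
      pars$h * exp(-(x - pars$xb)^2 / (2 * pars$wb^2)) -
      pars$d * exp(-(x - pars$xw)^2 / (2 * pars$ww^2))
  }
  df <- function(x) {
    -pars$slope -
      pars$h * (x - pars$xb) / pars$wb^2 *
        exp(-(x - pars$xb)^2 / (2 * pars$wb^2)) +
      pars$d * (x - pars$xw) / pars$ww^2 *
        exp(-(x - pars$xw)^2 / (2 * pars$ww^2))
  }
  structure(list(f = f, df = df, range_nm = range_nm, params = pars),
            class = "PMFSpec")
}

#' Evaluate a PMFSpec on a grid (profile referenced to zero at the start)
#'
#' @param spec a [pmf_spec()].
#' @param n number of grid points.
#' @return a `FreeEnergyProfile` data.frame -- the generator's ground
#'   truth, usable directly with [barrier_height()].
#' @export
pmf_true_profile <- function(spec, n = 2001) {
  x <- seq(spec$range_nm[1], spec$range_nm[2], length.out = n)
  free_energy_profile(x, spec$f(x), "ground_truth", NA_integer_, 310)
}

# compact, well-connected cluster of n nodes on a jittered 5 A grid with a
# 3 x 3 cross-section, elongated along x and ordered by increasing x so
# sequence distance tracks distance along the inter-domain axis
cluster_nodes <- function(n, jitter_A = 0.5) {
  cs <- 3
  nx <- ceiling(n / cs^2)
  g <- as.matrix(expand.grid(y = seq_len(cs), z = seq_len(cs),
                             x = seq_len(nx)))[seq_len(n), c("x", "y", "z")]
  xyz <- g * 5 + matrix(stats::runif(3 * n, -jitter_A, jitter_A), n, 3)
  xyz[order(xyz[, 1]), , drop = FALSE]
}

#' Hinged two-domain dumbbell structure
#'
#' Two compact Calpha clusters (jittered 5-Angstrom grids: many
#' intra-cluster contacts under the 8 Angstrom cutoff) joined by a thin
#' helical linker bridge whose nodes only contact near sequence
#' neighbours. The anti-phase rocking / twisting of the two clusters
#' about the low-mobility bridge appears among the first few internal
#' modes, which is the geometry the hinge detector is built for (use
#' [find_hinge_mode()] to pick the cleanest anti-phase mode).
#'
#' @param n1,n2 residues in the two clusters (>= 10 each).
#' @param linker linker residues (2..16; a 12-residue bridge gives the
#'   cleanest hinge localisation).
#' @param seed RNG seed; the structure is a pure function of it.
#' @return list with `structure` (a `MolecularStructure` of Calpha atoms,
#'   chain A, consecutive residues) and `labels` (per-residue
#'   `cluster1` / `linker` / `cluster2`).
#' @export
make_dumbbell <- function(n1 = 40, n2 = 20, linker = 4, seed = 1) {
  stopifnot(n1 >= 10, n2 >= 10, linker >= 2)
  if (linker > 16)
    stop("linker longer than 16 residues makes the thin bridge itself ",
         "floppy; use 2..16")
  with_seed(seed, {
    c1 <- cluster_nodes(n1)
    # anchor: the +x face atom nearest the cluster's y/z centre, so the
    # linker attaches at the middle of the face for every seed
    face_sel <- c1[, 1] >= max(c1[, 1]) - 2.5
    cen <- colMeans(c1)
    fa <- c1[face_sel, , drop = FALSE]
    a1 <- fa[which.min((fa[, 2] - cen[2])^2 + (fa[, 3] - cen[3])^2), ]
    # thin helical linker around the anchor axis: rise 2.0 A, radius
    # 2.0 A, 135 deg/residue; contacts reach i+-3 under the 8 A cutoff,
    # which keeps the bridge collectively rigid (6 zero modes) while
    # staying far sparser than the clusters, so low-frequency modes
    # bend/twist about it
    rise <- 2.0; rad <- 2.0; dphi <- 135 * pi / 180
    j <- seq_len(linker)
    lk <- cbind(a1[1] + j * rise,
                a1[2] + rad * cos(j * dphi),
                a1[3] + rad * sin(j * dphi))
    c2 <- cluster_nodes(n2)
    # place cluster 2 so its -x face-centre atom sits one rise beyond
    # the linker, on the linker axis
    a2_target <- c(a1[1] + (linker + 1) * rise, a1[2], a1[3])
    face_sel2 <- c2[, 1] <= min(c2[, 1]) + 2.5
    cen2 <- colMeans(c2)
    fb <- c2[face_sel2, , drop = FALSE]
    face <- fb[which.min((fb[, 2] - cen2[2])^2 + (fb[, 3] - cen2[3])^2), ]
    c2 <- sweep(c2, 2, face - a2_target)
    xyz <- rbind(c1, lk, c2)
    n <- nrow(xyz)
    atoms <- data.frame(atom_name = "CA", residue_name = "ALA",
                        residue_index = seq_len(n), chain_id = "A",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    s <- molecular_structure(atoms)
    comp <- network_components(xyz, cutoff = 8)
    if (max(comp) > 1)
      stop("generated network is disconnected (", max(comp),
           " components); adjust cluster sizes or linker length")
    labels <- c(rep("cluster1", n1), rep("linker", linker),
                rep("cluster2", n2))
    list(structure = s, labels = labels)
  })
}

# rejection-sample n points in the patch respecting contrast region,
# thinning channel and exclusion cylinders; all lengths nm
sample_patch_points <- function(n, box, contrast_x, factor, channel,
                                excl_centers, excl_radius) {
  lam_rel_max <- 1 + max(factor, 0)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    m <- max(2 * (n - nrow(pts)), 100)
    cand <- cbind(stats::runif(m, 0, box[1]),
                  stats::runif(m, -box[2] / 2, box[2] / 2),
                  stats::runif(m, -box[3] / 2, box[3] / 2))
    rel <- rep(1, m)
    if (!is.null(contrast_x))
      rel[cand[, 1] >= contrast_x[1] & cand[, 1] <= contrast_x[2]] <-
        1 + factor
    keep <- stats::runif(m) <= rel / lam_rel_max
    if (!is.null(channel)) {
      in_ch <- cand[, 1] >= channel$x_range_nm[1] &
        cand[, 1] <= channel$x_range_nm[2]
      keep <- keep & !(in_ch & abs(cand[, 3]) > channel$thickness_nm / 2)
    }
    if (!is.null(excl_centers)) {
      for (k in seq_len(nrow(excl_centers))) {
        d2 <- (cand[, 1] - excl_centers[k, 1])^2 +
          (cand[, 2] - excl_centers[k, 2])^2
        keep <- keep & d2 > excl_radius^2
      }
    }
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Membrane patch with known density contrast and optional thinning
#'
#' Point-atom lipid slab: tail atoms (name `C`, chain `L`) Poisson-like
#' sampled at a baseline number density, multiplied by `(1 + factor)`
#' inside a contrast x-interval (emulating the ~20% denser lipid packing
#' between two approaching monomers); head atoms (name `P`, chains
#' `U`/`D`) decorate the two leaflet surfaces, following an optional
#' thinned channel; two helical Calpha monomers (chains `A`, `B`) may be
#' embedded, each carrying a small lipid exclusion cylinder. Every
#' snapshot redraws the lipid microstate; the returned ground truth is the
#' generating density field.
#'
#' @param box_nm patch dimensions `c(Lx, Ly, thickness)` in nm (default
#'   `c(10, 5, 4)`, mirroring the 100 x 50 Angstrom alpha-monomer patch).
#' @param baseline_density_per_nm3 tail-atom number density (default 100,
#'   the peak packing scale).
#' @param contrast_x_range_nm x-interval with raised density, or `NULL`.
#' @param contrast_factor relative density excess in the region (default
#'   0.2, the ~20% packing contrast).
#' @param monomer_x_nm x-positions of embedded monomers (default
#'   `c(2.5, 7.5)`, i.e. 5 nm apart), or `NULL` for a bare patch.
#' @param channel optional thinning: `list(x_range_nm =, thickness_nm =)`.
#' @param n_snapshots snapshots (default 9, the alpha-domain protocol).
#' @param dt_ps snapshot spacing (default 100 ps).
#' @param head_density_per_nm2 leaflet head-atom area density (default 1.5).
#' @param seed RNG seed.
#' @return list with `frames` (a `TrajectoryFrames`), index vectors
#'   `tails`, `heads_upper`, `heads_lower`, `monomers`, and `truth`
#'   (generating densities and geometry).
#' @export
make_membrane_patch <- function(box_nm = c(10, 5, 4),
                                baseline_density_per_nm3 = 100,
                                contrast_x_range_nm = NULL,
                                contrast_factor = 0.2,
                                monomer_x_nm = c(2.5, 7.5),
                                channel = NULL,
                                n_snapshots = 9, dt_ps = 100,
                                head_density_per_nm2 = 1.5, seed = 1) {
  stopifnot(length(box_nm) == 3, all(box_nm > 0),
            baseline_density_per_nm3 > 0, n_snapshots >= 1)
  excl_radius <- 0.5
  excl <- NULL
  if (!is.null(monomer_x_nm)) {
    excl <- cbind(monomer_x_nm, 0)
    if (length(monomer_x_nm) > 1 &&
        min(dist(cbind(monomer_x_nm, 0))) < 2 * excl_radius)
      stop("overlapping exclusion volumes: monomers closer than ",
           2 * excl_radius, " nm")
  }
  with_seed(seed, {
    thick_at <- function(x) {
      h <- rep(box_nm[3], length(x))
      if (!is.null(channel))
        h[x >= channel$x_range_nm[1] & x <= channel$x_range_nm[2]] <-
          channel$thickness_nm
      h
    }
    # tail count = integral of the generating intensity over the patch,
    # so the realised number density matches the requested field even
    # with a thinned channel, contrast region or exclusion cylinders
    rel_at <- function(x) {
      r <- rep(1, length(x))
      if (!is.null(contrast_x_range_nm))
        r[x >= contrast_x_range_nm[1] & x <= contrast_x_range_nm[2]] <-
          1 + contrast_factor
      r
    }
    xs <- seq(0, box_nm[1], length.out = 4001)
    eff_vol <- box_nm[2] * mean(rel_at(xs) * thick_at(xs)) * box_nm[1]
    if (!is.null(monomer_x_nm))
      eff_vol <- eff_vol - sum(rel_at(monomer_x_nm) *
                                 thick_at(monomer_x_nm)) *
        pi * excl_radius^2
    n_tails <- round(baseline_density_per_nm3 * eff_vol)
    n_heads <- round(head_density_per_nm2 * box_nm[1] * box_nm[2])
    monomer_atoms <- NULL
    if (!is.null(monomer_x_nm)) {
      res0 <- 0
      for (k in seq_along(monomer_x_nm)) {
        nres <- 20
        t <- seq_len(nres)
        hel <- cbind(monomer_x_nm[k] + 0.23 * cos(t * 100 * pi / 180),
                     0.23 * sin(t * 100 * pi / 180),
                     seq(-box_nm[3] / 2 - 0.3, box_nm[3] / 2 + 0.3,
                         length.out = nres))
        monomer_atoms <- rbind(monomer_atoms, data.frame(
          atom_name = "CA", residue_name = "ALA", residue_index = t,
          chain_id = LETTERS[k], x = nm_to_ang(hel[, 1]),
          y = nm_to_ang(hel[, 2]), z = nm_to_ang(hel[, 3]),
          stringsAsFactors = FALSE))
        res0 <- res0 + nres
      }
    }
    draw_frame <- function() {
      tails <- sample_patch_points(n_tails, box_nm, contrast_x_range_nm,
                                   contrast_factor, channel, excl,
                                   excl_radius)
      hx <- stats::runif(n_heads, 0, box_nm[1])
      hy <- stats::runif(n_heads, -box_nm[2] / 2, box_nm[2] / 2)
      up <- cbind(hx, hy, thick_at(hx) / 2 + stats::rnorm(n_heads, 0, 0.05))
      hx2 <- stats::runif(n_heads, 0, box_nm[1])
      hy2 <- stats::runif(n_heads, -box_nm[2] / 2, box_nm[2] / 2)
      low <- cbind(hx2, hy2, -thick_at(hx2) / 2 +
                     stats::rnorm(n_heads, 0, 0.05))
      nm_to_ang(rbind(tails, up, low))
    }
    first <- draw_frame()
    n_mon <- if (is.null(monomer_atoms)) 0 else nrow(monomer_atoms)
    lipid_atoms <- data.frame(
      atom_name = rep(c("C", "P", "P"), c(n_tails, n_heads, n_heads)),
      residue_name = "POPC",
      residue_index = c(seq_len(n_tails), seq_len(n_heads),
                        seq_len(n_heads)),
      chain_id = rep(c("L", "U", "D"), c(n_tails, n_heads, n_heads)),
      x = first[, 1], y = first[, 2], z = first[, 3],
      stringsAsFactors = FALSE)
    atoms <- rbind(monomer_atoms, lipid_atoms)
    s <- molecular_structure(atoms)
    arr <- array(NA_real_, dim = c(nrow(atoms), 3, n_snapshots))
    mon_xyz <- if (n_mon > 0) as.matrix(monomer_atoms[, c("x", "y", "z")])
               else matrix(numeric(0), 0, 3)
    arr[, , 1] <- rbind(mon_xyz, first)
    if (n_snapshots > 1) for (m in 2:n_snapshots)
      arr[, , m] <- rbind(mon_xyz, draw_frame())
    frames <- trajectory_frames(s, arr, dt_ps = dt_ps)
    list(frames = frames,
         tails = n_mon + seq_len(n_tails),
         heads_upper = n_mon + n_tails + seq_len(n_heads),
         heads_lower = n_mon + n_tails + n_heads + seq_len(n_heads),
         monomers = seq_len(n_mon),
         truth = list(baseline_density_per_nm3 = baseline_density_per_nm3,
                      contrast_factor = contrast_factor,
                      contrast_x_range_nm = contrast_x_range_nm,
                      thickness_nm = box_nm[3], channel = channel,
                      box_nm = box_nm, exclusion_radius_nm = excl_radius,
                      monomer_x_nm = monomer_x_nm))
  })
}

#' Stochastic pulling traces from a prescribed free-energy profile
#'
#' Overdamped Langevin (Euler-Maruyama) motion of a particle on a
#' [pmf_spec()] landscape, pulled by a harmonic guide spring whose anchor
#' moves at constant speed -- the steered-MD setup with a constant-velocity
#' dummy point. Each repeat starts from the guide-spring Boltzmann
#' distribution at the start position and uses the shared seeded RNG
#' stream, so the full trace set is a pure function of the seed. Profile
#' heights in kBT are converted to pN nm on a fixed 310 K basis; the
#' simulation temperature only scales the thermal noise (so a
#' zero-temperature run is the deterministic drag limit).
#'
#' @param pmf a [pmf_spec()].
#' @param M number of repeats (default 10, the steering protocol).
#' @param speed_nm_ns guide speed (default 2.5 nm/ns, the study's choice).
#' @param spring_pN_nm guide spring constant (default 1000 pN/nm, stiff:
#'   thermal spread `sqrt(kBT/k)` ~ 0.065 nm at 310 K).
#' @param friction_pN_ns_nm friction coefficient gamma (default 10).
#' @param temperature_K thermal noise temperature (default 310 K; 0 allowed).
#' @param dt_ns integration step (default 0.002 ns); must satisfy
#'   `dt <= 0.5 * gamma / k_spring` or an error reports the bound.
#' @param record_every record every n-th step (default auto, ~2000 rows).
#' @param seed RNG seed.
#' @return list of `M` [force_trace()] objects (time ps, guide nm, spring
#'   force pN).
#' @export
simulate_pull <- function(pmf, M = 10, speed_nm_ns = 2.5,
                          spring_pN_nm = 1000, friction_pN_ns_nm = 10,
                          temperature_K = 310, dt_ns = 0.002,
                          record_every = NULL, seed = 1) {
  stopifnot(inherits(pmf, "PMFSpec"), M >= 1, speed_nm_ns > 0,
            spring_pN_nm > 0, friction_pN_ns_nm > 0, temperature_K >= 0)
  bound <- 0.5 * friction_pN_ns_nm / spring_pN_nm
  if (dt_ns > bound)
    stop("time step ", dt_ns, " ns exceeds the overdamped stability bound ",
         signif(bound, 3), " ns (0.5 * friction / spring)")
  kbt_unit <- kbt_pN_nm(310)  # fixed energy basis of the kBT profile
  noise_sd <- sqrt(2 * kB_pN_nm * temperature_K * dt_ns / friction_pN_ns_nm)
  x0 <- pmf$range_nm[1]; x1 <- pmf$range_nm[2]
  n_steps <- ceiling((x1 - x0) / (speed_nm_ns * dt_ns))
  if (is.null(record_every))
    record_every <- max(1L, floor(n_steps / 2000))
  with_seed(seed, {
    init_sd <- if (temperature_K > 0)
      sqrt(kB_pN_nm * temperature_K / spring_pN_nm) else 0
    x <- x0 + stats::rnorm(M, 0, init_sd)
    rec_idx <- unique(c(seq(0, n_steps, by = record_every), n_steps))
    times <- numeric(length(rec_idx))
    guides <- numeric(length(rec_idx))
    forces <- matrix(NA_real_, length(rec_idx), M)
    r <- 1
    for (n in 0:n_steps) {
      z <- x0 + speed_nm_ns * n * dt_ns
      f_spring <- spring_pN_nm * (z - x)
      if (n == rec_idx[r]) {
        times[r] <- n * dt_ns; guides[r] <- z; forces[r, ] <- f_spring
        r <- r + 1
      }
      if (n == n_steps) break
      f_pmf <- -pmf$df(x) * kbt_unit
      x <- x + dt_ns * (f_pmf + f_spring) / friction_pN_ns_nm +
        noise_sd * stats::rnorm(M)
    }
    lapply(seq_len(M), function(i)
      force_trace(times * 1000, guides, forces[, i]))
  })
}

#' Gaussian endpoint-work fixture
#'
#' M work curves rising linearly from zero to i.i.d. Gaussian endpoint
#' values on a short grid -- the closed-form oracle for the Jarzynski
#' estimators, whose Gaussian limit is `mu - beta sigma^2 / 2` (in kBT:
#' `mu - sigma^2 / 2`).
#'
#' @param mu_kBT mean endpoint work.
#' @param sigma2_kBT2 endpoint work variance (>= 0).
#' @param M number of repeats.
#' @param grid_nm coordinate grid (default `c(0, 1)`).
#' @param temperature_K temperature recorded on the set.
#' @param seed RNG seed.
#' @return a [work_trace_set()].
#' @export
gaussian_work_set <- function(mu_kBT = 10, sigma2_kBT2 = 4, M = 10,
                              grid_nm = c(0, 1), temperature_K = 310,
                              seed = 1) {
  stopifnot(sigma2_kBT2 >= 0, M >= 1, length(grid_nm) >= 2)
  with_seed(seed, {
    endpoints <- stats::rnorm(M, mu_kBT, sqrt(sigma2_kBT2))
    frac <- (grid_nm - grid_nm[1]) / (max(grid_nm) - grid_nm[1])
    works <- outer(frac, endpoints)
    work_trace_set(grid_nm, works, temperature_K = temperature_K)
  })
}
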