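#' @name traj_analysis
#' @title Geometry and energy post-processing of trajectory snapshots
#'
#' @description
#' Centre-of-mass separations, force-trace smoothing, work integration,
#' lipid density and membrane-thickness profiles along the inter-monomer
#' axis, lipid-shell tracking and truncated non-bonded group-group
#' energies. Structures store Angstrom; every result here is reported in
#' nm (and pN, kJ/mol) via the single unit converter.
NULL

frame_xyz <- function(frames, m) frames$coords[, , m, drop = TRUE]

atom_masses <- function(frames, masses = NULL) {
  if (!is.null(masses)) return(rep_len(masses, n_atoms(frames$struct)))
  if (!is.null(frames$struct$atoms$mass)) return(frames$struct$atoms$mass)
  rep(1, n_atoms(frames$struct))
}

com_of <- function(xyz, sel, w) {
  ws <- w[sel]
  colSums(xyz[sel, , drop = FALSE] * ws) / sum(ws)
}

#' Centre-of-mass distance between two selections over a trajectory
#'
#' Mass-weighted centres of mass per frame; unit masses are assumed when the
#' structure carries none.
#'
#' @param frames a `TrajectoryFrames`.
#' @param selA,selB atom index vectors (from [select_atoms()]).
#' @param masses optional per-atom masses (Da) overriding the structure's.
#' @return data.frame with `time_ps` and `distance_nm`.
#' @export
com_distance <- function(frames, selA, selB, masses = NULL) {
  stopifnot(inherits(frames, "TrajectoryFrames"))
  if (length(selA) == 0 || length(selB) == 0)
    stop("empty selection")
  w <- atom_masses(frames, masses)
  d <- vapply(seq_len(n_frames(frames)), function(m) {
    xyz <- frame_xyz(frames, m)
    sqrt(sum((com_of(xyz, selA, w) - com_of(xyz, selB, w))^2))
  }, numeric(1))
  data.frame(time_ps = frames$times_ps, distance_nm = ang_to_nm(d))
}

#' Boxcar window average of a series along a reaction coordinate
#'
#' For each input point, the mean of all samples whose coordinate lies
#' within `window/2` of it; at the edges the window is simply truncated.
#' This is the smoothing applied to raw pulling-force traces before
#' reading off force plateaus.
#'
#' @param x coordinate values (e.g. separation in nm), or a 2-column
#'   data.frame holding coordinate and value.
#' @param y values; omit when `x` is a data.frame.
#' @param window full window width in coordinate units (default 0.5 nm).
#' @return data.frame with the input coordinate and the smoothed value.
#' @export
window_average <- function(x, y = NULL, window = 0.5) {
  if (is.data.frame(x)) { y <- x[[2]]; x <- x[[1]] }
  if (length(x) == 0) stop("empty series")
  stopifnot(window > 0, length(x) == length(y))
  half <- window / 2
  sm <- vapply(x, function(x0) mean(y[abs(x - x0) <= half]), numeric(1))
  data.frame(x = x, smoothed = sm)
}

#' Force trace container
#'
#' @param time_ps times in ps, strictly increasing.
#' @param guide_nm position of the constant-velocity guide (dummy) point
#'   along the pulling direction, nm.
#' @param force_pN spring force on the steered selection, pN.
#' @return an object of class `ForceTrace` (a data.frame).
#' @export
force_trace <- function(time_ps, guide_nm, force_pN) {
  stopifnot(length(time_ps) == length(guide_nm),
            length(time_ps) == length(force_pN))
  if (length(time_ps) > 1 && any(diff(time_ps) <= 0))
    stop("time must be strictly increasing")
  if (!all(is.finite(c(time_ps, guide_nm, force_pN))))
    stop("non-finite values in force trace")
  structure(data.frame(time_ps = time_ps, guide_nm = guide_nm,
                       force_pN = force_pN),
            class = c("ForceTrace", "data.frame"))
}

#' Read / write a force trace (CSV or TSV with header time_ps,guide_nm,force_pN)
#'
#' @param file path; delimiter inferred from the header line.
#' @return a [force_trace()].
#' @export
read_force_trace <- function(file) {
  if (!file.exists(file)) stop("input file not found: ", file)
  hdr <- readLines(file, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep)
  need <- c("time_ps", "guide_nm", "force_pN")
  if (!all(need %in% names(d)))
    stop("force trace must have columns ", paste(need, collapse = ","))
  force_trace(d$time_ps, d$guide_nm, d$force_pN)
}

#' @rdname read_force_trace
#' @param trace a `ForceTrace`.
#' @param sep field separator (default tab).
#' @export
write_force_trace <- function(trace, file, sep = "\t") {
  utils::write.table(as.data.frame(trace), file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Integrate external work along the guide coordinate
#'
#' Trapezoidal integral of the spring force over the guide (dummy-point)
#' position -- the stiff-spring convention, where work is accumulated along
#' the coordinate of the constant-velocity guide rather than the
#' instantaneous molecular coordinate. The trace must be a forward pull
#' (monotone guide position).
#'
#' @param trace a [force_trace()] with at least 2 samples.
#' @param temperature_K temperature used for the kBT column (default 310).
#' @return data.frame with `guide_nm`, `work_pN_nm` and `work_kBT`,
#'   starting at zero work.
#' @export
integrate_work <- function(trace, temperature_K = 310) {
  if (nrow(trace) < 2) stop("need at least 2 samples to integrate work")
  dz <- diff(trace$guide_nm)
  if (!(all(dz > 0) || all(dz < 0)))
    stop("guide position must be monotone (forward pull)")
  w <- as.vector(pracma::cumtrapz(trace$guide_nm, trace$force_pN))
  data.frame(guide_nm = trace$guide_nm, work_pN_nm = w,
             work_kBT = w / kbt_pN_nm(temperature_K))
}

# Project frame coordinates (Angstrom) onto an axis given in nm.
# Returns s (along-axis, nm from point a), tr (in-plane transverse, nm), z (nm).
axis_coordinates <- function(xyz_ang, axis_a_nm, axis_b_nm) {
  ab <- axis_b_nm - axis_a_nm
  len <- sqrt(sum(ab^2))
  if (len == 0) stop("axis endpoints must be distinct")
  u <- ab / len
  # in-plane transverse direction: perpendicular to u within the xy-plane
  tr_dir <- c(-u[2], u[1], 0)
  trn <- sqrt(sum(tr_dir^2))
  if (trn < 1e-12) tr_dir <- c(1, 0, 0) else tr_dir <- tr_dir / trn
  r <- sweep(ang_to_nm(xyz_ang), 2, axis_a_nm)
  list(s = as.vector(r %*% u), tr = as.vector(r %*% tr_dir),
       z = ang_to_nm(xyz_ang[, 3]), length = len)
}

#' Lipid number-density profile along the inter-monomer axis
#'
#' Per snapshot, counts selected atoms whose projection onto the axis falls
#' in each bin and whose transverse / z coordinates fall inside the slab;
#' density is count / (bin_width x 2 half_width x z-interval), averaged
#' over snapshots. This is the profile used to quantify lipid packing
#' between two membrane-embedded monomers (the cytoplasmic leaflet is
#' selected with `z_range_nm`).
#'
#' @param frames a `TrajectoryFrames`.
#' @param lipid_sel atom indices of the lipid atoms to count.
#' @param axis_a_nm,axis_b_nm 3-vectors (nm) defining the profile axis.
#' @param bin_width_nm bin width along the axis (default 0.5 nm).
#' @param half_width_nm transverse half-width of the slab (nm).
#' @param z_range_nm length-2 z interval (nm) selecting the leaflet, e.g.
#'   `c(-2, 0)` for the cytoplasmic half of a 4 nm bilayer centred at z = 0.
#' @return a `DensityProfile`: data.frame with `bin_center_nm`,
#'   `density_per_nm3`; attributes carry the slab definition, per-frame
#'   counts and `n_snapshots`.
#' @export
lipid_density_profile <- function(frames, lipid_sel, axis_a_nm, axis_b_nm,
                                  bin_width_nm = 0.5, half_width_nm = 1,
                                  z_range_nm = c(-2, 0)) {
  stopifnot(inherits(frames, "TrajectoryFrames"))
  if (length(lipid_sel) == 0) stop("empty selection")
  z_len <- diff(range(z_range_nm))
  if (bin_width_nm <= 0 || half_width_nm <= 0 || z_len <= 0)
    stop("zero-volume slab")
  probe <- axis_coordinates(frame_xyz(frames, 1), axis_a_nm, axis_b_nm)
  edges <- seq(0, probe$length + bin_width_nm * 1e-9, by = bin_width_nm)
  if (max(edges) < probe$length) edges <- c(edges, max(edges) + bin_width_nm)
  nb <- length(edges) - 1
  counts <- matrix(0, nb, n_frames(frames))
  for (m in seq_len(n_frames(frames))) {
    ax <- axis_coordinates(frame_xyz(frames, m)[lipid_sel, , drop = FALSE],
                           axis_a_nm, axis_b_nm)
    inside <- abs(ax$tr) <= half_width_nm &
      ax$z >= min(z_range_nm) & ax$z <= max(z_range_nm) &
      ax$s >= 0 & ax$s <= edges[nb + 1]
    if (any(inside)) {
      b <- findInterval(ax$s[inside], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
      tb <- tabulate(b, nbins = nb)
      counts[, m] <- tb
    }
  }
  vol <- bin_width_nm * 2 * half_width_nm * z_len
  out <- data.frame(bin_center_nm = (edges[-1] + edges[-(nb + 1)]) / 2,
                    density_per_nm3 = rowMeans(counts) / vol)
  attr(out, "counts") <- counts
  attr(out, "bin_volume_nm3") <- vol
  attr(out, "n_snapshots") <- n_frames(frames)
  attr(out, "slab") <- list(bin_width_nm = bin_width_nm,
                            half_width_nm = half_width_nm,
                            z_range_nm = z_range_nm)
  class(out) <- c("DensityProfile", "data.frame")
  out
}

#' Track lipid-shell chains relative to a monomer
#'
#' Distance between the monomer's centre of mass and the centre of mass of
#' each tagged lipid chain, per frame: chains that co-travel with the
#' monomer keep a constant distance, chains left behind drift away.
#'
#' @param frames a `TrajectoryFrames`.
#' @param monomer_sel atom indices of the monomer.
#' @param chain_sels named list of atom index vectors, one per lipid chain.
#' @param masses optional per-atom masses.
#' @return data.frame with `time_ps` and one distance column (nm) per chain.
#' @export
track_shell <- function(frames, monomer_sel, chain_sels, masses = NULL) {
  stopifnot(inherits(frames, "TrajectoryFrames"))
  if (length(monomer_sel) == 0 || any(lengths(chain_sels) == 0))
    stop("empty selection")
  w <- atom_masses(frames, masses)
  out <- data.frame(time_ps = frames$times_ps)
  if (is.null(names(chain_sels)))
    names(chain_sels) <- paste0("chain", seq_along(chain_sels))
  for (nm in names(chain_sels)) {
    out[[nm]] <- vapply(seq_len(n_frames(frames)), function(m) {
      xyz <- frame_xyz(frames, m)
      ang_to_nm(sqrt(sum((com_of(xyz, monomer_sel, w) -
                          com_of(xyz, chain_sels[[nm]], w))^2)))
    }, numeric(1))
  }
  out
}

#' Membrane thickness profile along an axis
#'
#' Per bin along the axis, the mean z of the upper-leaflet head atoms minus
#' the mean z of the lower-leaflet head atoms, averaged over frames. Bins
#' where either leaflet has no atoms in a frame contribute a missing value
#' for that frame; a bin empty in every frame is reported as `NA`, never 0.
#'
#' @param frames a `TrajectoryFrames`.
#' @param head_sel_upper,head_sel_lower atom indices of head-group atoms of
#'   the two leaflets.
#' @param axis_a_nm,axis_b_nm 3-vectors (nm) defining the profile axis.
#' @param bin_width_nm bin width (nm).
#' @return data.frame with `bin_center_nm` and `thickness_nm`.
#' @export
membrane_thickness_profile <- function(frames, head_sel_upper,
                                       head_sel_lower, axis_a_nm, axis_b_nm,
                                       bin_width_nm = 0.5) {
  stopifnot(inherits(frames, "TrajectoryFrames"))
  if (length(head_sel_upper) == 0 || length(head_sel_lower) == 0)
    stop("empty selection")
  probe <- axis_coordinates(frame_xyz(frames, 1), axis_a_nm, axis_b_nm)
  edges <- seq(0, probe$length + bin_width_nm * 1e-9, by = bin_width_nm)
  if (max(edges) < probe$length) edges <- c(edges, max(edges) + bin_width_nm)
  nb <- length(edges) - 1
  gaps <- matrix(NA_real_, nb, n_frames(frames))
  for (m in seq_len(n_frames(frames))) {
    xyz <- frame_xyz(frames, m)
    for (leaf in 1:2) {
      sel <- if (leaf == 1) head_sel_upper else head_sel_lower
      ax <- axis_coordinates(xyz[sel, , drop = FALSE], axis_a_nm, axis_b_nm)
      b <- findInterval(ax$s, edges, rightmost.closed = TRUE)
      ok <- b >= 1 & b <= nb
      mz <- vapply(seq_len(nb), function(i) {
        zz <- ax$z[ok & b == i]
        if (length(zz) == 0) NA_real_ else mean(zz)
      }, numeric(1))
      if (leaf == 1) up <- mz else low <- mz
    }
    gaps[, m] <- up - low
  }
  data.frame(bin_center_nm = (edges[-1] + edges[-(nb + 1)]) / 2,
             thickness_nm = rowMeans(gaps, na.rm = TRUE))
}

#' Generic non-bonded parameter table for synthetic atoms
#'
#' Lennard-Jones well depth (kJ/mol), diameter (nm) and partial charge (e)
#' keyed by atom name. These are comparative defaults for point-atom
#' fixtures, not force-field parameters.
#' @return data.frame with columns `atom_name`, `epsilon_kJ_mol`,
#'   `sigma_nm`, `q_e`.
#' @export
default_nonbonded_params <- function() {
  data.frame(atom_name = c("C", "CA", "P", "N", "O"),
             epsilon_kJ_mol = c(0.45, 0.45, 0.60, 0.50, 0.65),
             sigma_nm = c(0.35, 0.38, 0.37, 0.33, 0.30),
             q_e = c(0, 0, -0.5, 0.5, -0.5),
             stringsAsFactors = FALSE)
}

# Coulomb prefactor 1/(4 pi eps0) in kJ mol^-1 nm e^-2
.ke_kJ_mol_nm <- 138.935458

#' Truncated group-group non-bonded interaction energy
#'
#' Pairwise 12-6 Lennard-Jones with Lorentz-Berthelot combining rules and
#' Coulomb with a fixed relative dielectric, both plainly truncated at the
#' cutoff (no switching function), summed over all A-B atom pairs per
#' frame. Used e.g. for the van der Waals interaction between the lipid
#' cylinders that co-travel with two approaching monomers.
#'
#' @param frames a `TrajectoryFrames`.
#' @param selA,selB disjoint atom index vectors.
#' @param params parameter table as in [default_nonbonded_params()]; every
#'   selected atom's name must appear in it.
#' @param cutoff_nm truncation distance (default 1.2 nm).
#' @param dielectric relative dielectric constant for Coulomb (default 1).
#' @return data.frame with `time_ps`, `lj_kJ_mol`, `coulomb_kJ_mol`.
#' @export
group_interaction_energy <- function(frames, selA, selB,
                                     params = default_nonbonded_params(),
                                     cutoff_nm = 1.2, dielectric = 1) {
  stopifnot(inherits(frames, "TrajectoryFrames"))
  if (length(selA) == 0 || length(selB) == 0) stop("empty selection")
  if (length(intersect(selA, selB)) > 0)
    stop("selections overlap: atoms ",
         paste(utils::head(intersect(selA, selB), 3), collapse = ", "))
  nm <- frames$struct$atoms$atom_name
  look <- function(sel) {
    i <- match(nm[sel], params$atom_name)
    if (anyNA(i))
      stop("missing non-bonded parameters for atom name '",
           nm[sel][which(is.na(i))[1]], "'")
    params[i, ]
  }
  pa <- look(selA); pb <- look(selB)
  # Lorentz-Berthelot combining
  sig <- outer(pa$sigma_nm, pb$sigma_nm, function(a, b) (a + b) / 2)
  eps <- outer(pa$epsilon_kJ_mol, pb$epsilon_kJ_mol,
               function(a, b) sqrt(a * b))
  qq <- outer(pa$q_e, pb$q_e)
  out <- data.frame(time_ps = frames$times_ps, lj_kJ_mol = NA_real_,
                    coulomb_kJ_mol = NA_real_)
  for (m in seq_len(n_frames(frames))) {
    xyz <- ang_to_nm(frame_xyz(frames, m))
    ra <- xyz[selA, , drop = FALSE]; rb <- xyz[selB, , drop = FALSE]
    d2 <- outer(rowSums(ra^2), rowSums(rb^2), `+`) - 2 * tcrossprod(ra, rb)
    r <- sqrt(pmax(d2, 0))
    within <- r <= cutoff_nm & r > 0
    sr6 <- (sig[within] / r[within])^6
    out$lj_kJ_mol[m] <- sum(4 * eps[within] * (sr6^2 - sr6))
    out$coulomb_kJ_mol[m] <-
      sum(.ke_kJ_mol_nm * qq[within] / (dielectric * r[within]))
  }
  out
}
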