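#' @name mechanics
#' @title Diffusion-derived steering speeds and force-feasibility arithmetic
#'
#' @description
#' Closed forms used to pick a physically sensible steering speed and to
#' judge whether cytoskeletal forces can supply an association barrier.
#' A membrane protein performing a 2-D random walk with diffusion
#' coefficient D has position variance `sigma^2 = 4 D t` (the 2-D
#' Green's-function relation), so over a simulation time scale t it stays
#' within `3 sigma` of its origin with 99.7% certainty, giving a
#' characteristic drift speed `3 sigma / t`. Resolving the walk at the
#' integration time step dt instead gives the much larger instantaneous
#' step speed `V = sqrt(4 D / dt)` (central-limit-theorem relation); a
#' steering speed well below V avoids imposing an unphysical impulse.
NULL

#' Diffusion parameter bundle
#'
#' @param D_nm2_per_us diffusion coefficient, nm^2/us (0.25 for a
#'   cortically hindered integrin dimer).
#' @param t_ns diffusing time / simulation time scale, ns.
#' @param dt_fs integration time step, fs.
#' @return a `DiffusionParams` list; all fields must be strictly positive
#'   (`D` may be zero only in the documented limiting sense).
#' @export
diffusion_params <- function(D_nm2_per_us = 0.25, t_ns = 2, dt_fs = 2) {
  stopifnot(D_nm2_per_us >= 0, t_ns > 0, dt_fs > 0)
  structure(list(D_nm2_per_us = D_nm2_per_us, t_ns = t_ns, dt_fs = dt_fs),
            class = "DiffusionParams")
}

# D in nm^2/ns
.D_per_ns <- function(p) p$D_nm2_per_us * 1e-3

#' Standard deviation of 2-D diffusive displacement
#'
#' `sigma = sqrt(4 D t)`. With D = 0.25 nm^2/us and t = 2 ns this is
#' 0.0447 nm (and 3 sigma = 0.1342 nm).
#'
#' @param p a [diffusion_params()].
#' @return sigma in nm.
#' @export
position_std <- function(p) {
  stopifnot(inherits(p, "DiffusionParams"))
  sqrt(4 * .D_per_ns(p) * p$t_ns)
}

#' Characteristic diffusive speed
#'
#' `3 sigma / t`: the speed at which the 99.7% displacement envelope grows.
#' 0.0671 nm/ns for D = 0.25 nm^2/us, t = 2 ns.
#'
#' @param p a [diffusion_params()].
#' @return speed in nm/ns.
#' @export
characteristic_speed <- function(p) {
  stopifnot(inherits(p, "DiffusionParams"))
  3 * position_std(p) / p$t_ns
}

#' Instantaneous (per-time-step) diffusive speed
#'
#' `V = sqrt(4 D / dt)`: the step speed a random walker resolved at the
#' integration time step actually moves at, which is what its surroundings
#' mechanically sense. 22.36 nm/ns for D = 0.25 nm^2/us and dt = 2 fs.
#' A steering speed about an order of magnitude below V (see
#' [recommended_pull_speed()]) avoids sharp impulses on free neighbours.
#'
#' @param p a [diffusion_params()].
#' @return V in nm/ns.
#' @export
instantaneous_speed <- function(p) {
  stopifnot(inherits(p, "DiffusionParams"))
  sqrt(4 * .D_per_ns(p) / (p$dt_fs * 1e-6))
}

#' @rdname instantaneous_speed
#' @param factor reduction factor below V (default 10).
#' @export
recommended_pull_speed <- function(p, factor = 10) {
  instantaneous_speed(p) / factor
}

#' Actin stretch required to supply an association barrier
#'
#' A constant force F working over a displacement d supplies energy F d;
#' the stretch needed to inject a barrier of `barrier_kBT` thermal units is
#' `barrier_kBT * kB * T / F`. A 400 kBT barrier at 310 K under the ~50 pN
#' load an actin filament sustains needs ~34 nm.
#'
#' @param barrier_kBT barrier height in kBT.
#' @param temperature_K temperature (default 310 K).
#' @param force_pN applied force, pN; must be positive.
#' @return required displacement in nm.
#' @export
required_stretch <- function(barrier_kBT, temperature_K = 310, force_pN = 50) {
  stopifnot(barrier_kBT >= 0, temperature_K > 0)
  if (force_pN <= 0) stop("force must be positive")
  barrier_kBT * kbt_pN_nm(temperature_K) / force_pN
}

#' Geometric radii of the monomer + lipid-shell cylinder
#'
#' When two membrane-embedded monomers carrying co-travelling lipid shells
#' stall at a final centre-of-mass separation, symmetry splits that
#' distance into one lipid-cylinder envelope radius per monomer
#' (`final / 2`); the bare-contact separation does the same for the
#' effective monomer radius, and the difference of the two radii is the
#' lipid shell thickness. The study's printed 5.1 nm final separation gives
#' a 2.55 nm envelope, and a 2 nm bare contact gives a ~1 nm monomer
#' radius (hence a ~1.5 nm shell).
#'
#' @param final_com_distance_nm stalling centre-of-mass separation, nm.
#' @param bare_contact_distance_nm separation at bare (shell-free)
#'   contact, nm; must satisfy `final >= bare > 0`.
#' @return list with `envelope_radius_nm`, `monomer_radius_nm` and
#'   `shell_thickness_nm`.
#' @export
geometric_radii <- function(final_com_distance_nm, bare_contact_distance_nm) {
  stopifnot(bare_contact_distance_nm > 0,
            final_com_distance_nm >= bare_contact_distance_nm)
  list(envelope_radius_nm = final_com_distance_nm / 2,
       monomer_radius_nm = bare_contact_distance_nm / 2,
       shell_thickness_nm = (final_com_distance_nm -
                             bare_contact_distance_nm) / 2)
}
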