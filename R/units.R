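#' Unit conversions and physical constants
#'
#' Structures are stored in Angstrom (the PDB native unit) while all membrane
#' and free-energy analyses report nanometres; these two converters are the
#' single crossing point between the unit systems. The Boltzmann constant is
#' the CODATA value expressed in pN nm / K.
#'
#' @param x numeric vector of lengths.
#' @return `ang_to_nm()` and `nm_to_ang()` return the converted lengths.
#' @examples
#' nm_to_ang(ang_to_nm(8)) # 8, exactly
#' @name units
NULL

#' @rdname units
#' @export
ang_to_nm <- function(x) x / 10

#' @rdname units
#' @export
nm_to_ang <- function(x) x * 10

#' Boltzmann constant, pN nm / K (CODATA: 1.380649e-23 J/K)
#' @export
kB_pN_nm <- 1.380649e-2

#' Thermal energy kBT in pN nm
#'
#' @param temperature_K temperature in kelvin (default 310 K, physiological).
#' @return thermal energy in pN nm (about 4.28 pN nm at 310 K).
#' @export
kbt_pN_nm <- function(temperature_K = 310) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  kB_pN_nm * temperature_K
}
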