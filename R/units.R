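#' Unit conversions between MD and SI conventions
#'
#' Molecular dynamics force traces are recorded in Angstrom/ps for velocity
#' and kcal/mol/A for force; the magnetophoretic design stage works in SI.
#' Three unit systems meet in this pipeline (MD, SI, MRI hardware), so all
#' conversions are centralized here and applied once, at the system
#' identification boundary.
#'
#' 1 A/ps = 100 m/s; 1 kcal/mol/A = 6.9477e-11 N
#' (4184 J / 6.02214076e23 per Angstrom).
#'
#' @param v velocity in Angstrom per picosecond.
#' @param f force in kcal/mol/Angstrom.
#' @return The same quantity in SI units (m/s, N).
#' @examples
#' si_velocity(1.0) # 100 m/s
#' si_force(1.0)    # 6.9477e-11 N
#' @name units
NULL

#' @rdname units
#' @export
si_velocity <- function(v) v * 100

#' @rdname units
#' @export
si_force <- function(f) f * 6.9477e-11

# kcal/mol/A expressed in newtons; kept to one constant so the round trip
# in si_force()/md_force() is exact.
.KCAL_MOL_A_IN_N <- 6.9477e-11

#' @rdname units
#' @export
md_force <- function(f) f / .KCAL_MOL_A_IN_N
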