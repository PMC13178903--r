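# Single authoritative definition of the pressure unit boundary.
PA_PER_MMHG <- 133.322387415

#' Convert pressure between pascal and millimetres of mercury
#'
#' The package works in SI units internally and reports pressure drops in
#' mmHg at its user-facing surfaces. The conversion constant is
#' 1 mmHg = 133.322387415 Pa and is defined in exactly one place.
#'
#' @param p numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @examples
#' pa_to_mmhg(133.322387415)  # 1
#' @export
pa_to_mmhg <- function(p) p / PA_PER_MMHG

#' @rdname pa_to_mmhg
#' @export
mmhg_to_pa <- function(p) p * PA_PER_MMHG

# Litres per minute to m^3/s (pump flow rates are quoted in L/min).
#' Convert a volumetric flow rate from L/min to m^3/s
#' @param q flow rate in litres per minute.
#' @return flow rate in m^3/s.
#' @examples lpm_to_m3s(2.5)
#' @export
lpm_to_m3s <- function(q) q * 1e-3 / 60
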