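#' Unit conversion: mmHg to kPa
#'
#' The package works internally in mm, kPa and years. Clinical pressures are
#' quoted in mmHg; the conversion constant is 1 mmHg = 0.1333224 kPa.
#'
#' @param P_mmHg pressure in mmHg.
#' @return pressure in kPa.
#' @export
#' @examples
#' mmHg_to_kPa(110)
mmHg_to_kPa <- function(P_mmHg) P_mmHg * 0.1333224

#' Unit conversion: kPa to mmHg
#'
#' @param P_kPa pressure in kPa.
#' @return pressure in mmHg.
#' @export
kPa_to_mmHg <- function(P_kPa) P_kPa / 0.1333224
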