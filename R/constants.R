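#' Unit-conversion and physical constants
#'
#' Internal unit system: concentrations in uM, lengths in um (membrane
#' thicknesses in nm where stated), time in s, currents in pA. The cyclase
#' half-saturation `K_cyc` is stored in nM as conventionally printed and
#' converted at the point of use.
#'
#' @name constants
#' @keywords internal
NULL

#- molecules per um^3 in a 1 uM solution: N_Av * 1e-21
UM_TO_MOLEC_PER_UM3 <- 602.214

#- nm -> um
NM_TO_UM <- 1e-3
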