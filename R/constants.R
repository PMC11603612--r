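#' Boltzmann constant in kJ mol^-1 K^-1
#'
#' Internal unit system: energies in kJ/mol, time in ps, temperatures in K,
#' fictitious lambda masses in kJ mol^-1 ps^2 per (lambda-unit)^2.
#'
#' @export
k_boltzmann <- 0.0083144621

.ln10 <- log(10)

#' Reference pKa values of the titratable site classes
#'
#' Model-compound reference pKa values used to parameterize the pH potential:
#' Glu 4.25, Asp 3.65, His tautomer 1 (N-epsilon) 6.53, His tautomer 2
#' (N-delta) 6.92.
#'
#' @export
reference_pka <- c(GLU = 4.25, ASP = 3.65,
                   HIS_TAUTOMER = 6.53, HIS_TAUTOMER2 = 6.92)
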