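# Physical constants (SI, CODATA 2018)
.const <- list(
  e       = 1.602176634e-19,   # elementary charge, C
  kB      = 1.380649e-23,      # Boltzmann, J/K
  Navo    = 6.02214076e23,     # Avogadro, 1/mol
  eps0    = 8.8541878128e-12,  # vacuum permittivity, F/m
  F       = 96485.33212        # Faraday, C/mol
)

#' @keywords internal
gas_constant <- function() .const$kB * .const$Navo
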