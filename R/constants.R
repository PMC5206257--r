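# Internal unit system: Å, fs, g/mol, K, atm, kJ/mol, elementary charge.
# One conversion layer; everything downstream works in these units.

.const <- list(
  coulomb  = 1389.35458,       # kJ Å mol^-1 e^-2
  kB       = 0.008314462618,   # kJ mol^-1 K^-1
  R_J      = 8.314,            # J mol^-1 K^-1, as used in the log D relation
  fconv    = 1e-4,             # kJ/mol -> g/mol Å^2 fs^-2
  keconv   = 1e4,              # g/mol (Å/fs)^2 -> kJ/mol
  patm     = 16388.246,        # kJ mol^-1 Å^-3 -> atm
  debye    = 0.2081943         # e Å per Debye
)

#' Physical constants and unit conversions used internally
#'
#' Returns the constants of the package's internal unit system
#' (Å, fs, g/mol, K, atm, kJ/mol, e), including the Coulomb prefactor
#' 1389.35458 kJ Å mol^-1 e^-2.
#'
#' @return Named list of constants.
#' @export
elba_constants <- function() .const
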