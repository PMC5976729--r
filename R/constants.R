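#' Physical constants used throughout the package
#'
#' SI values (CODATA). Exported as a named list so that every module shares a
#' single source of truth for unit conversions.
#'
#' @format A named list with elements
#' \describe{
#'   \item{c}{speed of light in vacuum, m/s}
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{NA}{Avogadro constant, 1/mol}
#'   \item{eps0}{vacuum permittivity, F/m}
#' }
#' @export
tke_constants <- list(
  c    = 299792458,
  kB   = 1.380649e-23,
  `NA` = 6.02214076e23,
  eps0 = 8.8541878128e-12
)

# internal shorthands
.c0 <- tke_constants$c
.kB <- tke_constants$kB
.NAvo <- tke_constants$`NA`
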