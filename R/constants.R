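## Physical constants (CODATA, SI units).

#' Physical constants used throughout the package
#'
#' A named list of SI constants: `kB` (Boltzmann constant, J/K), `e`
#' (elementary charge, C), `N_A` (Avogadro number, 1/mol), `eps0`
#' (vacuum permittivity, F/m).
#'
#' @format Named list of numeric scalars.
#' @export
times_constants <- list(
  kB   = 1.380649e-23,
  e    = 1.602176634e-19,
  N_A  = 6.02214076e23,
  eps0 = 8.8541878128e-12
)

#' Parse a concentration with unit suffix to SI (mol/m^3)
#'
#' Concentrations cross the package boundary in the units practitioners
#' use (micromolar and nanomolar); internally everything is mol/m^3.
#' Accepts a bare number (already mol/m^3) or a string like `"100 uM"`,
#' `"300 nM"`, `"0.1 mM"`, `"1 M"`, `"2 mol/m3"`.
#'
#' @param x numeric scalar/vector (passed through) or character like
#'   `"100 uM"`.
#' @return numeric vector, mol/m^3.
#' @examples
#' concentration_si("100 uM") # 0.1 mol/m^3
#' concentration_si("300 nM") # 3e-4 mol/m^3
#' @export
concentration_si <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(uM|nM|mM|pM|M|mol/m3)$", s))[[1]]
    if (length(m) == 0L) stop("unparseable concentration: '", s, "'")
    val <- as.numeric(m[2])
    # 1 mol/L = 1000 mol/m^3
    fac <- switch(m[3],
      "pM" = 1e-12 * 1e3, "nM" = 1e-9 * 1e3, "uM" = 1e-6 * 1e3,
      "mM" = 1e-3 * 1e3, "M" = 1e3, "mol/m3" = 1)
    val * fac
  }, numeric(1), USE.NAMES = FALSE)
}

#' Format a mol/m^3 concentration in a display unit
#'
#' @param x concentration, mol/m^3.
#' @param unit one of `"uM"`, `"nM"`, `"mM"`, `"M"`, `"mol/m3"`.
#' @return numeric in the requested unit.
#' @export
concentration_as <- function(x, unit = c("uM", "nM", "mM", "M", "mol/m3")) {
  unit <- match.arg(unit)
  fac <- switch(unit, "nM" = 1e-9 * 1e3, "uM" = 1e-6 * 1e3,
                "mM" = 1e-3 * 1e3, "M" = 1e3, "mol/m3" = 1)
  x / fac
}
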