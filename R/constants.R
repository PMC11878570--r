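#' Physical constants used throughout the package
#'
#' Returns the constants needed to convert between diffusion
#' coefficients, concentrations, and molecule counts. The water
#' viscosity curve is pinned at 25 degrees C (8.90e-4 Pa s) and
#' 37 degrees C (6.913e-4 Pa s) and interpolated between/beyond with an
#' Arrhenius form eta(T) = A * exp(B/T), which reproduces tabulated
#' water viscosities to well under 1% over 0-60 degrees C.
#'
#' @param avogadro Avogadro's number, mol^-1. CODATA value by default.
#' @param stokes_constant Stokes-Einstein proportionality constant used
#'   in the temperature correction of diffusion coefficients, Pa s / K.
#'   Chosen so that D(25C) * (25 + 273.15) / eta(25C) * stokes_constant
#'   is the identity.
#' @param hela_nuclear_volume Average HeLa nuclear volume in liters
#'   (6.90e-13 l = 690 cubic micrometers).
#' @return A list with elements `avogadro`, `stokes_constant`,
#'   `hela_nuclear_volume`, and `eta`, a function of temperature in
#'   degrees C returning the viscosity of water in Pa s (defined on
#'   0-60 degrees C).
#' @examples
#' const <- fcs_constants()
#' const$eta(37)  # 6.913e-4 Pa s
#' @export
fcs_constants <- function(avogadro = 6.02214076e23,
                          stokes_constant = 2.985e-6,
                          hela_nuclear_volume = 6.90e-13) {
  stopifnot(avogadro > 0, stokes_constant > 0, hela_nuclear_volume > 0)
  # Arrhenius fit through the two pinned viscosities
  t1 <- 298.15; eta1 <- 8.90e-4
  t2 <- 310.15; eta2 <- 6.913e-4
  b <- log(eta1 / eta2) / (1 / t1 - 1 / t2)
  a <- eta1 / exp(b / t1)
  eta <- function(t_celsius) {
    if (any(t_celsius < 0 | t_celsius > 60)) {
      stop("temperature outside the supported range [0, 60] degrees C",
           call. = FALSE)
    }
    a * exp(b / (t_celsius + 273.15))
  }
  list(
    avogadro = avogadro,
    stokes_constant = stokes_constant,
    hela_nuclear_volume = hela_nuclear_volume,
    eta = eta
  )
}

#' Registry of dye standards for confocal volume calibration
#'
#' Diffusion coefficients at 25 degrees C in water, as reported in the
#' photophysics literature for common calibration dyes.
#'
#' @return A data frame with columns `name` and `d25` (cm^2/s).
#' @seealso [temp_correct_diffusion()], [calibrate_focal_volume()]
#' @export
dye_standards <- function() {
  data.frame(
    name = c("alexa_594", "alexa_488"),
    d25 = c(3.88e-6, 4.14e-6),
    stringsAsFactors = FALSE
  )
}

#' Look up a dye standard by name
#'
#' @param name Dye name, e.g. `"alexa_594"`.
#' @param registry Registry data frame; defaults to [dye_standards()].
#'   Supply your own data frame (columns `name`, `d25`) to add dyes.
#' @return A list with elements `name` and `d25` (cm^2/s at 25 C).
#' @export
dye_standard <- function(name, registry = dye_standards()) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown dye standard '", name, "'; known: ",
         paste(registry$name, collapse = ", "), call. = FALSE)
  }
  list(name = registry$name[i], d25 = registry$d25[i])
}

# default structure factor: radial/axial ratio of the Gaussian focal
# volume, measured once with a dye standard and held fixed in all fits
.default_structure_factor <- 0.17
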