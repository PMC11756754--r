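#' Diffraction-limited lateral resolution (Rayleigh criterion)
#'
#' Computes the Rayleigh resolution limit `0.61 * wavelength / NA` for a
#' microscope objective. With the red LED illumination used by compact
#' bright-field incubator microscopes (peak 0.625 um), the supported 4X/10X/20X
#' plan-achromat objectives resolve 3.8, 1.52 and 0.95 um respectively.
#'
#' @param wavelength Illumination wavelength in micrometres. Default 0.625.
#' @param numerical_aperture Objective numerical aperture, in (0, 1).
#' @return Resolution in micrometres.
#' @examples
#' rayleigh_resolution(0.625, 0.10) # ~3.81 um, the 4X limit
#' @export
rayleigh_resolution <- function(wavelength = 0.625, numerical_aperture) {
  stopifnot(is.numeric(wavelength), is.numeric(numerical_aperture))
  if (any(wavelength <= 0)) {
    stop("`wavelength` must be positive (micrometres).", call. = FALSE)
  }
  if (any(numerical_aperture <= 0) || any(numerical_aperture >= 1)) {
    stop("`numerical_aperture` must lie strictly in (0, 1).", call. = FALSE)
  }
  0.61 * wavelength / numerical_aperture
}

#' Built-in objective configurations
#'
#' The three imaging modes of the instrument: 4X, 10X and 20X plan-achromat
#' objectives on a 20-megapixel CMOS sensor (5472 x 3648, 2.4 um pixels).
#' `pixel_equiv` is the sample-plane size of one camera pixel in micrometres;
#' `fov_w`/`fov_h` the field of view in millimetres. Detection is
#' diffraction-limited for every mode: `pixel_equiv` never exceeds the
#' Rayleigh resolution at the 0.625 um illumination peak.
#'
#' @return A tibble with one row per objective: `name`, `numerical_aperture`,
#'   `pixel_equiv` (um/px), `fov_w`, `fov_h` (mm), `wavelength` (um),
#'   `sensor_cols`, `sensor_rows`.
#' @examples
#' objective_configs()
#' @export
objective_configs <- function() {
  cfg <- tibble::tibble(
    name = c("4X", "10X", "20X"),
    numerical_aperture = c(0.10, 0.25, 0.40),
    pixel_equiv = c(1.08, 0.432, 0.216),
    fov_w = c(6, 2.3, 1.15),
    fov_h = c(4, 1.6, 0.8),
    wavelength = 0.625,
    sensor_cols = 5472L,
    sensor_rows = 3648L
  )
  validate_objective_configs(cfg)
  cfg
}

validate_objective_configs <- function(cfg) {
  stopifnot(
    all(cfg$numerical_aperture > 0 & cfg$numerical_aperture < 1),
    all(cfg$pixel_equiv > 0),
    all(cfg$fov_w > 0 & cfg$fov_h > 0),
    # magnification ordering: finer pixels, higher NA from 4X to 20X
    all(diff(cfg$pixel_equiv) < 0),
    all(diff(cfg$numerical_aperture) > 0),
    # diffraction-limited detection for every mode
    all(cfg$pixel_equiv <=
          rayleigh_resolution(cfg$wavelength, cfg$numerical_aperture))
  )
  invisible(cfg)
}

#' Look up one objective configuration by name
#'
#' @param name One of `"4X"`, `"10X"`, `"20X"`.
#' @return A one-row tibble (see [objective_configs()]).
#' @export
objective_config <- function(name) {
  cfg <- objective_configs()
  hit <- cfg[cfg$name == name, ]
  if (nrow(hit) != 1L) {
    stop("Unknown objective '", name, "'; use one of ",
         paste(cfg$name, collapse = ", "), call. = FALSE)
  }
  hit
}
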