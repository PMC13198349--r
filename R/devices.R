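# Device catalogue and volume-preserving design sweeps.

#' Construct a device specification
#'
#' @param name device name
#' @param length capsule length (mm)
#' @param diameter capsule diameter (mm); give exactly one of `diameter` or
#'   `volume`
#' @param volume capsule volume (mm^3)
#' @return object of class `device_spec` with consistent
#'   `volume = pi * (diameter/2)^2 * length`
#' @export
device_spec <- function(name, length, diameter = NULL, volume = NULL) {
  if (length <= 0) stop("device length must be > 0")
  if (is.null(diameter) && is.null(volume)) stop("give diameter or volume")
  if (is.null(diameter)) diameter <- volume_preserving_diameter(volume, length)
  if (diameter <= 0) stop("device diameter must be > 0")
  vol <- pi * (diameter / 2)^2 * length
  if (!is.null(volume) && abs(vol - volume) > 1e-6 * volume) {
    stop("inconsistent device volume")
  }
  structure(list(name = name, length = length, diameter = diameter,
                 volume = vol), class = "device_spec")
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec %s: length %.1f mm, diameter %.2f mm, volume %.2f cm3>\n",
              x$name, x$length, x$diameter, x$volume / 1000))
  invisible(x)
}

#' Contemporary leadless-pacemaker catalogue
#'
#' Micra TPS (25.9 mm), Aveir AR (32.2 mm) and Aveir VR (38 mm).  Device
#' diameters are configurable constants with manufacturer-nominal defaults
#' (Micra 6.7 mm, Aveir AR/VR 6.5 mm); every result table records the
#' configured values.
#'
#' @param diameters named numeric vector of diameters (mm) for
#'   `micra_tps`, `aveir_ar`, `aveir_vr`
#' @return list of [device_spec]
#' @export
lpm_catalogue <- function(diameters = c(micra_tps = 6.7, aveir_ar = 6.5,
                                        aveir_vr = 6.5)) {
  lengths <- c(micra_tps = 25.9, aveir_ar = 32.2, aveir_vr = 38.0)
  lapply(names(lengths), function(nm) {
    device_spec(nm, lengths[[nm]], diameter = diameters[[nm]])
  })
}

#' Diameter that preserves a given volume at a given length
#'
#' `2 * sqrt(volume / (pi * length))`.
#' @param volume mm^3, > 0
#' @param length mm, > 0
#' @export
volume_preserving_diameter <- function(volume, length) {
  if (any(volume <= 0) || any(length <= 0)) {
    stop("volume and length must be positive")
  }
  2 * sqrt(volume / (pi * length))
}

#' Volume-preserving length sweep for a base device
#'
#' Derived designs keep the base device volume while varying length
#' (default 15-45 mm in 5 mm increments), so battery capacity is held fixed
#' as the aspect ratio changes.
#'
#' @param base a [device_spec]
#' @param lengths lengths to sweep (mm)
#' @return object of class `design_sweep` with fields `base_device`,
#'   `lengths`, `derived` (list of [device_spec])
#' @export
build_sweep <- function(base, lengths = seq(15, 45, by = 5)) {
  if (any(lengths <= 0)) stop("sweep lengths must be positive")
  derived <- lapply(lengths, function(L) {
    device_spec(sprintf("%s_L%g", base$name, L), L, volume = base$volume)
  })
  structure(list(base_device = base, lengths = lengths, derived = derived),
            class = "design_sweep")
}

#' @export
print.design_sweep <- function(x, ...) {
  cat(sprintf("<design_sweep of %s (%.2f cm3): lengths %s mm>\n",
              x$base_device$name, x$base_device$volume / 1000,
              paste(x$lengths, collapse = ", ")))
  invisible(x)
}
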