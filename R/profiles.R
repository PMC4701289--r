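#' Class labels for ingestive behavior
#'
#' The five behavioral classes distinguished by the pipeline, in their
#' canonical order. This order is used for factor levels, confusion-matrix
#' rows/columns and all tie-breaking rules.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' chew_classes()
chew_classes <- function() {
  c("dietary_supplement", "hay", "ryegrass", "rumination", "idleness")
}

#' FBG sensor model
#'
#' A fiber Bragg grating strain transducer is characterized by its unstrained
#' Bragg wavelength and the linear sensitivity of the reflected wavelength to
#' mechanical strain. The default sensitivity of 1.2 pm per microstrain is
#' typical for silica fiber gratings near 1550 nm.
#'
#' @param bragg_wavelength_nm Unstrained Bragg wavelength (nm).
#' @param strain_sensitivity_pm_per_microstrain Wavelength shift per unit
#'   strain (pm per um/m).
#' @return An object of class `fbg_sensor`.
#' @export
#' @examples
#' sensor_model()
sensor_model <- function(bragg_wavelength_nm = 1541,
                         strain_sensitivity_pm_per_microstrain = 1.2) {
  stopifnot(is.numeric(bragg_wavelength_nm), bragg_wavelength_nm > 0,
            is.numeric(strain_sensitivity_pm_per_microstrain),
            strain_sensitivity_pm_per_microstrain > 0)
  structure(list(
    bragg_wavelength_nm = bragg_wavelength_nm,
    strain_sensitivity_pm_per_microstrain = strain_sensitivity_pm_per_microstrain
  ), class = "fbg_sensor")
}

#' Class-conditional chew-movement profile
#'
#' Parameters of the quasi-periodic jaw-strain waveform emitted during one
#' behavioral class: aperture peak strain, DC baseline strain, chew-cycle
#' fundamental frequency, relative depth of the jaw-closure trough, cycle-level
#' amplitude/period jitter and additive sensor noise.
#'
#' @param label Class name, one of [chew_classes()].
#' @param peak_strain_microstrain Aperture peak height above the DC baseline
#'   (um/m).
#' @param dc_strain_microstrain Baseline (DC) strain offset (um/m).
#' @param fundamental_hz Chew-cycle rate (Hz).
#' @param trough_fraction Depth of the closure trough relative to the aperture
#'   peak (unitless, in \[0, 1\]).
#' @param amplitude_jitter_cv Coefficient of variation of cycle amplitude.
#' @param period_jitter_cv Coefficient of variation of cycle period.
#' @param noise_sd_microstrain Standard deviation of additive Gaussian sensor
#'   noise (um/m).
#' @return An object of class `chew_profile`.
#' @export
class_profile <- function(label,
                          peak_strain_microstrain,
                          dc_strain_microstrain,
                          fundamental_hz,
                          trough_fraction = 0.3,
                          amplitude_jitter_cv = 0.05,
                          period_jitter_cv = 0.05,
                          noise_sd_microstrain = 2) {
  stopifnot(is.character(label), length(label) == 1L,
            peak_strain_microstrain >= 0,
            fundamental_hz > 0,
            trough_fraction >= 0, trough_fraction <= 1,
            amplitude_jitter_cv >= 0, amplitude_jitter_cv <= 0.5,
            period_jitter_cv >= 0, period_jitter_cv <= 0.5,
            noise_sd_microstrain >= 0)
  structure(list(
    label = label,
    peak_strain_microstrain = peak_strain_microstrain,
    dc_strain_microstrain = dc_strain_microstrain,
    fundamental_hz = fundamental_hz,
    trough_fraction = trough_fraction,
    amplitude_jitter_cv = amplitude_jitter_cv,
    period_jitter_cv = period_jitter_cv,
    noise_sd_microstrain = noise_sd_microstrain
  ), class = "chew_profile")
}

#' Default class profiles
#'
#' One waveform profile per behavioral class. Peak strains are 50
#' (dietary supplement), 178 (hay), 100 (ryegrass), 42 (rumination) and
#' 12 (idleness) um/m; chew-cycle fundamentals are 2.49, 1.66, 2.0, 1.66 and
#' 1.54 Hz respectively. DC baselines are ordered
#' idleness < rumination < every food class. Ryegrass carries a larger
#' amplitude jitter than the other classes so that its cycle peaks spread
#' down toward ~60 um/m.
#'
#' @return Named list of [class_profile()] objects, one per class, in
#'   [chew_classes()] order.
#' @export
#' @examples
#' default_profiles()[["hay"]]$peak_strain_microstrain
default_profiles <- function() {
  list(
    dietary_supplement = class_profile("dietary_supplement",
      peak_strain_microstrain = 50, dc_strain_microstrain = 30,
      fundamental_hz = 2.49),
    hay = class_profile("hay",
      peak_strain_microstrain = 178, dc_strain_microstrain = 40,
      fundamental_hz = 1.66),
    ryegrass = class_profile("ryegrass",
      peak_strain_microstrain = 100, dc_strain_microstrain = 35,
      fundamental_hz = 2.0, amplitude_jitter_cv = 0.15),
    rumination = class_profile("rumination",
      peak_strain_microstrain = 42, dc_strain_microstrain = 15,
      fundamental_hz = 1.66),
    idleness = class_profile("idleness",
      peak_strain_microstrain = 12, dc_strain_microstrain = 5,
      fundamental_hz = 1.54)
  )
}

#' @export
print.fbg_sensor <- function(x, ...) {
  cat(sprintf("FBG sensor: lambda_B = %g nm, sensitivity = %g pm per um/m\n",
              x$bragg_wavelength_nm, x$strain_sensitivity_pm_per_microstrain))
  invisible(x)
}

#' @export
print.chew_profile <- function(x, ...) {
  cat(sprintf(
    "chew profile '%s': peak %g um/m, DC %g um/m, f0 %g Hz (trough %g, noise sd %g)\n",
    x$label, x$peak_strain_microstrain, x$dc_strain_microstrain,
    x$fundamental_hz, x$trough_fraction, x$noise_sd_microstrain))
  invisible(x)
}
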