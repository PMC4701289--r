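#' Strain / wavelength trace containers
#'
#' A trace is a uniformly sampled series with per-sample class labels.
#' Strain traces carry jaw-bone strain in um/m; wavelength traces carry the
#' Bragg-reflected wavelength in nm.
#'
#' @param samples Numeric vector of sample values.
#' @param sampling_rate_hz Sampling rate (samples per second).
#' @param labels Character vector of per-sample class labels (or `NA` for
#'   unlabeled samples); recycled if length 1.
#' @return An object of class `strain_trace` or `wavelength_trace`.
#' @export
strain_trace <- function(samples, sampling_rate_hz, labels = NA_character_) {
  new_trace(samples, sampling_rate_hz, labels, "strain_trace")
}

#' @rdname strain_trace
#' @export
wavelength_trace <- function(samples, sampling_rate_hz, labels = NA_character_) {
  new_trace(samples, sampling_rate_hz, labels, "wavelength_trace")
}

new_trace <- function(samples, sampling_rate_hz, labels, cls) {
  stopifnot(is.numeric(samples), is.numeric(sampling_rate_hz),
            length(sampling_rate_hz) == 1L, sampling_rate_hz > 0)
  if (length(labels) == 1L) labels <- rep(as.character(labels), length(samples))
  if (length(labels) != length(samples))
    stop("samples and labels must have equal length")
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 labels = as.character(labels)),
            class = cls)
}

#' @export
print.strain_trace <- function(x, ...) {
  print_trace(x, "strain", "um/m")
}

#' @export
print.wavelength_trace <- function(x, ...) {
  print_trace(x, "wavelength", "nm")
}

print_trace <- function(x, what, unit) {
  n <- length(x$samples)
  cat(sprintf("%s trace: %d samples at %g S/s (%.2f s), range %.3f..%.3f %s\n",
              what, n, x$sampling_rate_hz, n / x$sampling_rate_hz,
              if (n) min(x$samples) else NA, if (n) max(x$samples) else NA,
              unit))
  lab <- table(x$labels, useNA = "no")
  if (length(lab))
    cat("labels:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "), "\n")
  invisible(x)
}

# One noiseless, unit-amplitude chew cycle over n samples: a raised-cosine
# aperture pulse over the first `peak_fraction` of the cycle followed by a
# negative half raised-cosine closure trough of relative depth
# `trough_fraction`. Starts and ends at 0 (the DC baseline).
chew_cycle_shape <- function(n, trough_fraction, peak_fraction = 0.6) {
  u <- (seq_len(n) - 1) / n
  ifelse(u < peak_fraction,
         0.5 * (1 - cos(2 * pi * u / peak_fraction)),
         -trough_fraction * 0.5 *
           (1 - cos(2 * pi * (u - peak_fraction) / (1 - peak_fraction))))
}

#' Generate one chew movement
#'
#' Simulates a single jaw open-close cycle for a behavioral class: a positive
#' aperture peak of height ~ `peak_strain_microstrain` above the DC baseline,
#' followed by a closure trough of relative depth `trough_fraction`, with
#' cycle-level amplitude/period jitter and additive Gaussian noise. The cycle
#' begins and ends at the DC baseline and has nominal duration
#' `1 / fundamental_hz`. Randomness is drawn from the current R random number
#' stream; seed it (or use [generate_session()]) for reproducibility.
#'
#' @param profile A [class_profile()].
#' @param sampling_rate_hz Sampling rate (S/s); must exceed twice the
#'   fundamental frequency.
#' @return A [strain_trace()] holding one cycle, labeled with the profile's
#'   class.
#' @export
#' @examples
#' set.seed(1)
#' mv <- generate_movement(default_profiles()[["hay"]])
#' length(mv$samples)
generate_movement <- function(profile, sampling_rate_hz = 1000) {
  stopifnot(inherits(profile, "chew_profile"))
  if (sampling_rate_hz <= 2 * profile$fundamental_hz)
    stop("sampling_rate_hz must exceed twice the fundamental frequency (aliasing)")
  period <- 1 / profile$fundamental_hz
  if (profile$period_jitter_cv > 0)
    period <- period * max(0.5, 1 + profile$period_jitter_cv * stats::rnorm(1))
  amp <- profile$peak_strain_microstrain
  if (profile$amplitude_jitter_cv > 0)
    amp <- max(0, amp * (1 + profile$amplitude_jitter_cv * stats::rnorm(1)))
  n <- max(2L, as.integer(round(sampling_rate_hz * period)))
  x <- profile$dc_strain_microstrain +
    amp * chew_cycle_shape(n, profile$trough_fraction)
  if (profile$noise_sd_microstrain > 0)
    x <- x + stats::rnorm(n, 0, profile$noise_sd_microstrain)
  strain_trace(x, sampling_rate_hz, profile$label)
}

#' Session specification
#'
#' Describes a labeled recording session as an ordered sequence of behavioral
#' segments, each contributing a number of chew movements separated by
#' baseline gaps. A trailing baseline tail is appended after the last
#' movement so that the final chew cycle is closed by a detectable baseline
#' crossing during segmentation.
#'
#' @param segments A data frame with columns `class` and `count`, one row per
#'   behavioral segment in session order.
#' @param sampling_rate_hz Sampling rate (S/s).
#' @param inter_movement_gap_s Baseline gap between consecutive movements (s).
#' @param tail_s Duration of the trailing baseline tail (s).
#' @param seed Integer seed fixing all randomness of the session.
#' @return An object of class `session_spec`.
#' @export
#' @examples
#' session_spec(data.frame(class = "hay", count = 10), seed = 7)
session_spec <- function(segments,
                         sampling_rate_hz = 1000,
                         inter_movement_gap_s = 0.1,
                         tail_s = 2,
                         seed = 1) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("class", "count") %in% names(segments)),
            nrow(segments) >= 1L,
            all(segments$count >= 1),
            sampling_rate_hz > 0,
            inter_movement_gap_s >= 0, tail_s >= 0)
  segments$class <- as.character(segments$class)
  segments$count <- as.integer(segments$count)
  structure(list(segments = segments,
                 sampling_rate_hz = sampling_rate_hz,
                 inter_movement_gap_s = inter_movement_gap_s,
                 tail_s = tail_s,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Balanced default session
#'
#' Convenience constructor for a session with the same number of movements for
#' each of the five classes, in canonical class order.
#'
#' @param movements_per_class Number of chew movements per class.
#' @param seed Integer seed.
#' @param ... Passed on to [session_spec()].
#' @return A `session_spec`.
#' @export
balanced_session_spec <- function(movements_per_class = 200, seed = 1, ...) {
  session_spec(data.frame(class = chew_classes(),
                          count = movements_per_class),
               seed = seed, ...)
}

#' Generate a labeled chewing session
#'
#' Assembles a strain trace by concatenating, for each segment of the
#' specification, the requested number of chew movements, each preceded by a
#' baseline gap at the class DC level, and appends a trailing baseline tail.
#' Every sample is labeled with its generating class. All randomness flows
#' from the seed in the specification; the caller's random number state is
#' left untouched, and identical specifications produce identical traces.
#'
#' @param spec A [session_spec()].
#' @param profiles Named list of [class_profile()] objects covering every
#'   class in the spec.
#' @return A labeled [strain_trace()].
#' @export
#' @examples
#' spec <- session_spec(data.frame(class = "idleness", count = 3), seed = 2)
#' tr <- generate_session(spec)
generate_session <- function(spec, profiles = default_profiles()) {
  stopifnot(inherits(spec, "session_spec"))
  unknown <- setdiff(spec$segments$class, names(profiles))
  if (length(unknown))
    stop("no profile for class: ", paste(unknown, collapse = ", "))
  fs <- spec$sampling_rate_hz
  gap_n <- as.integer(round(spec$inter_movement_gap_s * fs))
  tail_n <- as.integer(round(spec$tail_s * fs))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  pieces <- vector("list", sum(spec$segments$count) * 2L + 1L)
  labels <- character(length(pieces))
  k <- 0L
  for (s in seq_len(nrow(spec$segments))) {
    cls <- spec$segments$class[s]
    prof <- profiles[[cls]]
    for (i in seq_len(spec$segments$count[s])) {
      # lead-in baseline gap, then the chew cycle: a class segment then ends
      # at its last cycle, so falling class transitions sit on the lower DC
      # of the next class and cannot rise through the falling running mean
      if (gap_n > 0L) {
        gap <- rep(prof$dc_strain_microstrain, gap_n)
        if (prof$noise_sd_microstrain > 0)
          gap <- gap + stats::rnorm(gap_n, 0, prof$noise_sd_microstrain)
        k <- k + 1L; pieces[[k]] <- gap; labels[k] <- cls
      }
      mv <- generate_movement(prof, fs)
      k <- k + 1L; pieces[[k]] <- mv$samples; labels[k] <- cls
    }
  }
  if (tail_n > 0L) {
    prof <- profiles[[spec$segments$class[nrow(spec$segments)]]]
    tail_x <- rep(prof$dc_strain_microstrain, tail_n)
    if (prof$noise_sd_microstrain > 0)
      tail_x <- tail_x + stats::rnorm(tail_n, 0, prof$noise_sd_microstrain)
    k <- k + 1L; pieces[[k]] <- tail_x; labels[k] <- prof$label
  }
  pieces <- pieces[seq_len(k)]
  labels <- labels[seq_len(k)]
  strain_trace(unlist(pieces, use.names = FALSE), fs,
               rep(labels, lengths(pieces)))
}

#' Convert strain to Bragg wavelength
#'
#' Applies the linear FBG transduction law
#' `lambda(t) = lambda_B + k * epsilon(t)` with `k` the sensor sensitivity
#' expressed in nm per um/m (`strain_sensitivity_pm_per_microstrain / 1000`).
#'
#' @param trace A [strain_trace()].
#' @param sensor A [sensor_model()].
#' @return A [wavelength_trace()] with the same labels and sampling rate.
#' @export
#' @examples
#' tr <- strain_trace(c(0, 90), 1000)
#' encode_wavelength(tr, sensor_model())$samples  # 1541.000 1541.108
encode_wavelength <- function(trace, sensor = sensor_model()) {
  stopifnot(inherits(trace, "strain_trace"), inherits(sensor, "fbg_sensor"))
  k_nm <- sensor$strain_sensitivity_pm_per_microstrain / 1000
  wavelength_trace(sensor$bragg_wavelength_nm + k_nm * trace$samples,
                   trace$sampling_rate_hz, trace$labels)
}

#' Convert Bragg wavelength back to strain
#'
#' Exact inverse of [encode_wavelength()]:
#' `epsilon(t) = (lambda(t) - lambda_B) / k`.
#'
#' @param trace A [wavelength_trace()].
#' @param sensor A [sensor_model()].
#' @return A [strain_trace()].
#' @export
decode_strain <- function(trace, sensor = sensor_model()) {
  stopifnot(inherits(trace, "wavelength_trace"), inherits(sensor, "fbg_sensor"))
  k_nm <- sensor$strain_sensitivity_pm_per_microstrain / 1000
  strain_trace((trace$samples - sensor$bragg_wavelength_nm) / k_nm,
               trace$sampling_rate_hz, trace$labels)
}
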