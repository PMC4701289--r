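#' Discrete Fourier transform with 1/N normalization
#'
#' Computes `X(k) = (1/N) * sum_n x(n) exp(-i 2 pi k n / N)` over the
#' analyzed segment and returns the magnitude spectrum. Under this
#' normalization the k = 0 (DC) magnitude equals the absolute segment mean,
#' and the bin spacing is `sampling_rate / N`, which for a segment spanning
#' one chew cycle is the cycle's fundamental frequency.
#'
#' @param segment Numeric vector (the unpadded native samples of a movement).
#' @param sampling_rate_hz Sampling rate (S/s), used only to report the bin
#'   spacing.
#' @return An object of class `chew_spectrum` with fields `magnitudes`
#'   (bins k = 0..N-1), `bin_spacing_hz` and `native_length`.
#' @export
#' @examples
#' sp <- dft(cos(2 * pi * 5 * (0:999) / 1000), 1000)
#' sp$magnitudes[6]  # 0.5 at bin 5
dft <- function(segment, sampling_rate_hz = 1000) {
  if (!length(segment)) stop("empty segment")
  n <- length(segment)
  structure(list(magnitudes = Mod(stats::fft(segment)) / n,
                 bin_spacing_hz = sampling_rate_hz / n,
                 native_length = n),
            class = "chew_spectrum")
}

#' @export
print.chew_spectrum <- function(x, ...) {
  cat(sprintf("spectrum: N = %d, bin spacing %.4f Hz, DC magnitude %.6f\n",
              x$native_length, x$bin_spacing_hz, x$magnitudes[1]))
  invisible(x)
}

#' First spectral components of a movement
#'
#' Returns the magnitudes of bins 0..`n_components - 1`. Bin 0 is the DC
#' component (the segment mean); bin 1 sits at the movement's fundamental
#' frequency because the analyzed segment spans one chew period.
#'
#' @param spectrum A `chew_spectrum`.
#' @param n_components Number of components to keep.
#' @return Numeric vector of length `n_components`.
#' @export
spectral_attributes <- function(spectrum, n_components = 30L) {
  if (length(spectrum$magnitudes) < n_components)
    stop("segment has fewer samples than requested spectral components")
  spectrum$magnitudes[seq_len(n_components)]
}

#' Feature-construction parameters
#'
#' @param fft_input Whether the spectrum is computed on the unpadded
#'   `"native"` movement samples (default; bin spacing then equals the
#'   movement's own fundamental) or on the `"padded"` fixed-length vector
#'   (uniform 1 Hz spacing at 1 kS/s).
#' @param time_attrs Number of time-domain attributes: 1000 (all padded
#'   samples) or a reduced 500/250 obtained by uniform decimation of the
#'   padded vector.
#' @param n_spectral Number of spectral attributes appended after the time
#'   attributes.
#' @param target_length Padded instance length in samples.
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(fft_input = c("native", "padded"),
                           time_attrs = 1000L,
                           n_spectral = 30L,
                           target_length = 1000L) {
  fft_input <- match.arg(fft_input)
  time_attrs <- as.integer(time_attrs)
  stopifnot(time_attrs >= 1, time_attrs <= target_length,
            target_length %% time_attrs == 0,
            n_spectral >= 1)
  structure(list(fft_input = fft_input,
                 time_attrs = time_attrs,
                 n_spectral = as.integer(n_spectral),
                 target_length = as.integer(target_length)),
            class = "feature_params")
}

#' Build one feature instance from a movement
#'
#' The first `time_attrs` attributes are the padded (and, for reduced
#' configurations, uniformly decimated) wavelength samples of the movement;
#' the following `n_spectral` attributes are the magnitudes of the first
#' spectral components of its DFT. With defaults this yields the
#' 1030-attribute vector a1..a1030 where a1001 is the DC magnitude (the
#' absolute segment mean).
#'
#' @param movement A `chew_movement`.
#' @param params A [feature_params()].
#' @return List with `attributes` (named numeric vector) and `label`.
#' @export
build_instance <- function(movement, params = feature_params()) {
  stopifnot(inherits(params, "feature_params"))
  padded <- pad_to_length(movement, params$target_length)
  time_part <- if (params$time_attrs < params$target_length) {
    padded[seq(1L, params$target_length,
               by = params$target_length %/% params$time_attrs)]
  } else padded
  seg <- if (params$fft_input == "native") movement$samples else padded
  spec_part <- spectral_attributes(dft(seg, movement$sampling_rate_hz),
                                   params$n_spectral)
  attrs <- c(time_part, spec_part)
  names(attrs) <- paste0("a", seq_along(attrs))
  list(attributes = attrs, label = movement$label)
}

#' Assemble a labeled training set
#'
#' Takes the first `per_class_cap` movements of each class in temporal order
#' and builds one feature instance per movement. Classes with no movements
#' are omitted with a warning.
#'
#' @param movements List of `chew_movement` objects (from
#'   [segment_movements()]).
#' @param per_class_cap Maximum instances kept per class.
#' @param params A [feature_params()].
#' @param classes Class universe and ordering for the label factor.
#' @return An object of class `chew_dataset` with fields `X` (numeric matrix,
#'   one row per instance, columns a1..), `y` (factor of labels),
#'   `per_class_counts` and `params`.
#' @export
build_dataset <- function(movements, per_class_cap = 200L,
                          params = feature_params(),
                          classes = chew_classes()) {
  labs <- vapply(movements, function(m) m$label, character(1))
  present <- classes[classes %in% labs]
  missing <- setdiff(classes, present)
  if (length(missing))
    warning("no movements for class: ", paste(missing, collapse = ", "))
  keep <- unlist(lapply(present, function(cl) {
    idx <- which(labs == cl)
    idx[seq_len(min(per_class_cap, length(idx)))]
  }))
  keep <- sort(keep)
  if (!length(keep)) {
    return(structure(list(X = matrix(numeric(0), nrow = 0, ncol = 0),
                          y = factor(character(0), levels = present),
                          per_class_counts = table(factor(character(0),
                                                          levels = present)),
                          params = params),
                     class = "chew_dataset"))
  }
  rows <- lapply(movements[keep], build_instance, params = params)
  X <- do.call(rbind, lapply(rows, function(r) r$attributes))
  y <- factor(vapply(rows, function(r) r$label, character(1)),
              levels = present)
  structure(list(X = X, y = y,
                 per_class_counts = table(y),
                 params = params),
            class = "chew_dataset")
}

#' Construct a dataset from a feature matrix
#'
#' Low-level constructor used by file readers and tests.
#'
#' @param X Numeric matrix, one row per instance.
#' @param y Labels (factor or character).
#' @param params Optional [feature_params()].
#' @return A `chew_dataset`.
#' @export
chew_dataset <- function(X, y, params = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("a", seq_len(ncol(X)))
  if (!is.factor(y)) {
    lev <- intersect(chew_classes(), unique(as.character(y)))
    if (!length(lev)) lev <- sort(unique(as.character(y)))
    else lev <- c(lev, setdiff(sort(unique(as.character(y))), lev))
    y <- factor(as.character(y), levels = lev)
  }
  stopifnot(nrow(X) == length(y))
  structure(list(X = X, y = y, per_class_counts = table(y), params = params),
            class = "chew_dataset")
}

#' @export
print.chew_dataset <- function(x, ...) {
  cat(sprintf("chew dataset: %d instances x %d attributes\n",
              nrow(x$X), ncol(x$X)))
  print(x$per_class_counts)
  invisible(x)
}
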