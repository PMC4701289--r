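#' Segmentation parameters
#'
#' Controls the conversion of a wavelength trace into per-chew movements:
#' the block length of the running per-second mean, the minimum accepted
#' movement duration and the fixed instance length that movements are padded
#' or truncated to.
#'
#' @param block_s Width (s) of the running-mean window (or of the contiguous
#'   blocks when `mean_type = "block"`) used to evaluate the signal average
#'   that is subtracted before crossing detection.
#' @param min_movement_s Minimum duration (s) of an accepted movement; shorter
#'   spans (noise-induced micro-crossings) are dropped.
#' @param target_length Fixed sample count instances are padded/truncated to.
#' @param mean_type `"sliding"` (default) detrends with a centered running
#'   mean of width `block_s`, which varies smoothly and yields exactly one
#'   rising crossing per chew cycle on clean signals; `"block"` detrends with
#'   the piecewise-constant [blockwise_mean()], whose steps at block
#'   boundaries can fabricate crossings mid-cycle.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(block_s = 1,
                                min_movement_s = 0.05,
                                target_length = 1000L,
                                mean_type = c("sliding", "block")) {
  stopifnot(block_s > 0, min_movement_s > 0, target_length >= 1)
  structure(list(block_s = block_s,
                 min_movement_s = min_movement_s,
                 target_length = as.integer(target_length),
                 mean_type = match.arg(mean_type)),
            class = "segmentation_params")
}

#' Blockwise signal mean
#'
#' Evaluates the signal average over contiguous, non-overlapping blocks of
#' `block_s` seconds (the final partial block is averaged over its own
#' samples) and expands the block means back to one value per sample. This
#' piecewise-constant baseline is subtracted from the trace before
#' zero-crossing detection.
#'
#' @param trace A `strain_trace` or `wavelength_trace`.
#' @param block_s Block length in seconds.
#' @return Numeric vector, one baseline value per sample.
#' @export
blockwise_mean <- function(trace, block_s = 1) {
  x <- trace$samples
  if (!length(x)) stop("empty trace")
  block_n <- max(1L, as.integer(round(block_s * trace$sampling_rate_hz)))
  grp <- (seq_along(x) - 1L) %/% block_n
  means <- vapply(split(x, grp), mean, numeric(1))
  unname(means[as.character(grp)])
}

#' Centered running signal mean
#'
#' Mean over a centered window of `block_s` seconds around every sample, with
#' the window clipped at the trace edges. Unlike [blockwise_mean()] this
#' baseline varies smoothly, so subtracting it cannot fabricate crossings at
#' averaging-window boundaries. Windows lying entirely inside a
#' constant-valued stretch return that constant exactly.
#'
#' @inheritParams blockwise_mean
#' @return Numeric vector, one baseline value per sample.
#' @export
sliding_mean <- function(trace, block_s = 1) {
  x <- trace$samples
  n <- length(x)
  if (!n) stop("empty trace")
  w <- max(1L, as.integer(round(block_s * trace$sampling_rate_hz)))
  # anchor at the final sample so that windows fully inside a trailing
  # constant stretch come out exactly constant despite cumsum rounding
  c0 <- x[n]
  cs <- c(0, cumsum(x - c0))
  h1 <- (w - 1L) %/% 2L
  h2 <- w %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h1)
  hi <- pmin(n, i + h2)
  c0 + (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rising zero crossings
#'
#' Indices `i` of a baseline-subtracted series where `x[i - 1] < 0` and
#' `x[i] >= 0` (exact zeros count as non-negative), in increasing order.
#'
#' @param detrended Numeric vector, already baseline-subtracted.
#' @return Integer vector of crossing indices (possibly empty).
#' @export
#' @examples
#' detect_rising_crossings(c(-1, -0.5, 0.2, 1, -1, 0))  # 3 6
detect_rising_crossings <- function(detrended) {
  n <- length(detrended)
  if (n < 2L) return(integer(0))
  which(detrended[-1L] >= 0 & detrended[-n] < 0) + 1L
}

#' Segment a trace into chew movements
#'
#' Implements mean-crossing chew delimitation: the per-second signal mean
#' (a centered running mean by default, see [segmentation_params()]) is
#' subtracted from the trace, each span between consecutive rising zero
#' crossings of the detrended signal becomes one movement, the leading span
#' before the first crossing and the trailing span after the last crossing
#' are discarded, and spans shorter than `min_movement_s` are dropped.
#' Each movement keeps the original (mean-restored) sample values, the
#' baseline mean used in detrending, and the modal per-sample class label
#' (ties broken by earliest class in [chew_classes()] order).
#'
#' @param trace A `wavelength_trace` (or `strain_trace`).
#' @param params A [segmentation_params()].
#' @return List of `chew_movement` objects, each with fields `samples`,
#'   `start_index`, `native_length`, `mean_nm`, `label` and
#'   `sampling_rate_hz`.
#' @export
segment_movements <- function(trace, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  if (is.null(trace$sampling_rate_hz)) stop("trace sampling rate missing")
  x <- trace$samples
  if (!length(x)) return(list())
  baseline <- if (params$mean_type == "sliding") {
    sliding_mean(trace, params$block_s)
  } else {
    blockwise_mean(trace, params$block_s)
  }
  crossings <- detect_rising_crossings(x - baseline)
  if (length(crossings) < 2L) return(list())
  min_n <- params$min_movement_s * trace$sampling_rate_hz
  out <- vector("list", length(crossings) - 1L)
  kept <- 0L
  for (j in seq_len(length(crossings) - 1L)) {
    from <- crossings[j]
    to <- crossings[j + 1L] - 1L
    len <- to - from + 1L
    if (len < min_n) next
    span <- from:to
    kept <- kept + 1L
    out[[kept]] <- structure(list(
      samples = x[span],
      start_index = from,
      native_length = len,
      mean_nm = mean(baseline[span]),
      label = modal_label(trace$labels[span]),
      sampling_rate_hz = trace$sampling_rate_hz
    ), class = "chew_movement")
  }
  out[seq_len(kept)]
}

# Modal label with deterministic ties: earliest class in chew_classes()
# order, then alphabetical for any label outside the canonical set.
modal_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return(NA_character_)
  tab <- table(labels)
  cand <- names(tab)[tab == max(tab)]
  ord <- match(cand, chew_classes())
  ord[is.na(ord)] <- length(chew_classes()) + rank(cand[is.na(ord)])
  cand[which.min(ord)]
}

#' Pad or truncate a movement to a fixed length
#'
#' Movements shorter than `target_length` are extended by appending copies of
#' the movement's baseline mean at the tail; longer movements keep only their
#' first `target_length` samples.
#'
#' @param movement A `chew_movement` (or any list with `samples` and
#'   `mean_nm`).
#' @param target_length Output length in samples.
#' @return Numeric vector of length `target_length`.
#' @export
pad_to_length <- function(movement, target_length = 1000L) {
  if (target_length < 1) stop("target_length must be >= 1")
  x <- movement$samples
  if (!length(x)) stop("empty movement")
  n <- length(x)
  if (n >= target_length) return(x[seq_len(target_length)])
  c(x, rep(movement$mean_nm, target_length - n))
}

#' @export
print.chew_movement <- function(x, ...) {
  cat(sprintf(
    "chew movement '%s': %d native samples from index %d (mean %.6f)\n",
    x$label, x$native_length, x$start_index, x$mean_nm))
  invisible(x)
}
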