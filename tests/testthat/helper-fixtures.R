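# Shared fixtures, all built in code.

# Default profiles with every stochastic element switched off.
noiseless_profiles <- function() {
  lapply(default_profiles(), function(p) {
    p$noise_sd_microstrain <- 0
    p$amplitude_jitter_cv <- 0
    p$period_jitter_cv <- 0
    p
  })
}

# Small balanced zero-noise session trace in wavelength units.
noiseless_session_trace <- function(n_per_class = 10, seed = 3) {
  spec <- session_spec(data.frame(class = chew_classes(), count = n_per_class),
                       seed = seed)
  encode_wavelength(generate_session(spec, noiseless_profiles()))
}

movement_labels <- function(movements) {
  vapply(movements, function(m) m$label, character(1))
}

# Zero-noise single-cycle movement wrapped as a chew_movement record.
clean_movement <- function(class, sampling_rate_hz = 1000) {
  tr <- generate_movement(noiseless_profiles()[[class]], sampling_rate_hz)
  structure(list(samples = tr$samples,
                 start_index = 1L,
                 native_length = length(tr$samples),
                 mean_nm = mean(tr$samples),
                 label = class,
                 sampling_rate_hz = sampling_rate_hz),
            class = "chew_movement")
}

# Independent O(N^2) evaluation of the 1/N-normalized DFT magnitudes.
brute_force_dft_magnitudes <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)) / n)
  }, numeric(1))
}

# Independent exhaustive best-split search mirroring the published contract:
# candidate thresholds at midpoints of consecutive distinct sorted values,
# both branches >= min_leaf, positive gain, optional average-gain guard,
# ties to the lowest attribute index then lowest threshold.
brute_force_best_split <- function(X, y, min_leaf = 2, guard = TRUE) {
  ds <- chew_dataset(X, y)
  cands <- list()
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      nl <- sum(X[, j] <= t)
      if (nl < min_leaf || nrow(X) - nl < min_leaf) next
      s <- evaluate_split(ds, j, t)
      if (!is.null(s) && s$gain > 1e-12) cands[[length(cands) + 1L]] <- s
    }
  }
  if (!length(cands)) return(NULL)
  gains <- vapply(cands, `[[`, numeric(1), "gain")
  eligible <- if (guard) gains >= mean(gains) - 1e-12 else rep(TRUE, length(gains))
  grs <- vapply(cands, `[[`, numeric(1), "gain_ratio")
  grs[!eligible] <- -Inf
  best <- which(grs > max(grs) - 1e-12)[1]
  cands[[best]]
}

# Evaluate one rendered rule string against a named attribute vector.
rule_matches <- function(rule, attrs) {
  lhs <- sub("^IF (.*) THEN .*$", "\\1", rule)
  if (lhs == "TRUE") return(TRUE)
  conds <- strsplit(lhs, " AND ", fixed = TRUE)[[1]]
  all(vapply(conds, function(cond) {
    m <- regmatches(cond, regexec("^\\((a\\d+) (<=|>) (.*)\\)$", cond))[[1]]
    v <- attrs[[m[2]]]
    thr <- as.numeric(m[4])
    if (m[3] == "<=") v <= thr else v > thr
  }, logical(1)))
}
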