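test_that("blockwise mean averages each second and the trailing partial block", {
  fs <- 1000
  expect_equal(blockwise_mean(strain_trace(rep(2.5, 1500), fs)),
               rep(2.5, 1500))
  two <- strain_trace(c(rep(1, 1000), rep(3, 1000)), fs)
  expect_equal(blockwise_mean(two), c(rep(1, 1000), rep(3, 1000)))
  ramp <- strain_trace(seq(0, 1, length.out = 1000), fs)
  expect_equal(blockwise_mean(ramp),
               rep(sum(seq(0, 1, length.out = 1000)) / 1000, 1000))
  # trailing partial block is averaged over its own samples
  part <- strain_trace(c(rep(1, 1000), rep(5, 300)), fs)
  expect_equal(blockwise_mean(part), c(rep(1, 1000), rep(5, 300)))
  expect_error(blockwise_mean(strain_trace(numeric(0), fs)), "empty")
})

test_that("sliding mean matches per-window brute force and is exact on constants", {
  fs <- 100
  set.seed(8)
  x <- cumsum(rnorm(350))
  tr <- strain_trace(x, fs)
  got <- sliding_mean(tr, block_s = 0.5)  # 50-sample window
  w <- 50L; h1 <- (w - 1L) %/% 2L; h2 <- w %/% 2L
  want <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - h1):min(length(x), i + h2)])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  # windows fully inside a constant stretch return the constant exactly
  const <- strain_trace(c(rnorm(120), rep(1541.108, 200)), fs)
  out <- sliding_mean(const, block_s = 0.5)
  expect_identical(out[170:200 + 120], rep(1541.108, 31))
})

test_that("rising crossings match the sign-change definition", {
  expect_identical(detect_rising_crossings(c(1, 2, 3)), integer(0))
  expect_identical(detect_rising_crossings(c(-1, -0.5, 0.2, 1, -1, 0)),
                   c(3L, 6L))
  # exact zeros count as non-negative
  expect_identical(detect_rising_crossings(c(-1, 0, -1, 0.5)), c(2L, 4L))
  t <- (0:2199) / 1000
  cr <- detect_rising_crossings(sin(2 * pi * 2 * t))
  expect_true(all(abs(diff(cr) - 500) <= 1))
  off <- (cr - 1) %% 500
  expect_true(all(pmin(off, 500 - off) <= 1))
  # sign flip turns rising crossings into falling crossings of the original
  set.seed(2)
  x <- rnorm(400)
  falling <- which(x[-400] > 0 & x[-1] <= 0) + 1L
  expect_identical(detect_rising_crossings(-x), falling)
})

test_that("a pure tone over an offset splits into whole-period movements", {
  # small negative phase lead so the first rising crossing is observable
  t <- (0:2199) / 1000
  tr <- wavelength_trace(5 + sin(2 * pi * 2 * t - 0.1), 1000)
  for (mt in c("sliding", "block")) {
    mv <- segment_movements(tr, segmentation_params(mean_type = mt))
    expect_length(mv, 4)
    lens <- vapply(mv, `[[`, numeric(1), "native_length")
    expect_true(all(abs(lens[1:3] - 500) <= 2), info = mt)
    # the final span absorbs the edge bias of the shortened averaging window
    expect_lt(abs(lens[4] - 500), 0.15 * 500)
  }
  expect_length(segment_movements(wavelength_trace(rep(7, 3000), 1000)), 0)
})

test_that("zero-noise sessions are recovered movement for movement", {
  for (seed in c(3, 17)) {
    tr <- noiseless_session_trace(n_per_class = 10, seed = seed)
    mv <- segment_movements(tr)
    tab <- table(factor(movement_labels(mv), levels = chew_classes()))
    expect_true(all(tab == 10), info = paste("seed", seed))
    # spans are disjoint and ordered
    starts <- vapply(mv, `[[`, numeric(1), "start_index")
    lens <- vapply(mv, `[[`, numeric(1), "native_length")
    expect_true(all(diff(starts) >= lens[-length(lens)]))
  }
})

test_that("movement boundaries equal an exhaustive per-sample sign scan", {
  tr <- noiseless_session_trace(n_per_class = 5, seed = 21)
  params <- segmentation_params()
  baseline <- sliding_mean(tr, params$block_s)
  det <- tr$samples - baseline
  scan <- integer(0)  # brute-force loop over adjacent sample pairs
  for (i in 2:length(det))
    if (det[i - 1] < 0 && det[i] >= 0) scan <- c(scan, i)
  mv <- segment_movements(tr, params)
  starts <- vapply(mv, `[[`, numeric(1), "start_index")
  expect_true(all(starts %in% scan))
  ends <- starts + vapply(mv, `[[`, numeric(1), "native_length")
  expect_true(all(ends %in% scan))
})

test_that("movements keep original values and the detrending mean", {
  tr <- noiseless_session_trace(n_per_class = 4, seed = 5)
  baseline <- sliding_mean(tr, 1)
  mv <- segment_movements(tr)
  for (m in mv[1:3]) {
    span <- m$start_index:(m$start_index + m$native_length - 1)
    expect_identical(m$samples, tr$samples[span])
    expect_equal(m$mean_nm, mean(baseline[span]))
  }
})

test_that("segmented labels agree with the generating class under noise", {
  spec <- session_spec(data.frame(class = chew_classes(), count = 20),
                       seed = 6)
  tr <- encode_wavelength(generate_session(spec))
  mv <- segment_movements(tr)
  tab <- table(factor(movement_labels(mv), levels = chew_classes()))
  expect_true(all(tab >= 20))          # fragmentation never loses a class
  # every movement's label matches the class generating its samples
  ok <- vapply(mv, function(m) {
    span <- m$start_index:(m$start_index + m$native_length - 1)
    mean(tr$labels[span] == m$label) > 0.5
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("padding appends the mean, truncates long segments and is idempotent", {
  m <- structure(list(samples = rep(1541.2, 600), mean_nm = 1541.05),
                 class = "chew_movement")
  padded <- pad_to_length(m, 1000)
  expect_length(padded, 1000)
  expect_identical(padded[601:1000], rep(1541.05, 400))
  expect_identical(padded[1:600], rep(1541.2, 600))
  # exact-length and over-length inputs
  exact <- structure(list(samples = rnorm(1000), mean_nm = 0),
                     class = "chew_movement")
  expect_identical(pad_to_length(exact, 1000), exact$samples)
  long <- structure(list(samples = seq_len(1200) / 7, mean_nm = 0),
                    class = "chew_movement")
  expect_identical(pad_to_length(long, 1000), (seq_len(1000)) / 7)
  # idempotence
  repad <- structure(list(samples = padded, mean_nm = 1541.05),
                     class = "chew_movement")
  expect_identical(pad_to_length(repad, 1000), padded)
  expect_error(pad_to_length(m, 0), "target_length")
})
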