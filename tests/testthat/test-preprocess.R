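make_rec <- function(samples, srate, labels = NULL, annotations = NULL) {
  if (is.null(labels)) {
    labels <- paste0("ch", seq_len(if (is.matrix(samples)) nrow(samples) else 1))
  }
  if (is.null(annotations)) {
    annotations <- tibble::tibble(onset = numeric(), duration = numeric(),
                                  trial = integer(), slot = integer(),
                                  step_index = integer(), step_value = numeric(),
                                  phase = character(), condition = character(),
                                  direction = character())
  }
  structure(list(labels = labels, srate = srate,
                 samples = matrix(samples, nrow = length(labels),
                                  dimnames = list(labels, NULL)),
                 annotations = annotations,
                 montage = tibble::tibble(electrode = labels,
                                          x = seq_along(labels), y = 0)),
            class = "eeg_recording")
}

test_that("downsampling preserves constants and 20 Hz amplitude", {
  rec <- make_rec(rep(2, 2048 * 4), 2048)
  out <- downsample(rec, 250)
  expect_equal(out$srate, 250)
  mid <- out$samples[1, 100:900]
  expect_true(all(abs(mid - 2) < 1e-6))

  t <- seq(0, 4 - 1 / 2048, by = 1 / 2048)
  rec2 <- make_rec(3 * sin(2 * pi * 20 * t), 2048)
  out2 <- downsample(rec2, 250)
  # amplitude from an interior 1-s window (edges carry filter transients)
  amp <- dft_bin(out2$samples[1, 251:500], 250, 20)$amplitude
  expect_equal(amp, 3, tolerance = 0.01)

  expect_error(downsample(rec, 0), "positive")
  expect_error(downsample(rec, 5000), "exceeds")
})

test_that("detrending removes ramps; the low-pass keeps 20 Hz and kills 60 Hz", {
  ramp <- make_rec(seq(-5, 5, length.out = 1000), 250)
  out <- detrend_lowpass(ramp, 45)
  expect_lt(max(abs(out$samples)), 1e-6)

  t <- seq(0, 4 - 1 / 250, by = 1 / 250)
  s20 <- make_rec(sin(2 * pi * 20 * t), 250)
  a20 <- dft_bin(detrend_lowpass(s20, 45)$samples[1, 501:750], 250, 20)$amplitude
  expect_equal(a20, 1, tolerance = 0.01)

  s60 <- make_rec(sin(2 * pi * 60 * t), 250)
  a60 <- dft_bin(detrend_lowpass(s60, 45)$samples[1, 501:750], 250, 60)$amplitude
  expect_lt(20 * log10(a60 / 1), -20)   # at least 20 dB down

  expect_error(detrend_lowpass(s20, 200), "Nyquist")
})

test_that("filter and resampler commute for band-limited signals", {
  t <- seq(0, 4 - 1 / 1000, by = 1 / 1000)
  sig <- 2 * sin(2 * pi * 20 * t) + sin(2 * pi * 7 * t)
  rec <- make_rec(sig, 1000)
  a <- detrend_lowpass(downsample(rec, 250), 45)
  b <- downsample(detrend_lowpass(rec, 45), 250)
  amp_a <- dft_bin(a$samples[1, 401:650], 250, 20)$amplitude
  amp_b <- dft_bin(b$samples[1, 401:650], 250, 20)$amplitude
  expect_equal(amp_a, amp_b, tolerance = 0.02 * amp_a)
})

test_that("epoching keeps exactly the core steps", {
  rec <- quick_recording(n_trials = 6, seed = 2)
  ep <- epoch(rec)
  expect_equal(dim(ep$data)[3], 6 * 18)
  expect_equal(dim(ep$data)[2], rec$srate)   # 1-s epochs
  # each trial contributes 18 core epochs out of its 20 presented slots
  expect_equal(as.integer(table(ep$index$trial)), rep(18L, 6))
  # empty recording -> empty epoch set
  empty <- make_rec(numeric(0), 250, labels = "ch1")
  ep0 <- epoch(empty)
  expect_equal(dim(ep0$data)[3], 0)
})

test_that("peak-to-peak rejection flags only offending epochs and keeps count", {
  ep <- quick_epochs(noise = noise_model(white_sd = 0, pink_scale = 0),
                     n_trials = 1)
  expect_equal(nrow(reject_epochs(ep, 150)$rejected), 0)
  # plant a 500 uV spike in one known epoch
  ep$data["Cz", 10, 4] <- 500
  out <- reject_epochs(ep, 150)
  expect_equal(nrow(out$rejected), 1)
  expect_equal(out$rejected$step_index, ep$index$step_index[4])
  expect_match(out$rejected$reason, "peak-to-peak")
  # bookkeeping: retained + rejected constant
  expect_equal(dim(out$data)[3] + nrow(out$rejected), dim(ep$data)[3])
  # infinite limit is the identity
  expect_equal(dim(reject_epochs(ep, Inf)$data)[3], dim(ep$data)[3])
})

test_that("re-referencing schemes do what they claim", {
  ep <- quick_epochs(n_trials = 1, seed = 9)
  # occipital electrodes carrying identical copies become zero
  occ <- occipital_set()
  idx <- match(occ, ep$labels)
  for (i in seq_len(dim(ep$data)[3])) {
    for (j in idx) ep$data[j, , i] <- ep$data[idx[1], , i]
  }
  out <- rereference(ep, "occipital_mean")
  expect_lt(max(abs(out$data[idx, , ])), 1e-12)
  expect_equal(out$reference, "occipital_mean")

  # common average: channel mean is zero at every sample
  ca <- rereference(quick_epochs(n_trials = 1, seed = 9), "common_average")
  mean_trace <- apply(ca$data, c(2, 3), mean)
  expect_lt(max(abs(mean_trace)), 1e-10)

  # single-electrode reference zeroes that electrode
  se <- rereference(quick_epochs(n_trials = 1, seed = 9), "single:Fpz")
  expect_lt(max(abs(se$data["Fpz", , ])), 1e-12)

  expect_error(rereference(ep, "single:XX9"), "XX9")
  # idempotence of the occipital mean
  once <- rereference(quick_epochs(n_trials = 1, seed = 3), "occipital_mean")
  twice <- rereference(once, "occipital_mean")
  expect_equal(once$data, twice$data, tolerance = 1e-12)
})

test_that("bad-channel interpolation uses nearby neighbours", {
  ep <- quick_epochs(n_trials = 1, seed = 4)
  # make every channel except Pz a copy of one signal; Pz must become it
  base <- ep$data["Oz", , 1]
  for (i in seq_len(dim(ep$data)[3])) {
    for (ch in seq_along(ep$labels)) ep$data[ch, , i] <- ep$data["Oz", , i]
  }
  out <- interpolate_channels(ep, "Pz")
  expect_equal(out$data["Pz", , 1], ep$data["Oz", , 1], tolerance = 1e-10)
  # empty bad list is the identity
  expect_identical(interpolate_channels(ep, character(0)), ep)
  expect_error(interpolate_channels(ep, ep$labels), "too many")
  expect_error(interpolate_channels(ep, "nope"), "unknown")
})

test_that("recordings round-trip through the columnar text format", {
  rec <- quick_recording(n_trials = 1, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- load_recording(path)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$srate, rec$srate)
  expect_equal(unname(back$samples), unname(rec$samples), tolerance = 1e-6)
  expect_equal(nrow(back$annotations), nrow(rec$annotations))
  expect_equal(back$annotations$onset, rec$annotations$onset)
  # simulator annotations: trials x 20 slots
  expect_equal(nrow(back$annotations), 20)

  # duplicate labels are a parse error
  writeLines(c("# sweepvep columnar recording v1", "# srate=250",
               "A\tA", "1\t2"), path)
  file.copy(path, annotation_path <- paste0(path, ".annotations.csv"))
  expect_error(load_recording(path), "duplicate")
  expect_error(load_recording("/nonexistent/file.tsv"), "no such")
})
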