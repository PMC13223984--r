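test_that("single-bin DFT recovers amplitude and phase analytically", {
  t <- seq(0, 1 - 1 / 250, by = 1 / 250)
  r <- dft_bin(3 * sin(2 * pi * 20 * t), 250, 20)
  expect_equal(r$amplitude, 3, tolerance = 1e-9)
  expect_equal(r$phase, 0, tolerance = 1e-9)

  r2 <- dft_bin(3 * sin(2 * pi * 20 * t + pi / 4), 250, 20)
  expect_equal(r2$amplitude, 3, tolerance = 1e-9)
  expect_equal(r2$phase, pi / 4, tolerance = 1e-9)

  # constant waveform has nothing at 20 Hz
  expect_equal(dft_bin(rep(5, 250), 250, 20)$amplitude, 0, tolerance = 1e-12)

  # phase convention stays in (-pi, pi]
  r3 <- dft_bin(sin(2 * pi * 20 * t + 3), 250, 20)
  expect_equal(r3$phase, 3, tolerance = 1e-9)
  r4 <- dft_bin(sin(2 * pi * 20 * t - 3), 250, 20)
  expect_equal(r4$phase, -3, tolerance = 1e-9)

  expect_error(dft_bin(t, 250, 20.5), "bin grid")
  expect_error(dft_bin(t[1:100], 250, 20), "samples")
})

test_that("single-bin DFT matches a direct-summation full transform", {
  set.seed(11)
  for (srate in c(100, 250)) {
    x <- rnorm(srate)
    # brute-force DFT by direct summation
    brute <- function(k) {
      n <- length(x)
      re <- sum(x * cos(2 * pi * k * (0:(n - 1)) / n))
      im <- -sum(x * sin(2 * pi * k * (0:(n - 1)) / n))
      2 * sqrt(re^2 + im^2) / n
    }
    for (f in c(7, 20, 31)) {
      expect_equal(dft_bin(x, srate, f)$amplitude, brute(f), tolerance = 1e-9)
    }
  }
})

test_that("noise floor uses the 12 neighbours, skipping adjacent bins", {
  cfg <- spectrum_config()
  expect_equal(noise_bins(cfg), c(13:18, 22:27))
  spec <- tibble::tibble(freq = 0:125, amplitude = 0)
  spec$amplitude[spec$freq %in% c(13:18)] <- 1
  spec$amplitude[spec$freq %in% c(22:27)] <- 3
  nf <- noise_floor(spec, cfg)
  expect_equal(nf$noise_mean, 2)
  expect_equal(nf$noise_sd, sd(rep(c(1, 3), each = 6)))

  # all neighbours equal: sd 0 -> degenerate, flagged downstream
  spec2 <- tibble::tibble(freq = 0:125, amplitude = 2)
  nf2 <- noise_floor(spec2, cfg)
  expect_equal(nf2$noise_mean, 2)
  expect_equal(nf2$noise_sd, 0)

  # bins out of range
  spec3 <- tibble::tibble(freq = 0:20, amplitude = 1)
  expect_error(noise_floor(spec3, cfg), "outside")
})

test_that("white-noise spectra give near-zero adjusted amplitude on average", {
  set.seed(21)
  n_rep <- 300
  adj <- replicate(n_rep, {
    x <- rnorm(250)
    spec <- amplitude_spectrum(x, 250)
    nf <- noise_floor(spec)
    dft_bin(x, 250, 20)$amplitude - nf$noise_mean
  })
  expect_lt(abs(mean(adj)), 3 * sd(adj) / sqrt(n_rep))
})

test_that("spectral table arithmetic and degenerate flags are right", {
  # trial averaging: identical epochs average to themselves, s and -s cancel
  ep <- quick_epochs(noise = noise_model(white_sd = 0, pink_scale = 0),
                     n_trials = 2)
  av <- trial_average(ep)
  expect_equal(av$index$n_epochs, rep(2L, 18))
  expect_equal(av$data[, , 10],
               ep$data[, , which(ep$index$step_index == 10)[1]],
               tolerance = 1e-12)
  ep$data[, , ep$index$step_index == 10][, , 2] <-
    -ep$data[, , which(ep$index$step_index == 10)[1]]
  av2 <- trial_average(ep)
  expect_lt(max(abs(av2$data[, , 10])), 1e-12)

  # random-phase averaging never beats the single-trial amplitude
  set.seed(5)
  t <- seq(0, 1 - 1 / 250, by = 1 / 250)
  phases <- runif(8, -pi, pi)
  waves <- sapply(phases, function(p) sin(2 * pi * 20 * t + p))
  avg_amp <- dft_bin(rowMeans(waves), 250, 20)$amplitude
  expect_lte(avg_amp, 1 + 1e-9)

  # z / snr arithmetic on a constructed spectrum
  x <- 10 * sin(2 * pi * 20 * t)
  nb <- noise_bins(spectrum_config())
  for (i in seq_along(nb)) {
    x <- x + (2 + (i %% 2 == 0)) * sin(2 * pi * nb[i] * t + i)
  }
  spec <- amplitude_spectrum(x, 250)
  nf <- noise_floor(spec)
  amp <- dft_bin(x, 250, 20)$amplitude
  expect_equal(amp - nf$noise_mean, 10 - 2.5, tolerance = 1e-9)
  expect_equal(amp / nf$noise_mean, 4, tolerance = 1e-9)

  # noiseless subthreshold steps are all-zero waveforms: noise sd is
  # exactly 0, so z is undefined and the row is flagged
  tab <- build_spectral_table(quick_epochs(
    noise = noise_model(white_sd = 0, pink_scale = 0), n_trials = 1))
  sub_thr <- tab[tab$electrode == "Oz" & tab$step_value < 0.8, ]
  expect_true(all(is.na(sub_thr$z)))
  expect_true(all(sub_thr$flagged))
  supra <- tab[tab$electrode == "Oz" & tab$step_value > 0.8, ]
  expect_equal(supra$adj_amp, supra$amp - supra$noise_mean)
})

test_that("spectral measures are linear in signal scale; z and snr are not", {
  ep <- quick_epochs(n_trials = 2, seed = 14)
  tab1 <- build_spectral_table(ep)
  ep$data <- ep$data * 3.7
  tab2 <- build_spectral_table(ep)
  for (col in c("amp", "noise_mean", "noise_sd", "adj_amp")) {
    expect_equal(tab2[[col]], tab1[[col]] * 3.7, tolerance = 1e-9)
  }
  expect_equal(tab2$z, tab1$z, tolerance = 1e-9)
  expect_equal(tab2$snr, tab1$snr, tolerance = 1e-9)
})

test_that("pooled periodogram peaks at 20 Hz for suprathreshold sweeps", {
  peaks <- sapply(1:3, function(s) {
    ep <- quick_epochs(true_threshold = 0.2, n_trials = 2, seed = s,
                       srate = 250)
    pg <- pooled_periodogram(ep, "Oz", reference = "single:Fpz")
    pg$freq[pg$freq > 0][which.max(pg$power[pg$freq > 0])]
  })
  expect_true(all(peaks == 20))
  # harmonic shows as a secondary local peak at 40 Hz
  ep <- quick_epochs(true_threshold = 0.2, n_trials = 2, seed = 1,
                     srate = 250, harmonic_ratio = 0.3)
  pg <- pooled_periodogram(ep, "Oz")
  p40 <- pg$power[pg$freq == 40]
  expect_gt(p40, pg$power[pg$freq == 38])
  expect_gt(p40, pg$power[pg$freq == 42])
  expect_error(pooled_periodogram(ep, "XX1"), "not present")
})

test_that("topography arrays follow montage order and peak at Oz", {
  ep <- quick_epochs(true_threshold = 0.2, n_trials = 2, seed = 6)
  tab <- build_spectral_table(ep)
  topo <- topography_array(tab, "contrast", "increasing", 18,
                           montage = small_montage())
  expect_equal(topo$electrode, small_montage()$electrode)
  expect_equal(topo$electrode[which.max(topo$adj_amp)], "Oz")
  expect_error(topography_array(tab, "contrast", "increasing", 99),
               "no spectral rows")
  expect_error(topography_array(tab, "contrast", "increasing", 18),
               "missing electrode")   # default montage wants all 64
})
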