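test_that("significance mask is a strict comparison with NA as FALSE", {
  expect_equal(significance_mask(c(2.33, 10, NA, 1), 2.33),
               c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(significance_mask(rep(10, 18))))
  expect_equal(significance_mask(c(1, 1, 3, 1, 3, 3, 3, 3), 2.33),
               c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("Sig rule hand traces: decreasing takes the last candidate, increasing the first", {
  # decreasing-intensity sweep: significant run then silence from step 6
  dec <- make_sweep_design("contrast", "decreasing")
  mask <- c(rep(TRUE, 5), rep(FALSE, 13))
  res <- sig_threshold(mask, dec)
  # candidates: step 6 (4/4 preceding significant) and step 7 (3/4); last wins
  expect_equal(res$step_index, 7L)
  expect_equal(res$threshold_value, design_steps(dec)[7])
  expect_true(res$valid)

  # increasing-intensity sweep: silence then significance from step 6
  inc <- make_sweep_design("contrast", "increasing")
  mask_i <- c(rep(FALSE, 5), rep(TRUE, 13))
  res_i <- sig_threshold(mask_i, inc)
  # candidates: step 6 (4/4 preceding non-significant) and step 7 (3/4); first wins
  expect_equal(res_i$step_index, 6L)
  expect_equal(res_i$threshold_value, design_steps(inc)[6])

  # an SF parameter-increasing sweep is a decreasing-intensity sweep
  sf <- make_sweep_design("spatial_frequency", "increasing")
  res_sf <- sig_threshold(mask, sf)
  expect_equal(res_sf$step_index, 7L)

  # all-false mask: no threshold
  none <- sig_threshold(rep(FALSE, 18), dec)
  expect_false(none$valid)
  expect_true(is.na(none$threshold_value))
  expect_match(none$reason, "no qualifying")

  expect_error(sig_threshold(rep(TRUE, 10), dec), "does not match")
})

test_that("the swapped rule reading differs only in the increasing pick", {
  inc <- make_sweep_design("contrast", "increasing")
  # two separated candidate transitions
  mask <- c(rep(FALSE, 5), TRUE, TRUE, FALSE, FALSE, FALSE, rep(TRUE, 8))
  mirrored <- sig_threshold(mask, inc, selection_config(sig_rule = "mirrored"))
  swapped <- sig_threshold(mask, inc, selection_config(sig_rule = "swapped"))
  expect_lt(mirrored$step_index, swapped$step_index)
  dec <- make_sweep_design("contrast", "decreasing")
  mask_d <- c(rep(TRUE, 5), rep(FALSE, 13))
  expect_equal(sig_threshold(mask_d, dec,
                             selection_config(sig_rule = "swapped"))$step_index,
               sig_threshold(mask_d, dec)$step_index)
})

test_that("raising the criterion never eases the increasing-sweep threshold", {
  inc <- make_sweep_design("contrast", "increasing")
  set.seed(77)
  for (i in 1:200) {
    # monotone z profiles: a clean response growing through the sweep
    z <- sort(c(rnorm(9, 0, 1.5), rnorm(9, 5, 1.5)))
    lo <- sig_threshold(significance_mask(z, 2.0), inc)
    hi <- sig_threshold(significance_mask(z, 3.0), inc)
    if (isTRUE(lo$valid) && isTRUE(hi$valid)) {
      expect_gte(hi$step_index, lo$step_index)
    }
  }
})

test_that("electrode selection maximises easy-half mean z with ordered tie-break", {
  ep <- quick_epochs(true_threshold = 0.4, n_trials = 2, seed = 12)
  tab <- build_spectral_table(rereference(ep))
  expect_equal(select_electrode(tab), "Oz")

  # hand-built table: tie between two electrodes resolves to first in order
  base <- linear_spectral_rows(make_sweep_design("contrast", "increasing"))
  other <- dplyr::mutate(base, electrode = "POz")
  tied <- dplyr::bind_rows(base, other)   # Oz rows first
  expect_equal(select_electrode(tied), "Oz")
  expect_equal(select_electrode(dplyr::bind_rows(other, base)), "POz")
  expect_equal(select_electrode(other), "POz")

  und <- dplyr::mutate(base, z = NA_real_)
  expect_error(select_electrode(und), "undefined")
  expect_error(select_electrode(dplyr::mutate(base, condition = "x")),
               "single condition|easy-half")
})

test_that("Reg method recovers a constructed linear threshold exactly", {
  d <- make_sweep_design("contrast", "increasing")
  rows <- linear_spectral_rows(d, slope = 2, crossing = -0.5)
  res <- reg_threshold(rows, d)
  expect_true(res$valid)
  expect_equal(res$threshold_value, 10^(-0.5), tolerance = 1e-6)
  dg <- attr(res, "diagnostics")
  expect_gt(dg$slope, 0)

  # same construction on the decreasing design
  dd <- make_sweep_design("contrast", "decreasing")
  rows_d <- linear_spectral_rows(dd, slope = 2, crossing = -0.5)
  res_d <- reg_threshold(rows_d, dd)
  expect_equal(res_d$threshold_value, 10^(-0.5), tolerance = 1e-6)

  # spatial frequency: linear axis in cpd, threshold where the line hits zero
  sf <- make_sweep_design("spatial_frequency", "increasing")
  rows_sf <- linear_spectral_rows(sf, slope = 0.4, crossing = 30)
  res_sf <- reg_threshold(rows_sf, sf)
  expect_true(res_sf$valid)
  expect_equal(res_sf$threshold_value, 30, tolerance = 1e-6)
})

test_that("Reg method fails loudly without onset, with wrong slope or bad phase", {
  d <- make_sweep_design("contrast", "increasing")
  rows <- linear_spectral_rows(d)
  low <- dplyr::mutate(rows, snr = 2)
  r1 <- reg_threshold(low, d)
  expect_false(r1$valid)
  expect_match(r1$reason, "no-onset")

  # amplitude rising towards harder stimuli: wrong sign
  flipped <- dplyr::mutate(rows, amp = rev(amp), snr = rev(snr))
  r2 <- reg_threshold(flipped, d)
  expect_false(r2$valid)

  # phase drifting beyond tolerance on a contrast sweep (lagging)
  lag <- dplyr::mutate(rows,
                       phase = 0.3 - 0.5 * (18 - dplyr::row_number()))
  r3 <- reg_threshold(lag, d)
  expect_false(r3$valid)
  expect_match(r3$reason, "phase")
})

test_that("phase validity encodes leading/lagging per condition", {
  same <- rep(1.2, 6)
  for (cond in c("contrast", "spatial_frequency", "orientation")) {
    expect_true(phase_check(same, cond))
  }
  leading <- 1 + (0:5) * pi / 8
  expect_true(phase_check(leading, "contrast"))
  expect_false(phase_check(leading, "spatial_frequency"))
  expect_false(phase_check(leading, "orientation"))
  lagging <- 1 - (0:5) * pi / 8
  expect_false(phase_check(lagging, "contrast"))
  expect_true(phase_check(lagging, "spatial_frequency"))
  alternating <- rep(c(pi, 0), 3)
  expect_false(phase_check(alternating, "contrast"))
  # wrap-around phases unwrap before checking
  wrapped <- c(3.1, -3.1, 3.05, -3.12)
  expect_true(phase_check(wrapped, "orientation", tolerance = pi / 4))
})

test_that("direction scores combine on the condition's spacing scale", {
  inc <- sig_threshold(c(rep(FALSE, 7), rep(TRUE, 11)),
                       make_sweep_design("contrast", "increasing"))
  dec <- sig_threshold(c(rep(TRUE, 7), rep(FALSE, 11)),
                       make_sweep_design("contrast", "decreasing"))
  manual_inc <- inc$threshold_value
  manual_dec <- dec$threshold_value
  comb <- combine_directions(inc, dec)
  expect_equal(comb$score, sqrt(manual_inc * manual_dec))
  expect_false(comb$flagged)

  # geometric mean example: 1% and 4% combine to 2%
  a <- inc; a$threshold_value <- 1
  b <- dec; b$threshold_value <- 4
  expect_equal(combine_directions(a, b)$score, 2)

  # spatial frequency combines arithmetically
  sfi <- sig_threshold(c(rep(TRUE, 7), rep(FALSE, 11)),
                       make_sweep_design("spatial_frequency", "increasing"))
  sfd <- sig_threshold(c(rep(FALSE, 7), rep(TRUE, 11)),
                       make_sweep_design("spatial_frequency", "decreasing"))
  expect_equal(combine_directions(sfi, sfd)$score,
               mean(c(sfi$threshold_value, sfd$threshold_value)))

  # one invalid: passthrough, flagged; both invalid: undefined
  bad <- dec; bad$valid <- FALSE
  one <- combine_directions(inc, bad)
  expect_equal(one$score, inc$threshold_value)
  expect_true(one$flagged)
  bad2 <- inc; bad2$valid <- FALSE
  expect_true(is.na(combine_directions(bad2, bad)$score))
})
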