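test_that("band-pass filter has the designed pass/stop behavior", {
  b <- design_bandpass_fir(1, 32, 2000, 1000)
  # linear phase: impulse response symmetric to machine precision
  expect_lt(max(abs(b - rev(b))), 1e-14)
  # frequency response at 10 Hz (passband), 40 Hz (stopband), 0 Hz (DC)
  hgain <- function(f) Mod(sum(b * exp(-2i * pi * f * (seq_along(b) - 1) / 1000)))
  expect_equal(hgain(10), 1, tolerance = 0.01)
  expect_lt(20 * log10(hgain(40)), -40)
  expect_lt(hgain(0), 0.01)
})

test_that("filtering a recording passes 10 Hz, removes DC and 40 Hz", {
  rec <- make_sine_recording(c(10, 40), c(1, 1), dc = 100, dur = 60,
                             srate = 1000)
  out <- bandpass_fir(rec, 1, 32, order = 2000, pad = 2)
  mid <- 5000:25000  # interior of first block
  y <- out$data[1, mid]
  t <- (mid - 1) / 1000
  amp10 <- 2 * abs(mean(y * exp(-2i * pi * 10 * t)))
  amp40 <- 2 * abs(mean(y * exp(-2i * pi * 40 * t)))
  expect_equal(amp10, 1, tolerance = 0.01)
  expect_lt(amp40, 0.01)
  # the 100 uV DC offset is attenuated by at least two orders of magnitude
  expect_lt(abs(mean(y)), 1)
})

test_that("filter errors on blocks too short for the padded kernel", {
  rec <- make_sine_recording(10, dur = 4, srate = 250)  # 2 s blocks
  expect_error(bandpass_fir(rec, 1, 32, order = 2000, pad = 2), "block")
})

test_that("resampling preserves duration and tone amplitude", {
  rec <- make_sine_recording(5, dur = 30, srate = 2048)
  rec$blocks <- data.frame(condition = "EO", start = 0, duration = 30)
  out <- resample_recording(rec, 1000)
  expect_lte(abs(ncol(out$data) - 30000), 1)
  expect_equal(out$srate, 1000)
  t <- (5000:25000 - 1) / 1000
  amp <- 2 * abs(mean(out$data[1, 5000:25000] * exp(-2i * pi * 5 * t)))
  expect_equal(amp, 1, tolerance = 0.01)
  expect_identical(resample_recording(rec, 2048), rec)
})

test_that("epoching tiles blocks, skips masked intervals, keeps labels", {
  rec <- make_sine_recording(10, dur = 240)  # 120 s EO + 120 s EC
  ep <- epoch_recording(rec, 2.5)
  expect_equal(unname(count_epochs(ep)), c(48, 48))
  # 30 s block with first 5 s masked -> 10 epochs starting at 5 s
  rec2 <- make_sine_recording(10, dur = 60)
  rec2$blocks <- data.frame(condition = "EO", start = 0, duration = 30)
  rec2$data <- rec2$data[, 1:(30 * fs_test), drop = FALSE]
  ep2 <- epoch_recording(rec2, 2.5,
                         artifact_mask = data.frame(onset = 0, duration = 5))
  expect_equal(length(ep2$condition), 10)
  expect_equal(ep2$starts[1], 5)
  expect_warning(
    epoch_recording(rec2, 2.5,
                    artifact_mask = data.frame(onset = 0, duration = 30)),
    "no clean epochs")
})

test_that("epoching then concatenating reproduces the unmasked samples", {
  rec <- make_sine_recording(7, dur = 10)
  rec$blocks <- data.frame(condition = "EO", start = 0, duration = 10)
  ep <- epoch_recording(rec, 2.5)
  recon <- do.call(cbind, lapply(seq_len(4), function(e) ep$data[, , e]))
  expect_identical(recon, rec$data[, 1:(10 * fs_test)])
})

test_that("average reference zeroes the channel mean and is idempotent", {
  ep <- make_noise_epochs(n_ch = 5, n_ep = 4)
  ep$data[3, , ] <- ep$data[3, , ] + 50  # constant channel offset
  out <- average_reference(ep)
  for (e in 1:4)
    expect_lt(max(abs(colMeans(out$data[, , e]))), 1e-10)
  out2 <- average_reference(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
})

test_that("inclusion criteria match the three exclusion rules", {
  ep_ok <- make_noise_epochs(n_ep = 40, cond = rep(c("EO", "EC"), 20))
  ep_few <- make_noise_epochs(n_ep = 29, cond = c(rep("EO", 14), rep("EC", 15)))
  r1 <- inclusion_check(ep_few, 61, 0, 0, 61)
  expect_false(r1$included)
  expect_identical(r1$reasons, "epochs")
  # good - ICs = 36 >= 35 passes criterion 3
  r2 <- inclusion_check(ep_ok, 61, 0, 4, 40)
  expect_true(r2$included)
  expect_equal(r2$n_good_minus_ics, 36)
  r3 <- inclusion_check(ep_ok, 50, 0, 0, 61)
  expect_false(r3$included)
  expect_identical(r3$reasons, "channels")
  r4 <- inclusion_check(ep_ok, 61, 4, 0, 61)
  expect_false(r4$included)
  # pure function: same inputs, same report
  expect_identical(inclusion_check(ep_ok, 61, 0, 4, 40), r2)
})

test_that("largest neighboring-bad-channel group uses graph components", {
  adj <- matrix(FALSE, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  adj[cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))] <- TRUE
  adj <- adj | t(adj)
  expect_equal(max_adjacent_bad(c("a", "b", "d"), adj), 2)
  expect_equal(max_adjacent_bad(c("a", "c", "e"), adj), 1)
  expect_equal(max_adjacent_bad(character(0), adj), 0)
})
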