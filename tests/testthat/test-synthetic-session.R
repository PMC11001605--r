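# Cohort generator: schedule constraints, determinism, label rates and the
# spectral structure of the background activity.

test_that("fixed seed reproduces a session bit-identically; participants differ", {
  spec <- cohort_spec(n_participants = 2, n_blocks = 1, block_duration = 120,
                      sampling_rate = 128, n_channels = 4,
                      channel_labels = c("FP1", "F3", "C3", "O1"), seed = 9)
  m <- signal_model()
  s1 <- generate_session(spec, m, "S01")
  s2 <- generate_session(spec, m, "S01")
  expect_identical(s1$signal, s2$signal)
  expect_identical(s1$probes, s2$probes)
  s3 <- generate_session(spec, m, "S02")
  expect_false(isTRUE(all.equal(s1$signal, s3$signal)))
})

test_that("signal shape follows the recording geometry", {
  spec <- cohort_spec(n_participants = 1, n_blocks = 1, block_duration = 60,
                      sampling_rate = 1024, n_channels = 30, seed = 3)
  s <- generate_session(spec, signal_model(), "S01")
  expect_equal(dim(s$signal), c(30, 61440))
})

test_that("a block too short for one probe is rejected", {
  spec <- cohort_spec(n_participants = 1, n_blocks = 1, block_duration = 30,
                      sampling_rate = 64, n_channels = 2,
                      channel_labels = c("FP1", "O1"), seed = 1)
  expect_error(generate_session(spec, signal_model(), "S01"), "too short")
})

test_that("probe schedules respect the gap and the manual cap", {
  spec <- cohort_spec(n_participants = 6, n_blocks = 5, block_duration = 400,
                      sampling_rate = 32, n_channels = 2,
                      channel_labels = c("FP1", "O1"), seed = 21)
  coh <- generate_cohort(spec, signal_model())
  expect_length(coh, 6)
  for (s in coh) {
    for (b in unique(s$probes$block)) {
      pb <- s$probes[s$probes$block == b, ]
      expect_true(all(diff(pb$time_s) >= spec$min_probe_gap - 1e-9))
      expect_lte(sum(pb$trigger == "manual"), spec$manual_probe_cap_per_block)
    }
  }
})

test_that("MW response rate converges to the configured rate", {
  spec <- cohort_spec(n_participants = 30, n_blocks = 5, block_duration = 400,
                      sampling_rate = 32, n_channels = 2,
                      channel_labels = c("FP1", "O1"), seed = 8)
  coh <- generate_cohort(spec, signal_model())
  resp <- unlist(lapply(coh, function(s) s$probes$response))
  expect_gt(length(resp), 500)
  rate <- mean(resp == 3)
  expect_lt(abs(rate - spec$mw_rate), 0.05)
  # response 3 coincides with the latent state by construction
  latent <- unlist(lapply(coh, function(s) s$probes$latent_mw))
  expect_identical(unname(resp == 3), unname(latent))
})

test_that("background activity has the configured 1/f spectral slope", {
  spec <- cohort_spec(n_participants = 1, n_blocks = 1, block_duration = 120,
                      sampling_rate = 256, n_channels = 2,
                      channel_labels = c("FP1", "O1"), mw_rate = 0.01, seed = 5)
  quiet <- signal_model(alpha_burst_amp_nonmw = 0, alpha_burst_amp_mw = 0,
                        band_osc_amps = c(delta = 0, theta = 0, beta = 0),
                        ocular_artifact_rate = 0,
                        background_exponent_nonmw = 1.0,
                        background_exponent_mw = 1.0)
  s <- generate_session(spec, quiet, "S01")
  slope <- mwdetect:::psd_slope(welch_psd(s$signal[1, ], 256), 2, 30)
  expect_lt(abs(slope - (-1.0)), 0.15)
  # steeper configured exponent -> steeper measured slope
  quiet2 <- signal_model(alpha_burst_amp_nonmw = 0, alpha_burst_amp_mw = 0,
                         band_osc_amps = c(delta = 0, theta = 0, beta = 0),
                         ocular_artifact_rate = 0,
                         background_exponent_nonmw = 1.6,
                         background_exponent_mw = 1.6)
  s2 <- generate_session(spec, quiet2, "S01")
  slope2 <- mwdetect:::psd_slope(welch_psd(s2$signal[1, ], 256), 2, 30)
  expect_lt(abs(slope2 - (-1.6)), 0.15)
})

test_that("sessions round-trip through the on-disk layout", {
  spec <- cohort_spec(n_participants = 1, n_blocks = 1, block_duration = 60,
                      sampling_rate = 64, n_channels = 3,
                      channel_labels = c("FP1", "CZ", "O1"), seed = 2)
  s <- generate_session(spec, signal_model(), "S01")
  dir <- tempfile("sess")
  write_session(s, dir)
  s2 <- read_session(dir, "S01")
  expect_equal(s2$sampling_rate, s$sampling_rate)
  expect_equal(s2$channel_labels, s$channel_labels)
  expect_equal(s2$probes$time_s, s$probes$time_s)
  expect_equal(s2$signal, s$signal, tolerance = 1e-6)  # float32 round trip
})
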