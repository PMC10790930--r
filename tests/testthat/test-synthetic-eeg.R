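test_that("built-in montages have the advertised geometry", {
  g64 <- montage("gel64"); g16 <- montage("gel16"); d20 <- montage("dry20")
  expect_length(g64$channel_names, 64)
  expect_length(g16$channel_names, 16)
  expect_length(d20$channel_names, 20)
  expect_equal(g64$sampling_rate, 250)
  expect_equal(d20$sampling_rate, 500)
  for (m in list(g64, g16, d20)) {
    expect_true(all(c("Fz", "Cz") %in% m$channel_names))
    expect_true(all(m$frontocentral_weights >= 0 &
                    m$frontocentral_weights <= 1))
  }
  expect_true(all(g16$channel_names %in% g64$channel_names))
  expect_error(montage("custom"), "custom montage requires")
  expect_error(montage("gel64", channel_names = c("Fz", "Cz")), "64 channels")
})

test_that("error scheduling is fixed-count for every (n, fraction)", {
  m <- montage("gel16")
  for (case in list(c(10, 0.2), c(37, 0.33), c(11, 0.5), c(25, 0))) {
    rec <- generate_recording(m, errp_model(noise_sd = 1), n_trials = case[1],
                              error_fraction = case[2], seed = 5)
    expect_equal(sum(rec$events$label == "error"), round(case[1] * case[2]))
    expect_equal(nrow(rec$events), case[1])
  }
})

test_that("the study-one protocol yields exactly 100 errors of 500 at 20%", {
  # counts only depend on the schedule, so a quiet model keeps this cheap
  rec <- generate_recording(montage("gel16"),
                            errp_model(noise_sd = 0.1,
                                       line_noise_amplitude = 0),
                            n_trials = 500, error_fraction = 0.2, seed = 7)
  expect_equal(sum(rec$events$label == "error"), 100)
})

test_that("identical seed and parameters give identical recordings", {
  m <- montage("dry20")
  a <- generate_recording(m, errp_model(), 12, 0.5, seed = 3)
  b <- generate_recording(m, errp_model(), 12, 0.5, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  c <- generate_recording(m, errp_model(), 12, 0.5, seed = 4)
  expect_false(identical(a$samples, c$samples))
  expect_equal(sum(c$events$label == "error"),
               sum(a$events$label == "error"))
})

test_that("null model with zero noise gives identical error and true epochs", {
  null <- errp_model(n200_amplitude = 0, p300_amplitude = 0, noise_sd = 0,
                     line_noise_amplitude = 0, trial_latency_jitter_sd = 0)
  rec <- generate_recording(montage("gel16"), null, 10, 0.5, seed = 1)
  ep <- epoch_ground_truth(rec)
  err <- ep$data[ep$labels == "error", , , drop = FALSE]
  tru <- ep$data[ep$labels == "true", , , drop = FALSE]
  expect_equal(err[1, , ], tru[1, , ], tolerance = 1e-12)
})

test_that("ground-truth epoching preserves counts and window arithmetic", {
  rec <- generate_recording(montage("gel16"), errp_model(noise_sd = 1),
                            40, 0.25, seed = 2)
  ep <- epoch_ground_truth(rec, window = c(-0.2, 1.0))
  expect_equal(dim(ep$data)[1], 40)
  # half-open window: 1.2 s at 250 Hz = 300 samples
  expect_equal(dim(ep$data)[3], 300)
  expect_equal(ep$onset_index, 51L)
  expect_identical(ep$labels, rec$events$label)
  expect_identical(ep$channel_names, rec$montage$channel_names)

  empty <- rec
  empty$events <- rec$events[0, ]
  ep0 <- epoch_ground_truth(empty)
  expect_equal(dim(ep0$data)[1], 0)
})

test_that("epochs outside the recording are dropped with a warning", {
  rec <- generate_recording(montage("gel16"), errp_model(noise_sd = 1),
                            5, 0.2, seed = 2, lead_in = 1)
  rec$events$sample[1] <- 10  # too close to the start for a -0.2 s window
  expect_warning(ep <- epoch_ground_truth(rec), "dropped 1 epoch")
  expect_equal(dim(ep$data)[1], 4)
})

test_that("generation rejects invalid protocols", {
  m <- montage("gel16")
  expect_error(generate_recording(m, errp_model(), 10, 1.5), "error_fraction")
  expect_error(generate_recording(m, errp_model(), 10, 0.2,
                                  inter_trial_interval = 1), "1.2 s")
  expect_error(generate_recording(m, errp_model(), 0, 0.2), "n_trials")
})

test_that("recordings and epoch sets round-trip through the CSV container", {
  rec <- generate_recording(montage("gel16"), errp_model(), 6, 0.5, seed = 9)
  base <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, base)
  rec2 <- read_recording(base)
  expect_equal(rec2$samples, rec$samples, tolerance = 1e-12)
  expect_equal(rec2$events, rec$events)
  expect_equal(rec2$rate, rec$rate)

  ep <- epoch_ground_truth(rec)
  base2 <- file.path(withr::local_tempdir(), "ep")
  write_epochs(ep, base2)
  ep2 <- read_epochs(base2)
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
  expect_identical(ep2$labels, ep$labels)
  expect_equal(ep2$onset_index, ep$onset_index)
})
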