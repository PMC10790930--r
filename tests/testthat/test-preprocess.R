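make_recording_from <- function(x, rate, montage_obj, events = NULL) {
  if (is.null(events))
    events <- data.frame(sample = integer(0), label = character(0))
  structure(list(samples = x, events = events, montage = montage_obj,
                 rate = rate, seed = 0, errp = NULL),
            class = "subject_recording")
}

test_that("the composed filter chain attenuates 50 Hz by at least 40 dB", {
  m <- montage("gel16")
  fs <- 250
  tt <- (0:(fs * 30 - 1)) / fs
  x <- matrix(sin(2 * pi * 50 * tt), nrow = 16, ncol = length(tt),
              byrow = TRUE)
  rownames(x) <- m$channel_names
  # CAR would cancel an identical signal across channels; scale per channel
  x <- x * seq(0.5, 2, length.out = 16)
  ev <- data.frame(sample = seq(5 * fs, 25 * fs, by = 2 * fs),
                   label = rep(c("error", "true"), length.out = 11))
  rec <- make_recording_from(x, fs, m, ev)
  ep <- preprocess_recording(rec)
  # the reference level is the post-CAR input (CAR runs before epoching and
  # partially cancels the common component)
  xc <- sweep(x, 2, colMeans(x))
  rms_out <- sqrt(mean(ep$data^2))
  rms_in <- sqrt(mean(xc^2))
  expect_lt(20 * log10(rms_out / rms_in), -40)
})

test_that("constant input is rejected by the 1 Hz high-pass edge", {
  m <- montage("gel16")
  fs <- 250
  x <- matrix(7, nrow = 16, ncol = fs * 20)
  rownames(x) <- m$channel_names
  ev <- data.frame(sample = c(5, 10) * fs, label = c("error", "true"))
  rec <- make_recording_from(x, fs, m, ev)
  ep <- preprocess_recording(rec)
  expect_lt(max(abs(ep$data)), 1e-6)
})

test_that("common average reference removes the instantaneous channel mean", {
  rec <- generate_recording(montage("gel16"), errp_model(), 8, 0.5, seed = 3)
  cfg <- preproc_config()
  # re-run the continuous part of the chain to inspect the CAR output:
  # epoched data are CAR'd before baseline correction, so the channel mean
  # of every epoch sample equals the (channel mean of the) baseline shift
  ep <- preprocess_recording(rec, cfg)
  chan_mean <- apply(ep$data, c(1, 3), mean)  # trials x time
  # baseline correction subtracts a per-trial/channel constant, whose
  # channel mean is constant over time: remove it before asserting zero
  centered <- chan_mean - rowMeans(chan_mean)
  expect_lt(max(abs(centered)), 1e-9)
})

test_that("500 Hz recordings are downsampled to 250 Hz with 300-sample epochs", {
  rec <- generate_recording(montage("dry20"), errp_model(), 10, 0.5, seed = 4)
  expect_equal(rec$rate, 500)
  ep <- preprocess_recording(rec)
  expect_equal(ep$rate, 250)
  expect_equal(dim(ep$data)[3], 300)
  expect_equal(dim(ep$data)[1], 10)
  expect_identical(ep$labels, rec$events$label)
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  rec <- generate_recording(montage("gel16"), errp_model(), 10, 0.5, seed = 5)
  ep <- preprocess_recording(rec)
  tt <- (seq_len(dim(ep$data)[3]) - ep$onset_index) / ep$rate
  bl <- which(tt >= -0.2 & tt < 0)
  bl_means <- apply(ep$data[, , bl, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl_means)), 1e-9)
  twice <- baseline_correct(ep)
  expect_equal(twice$data, ep$data, tolerance = 1e-12)
})

test_that("the interest window cut follows the stated index arithmetic", {
  rec <- generate_recording(montage("gel16"), errp_model(), 6, 0.5, seed = 6)
  ep <- preprocess_recording(rec)
  iw <- extract_interest_window(ep, c(0.2, 0.8))
  expect_equal(dim(iw$data)[3], 150)
  # onset at (1-based) index 51 -> window starts at index 101
  expect_equal(iw$data[1, 1, 1], ep$data[1, 1, 101])
  expect_identical(iw$labels, ep$labels)

  ident <- extract_interest_window(ep, c(-0.2, 1.0))
  expect_equal(ident$data, ep$data)

  empty <- subset_epochs(ep, integer(0))
  iw0 <- extract_interest_window(empty, c(0.2, 0.8))
  expect_equal(dim(iw0$data)[1], 0)
  expect_equal(dim(iw0$data)[3], 150)

  expect_error(extract_interest_window(ep, c(0.9, 2.0)), "epoch span")
})

test_that("the IIR chain is stable on long noise input", {
  fs <- 250
  x <- matrix(rnorm(1e6), nrow = 1)
  nyq <- fs / 2
  notch <- signal::butter(2, c(49, 51) / nyq, type = "stop")
  bp <- signal::butter(2, c(1, 10) / nyq, type = "pass")
  y <- signal::filtfilt(bp, signal::filtfilt(notch, x[1, ]))
  expect_true(all(is.finite(y)))
  expect_lt(stats::sd(y), stats::sd(x))
})

test_that("non-finite samples are rejected", {
  m <- montage("gel16")
  x <- matrix(0, 16, 1000); x[3, 500] <- NA
  rownames(x) <- m$channel_names
  rec <- make_recording_from(x, 250, m)
  expect_error(preprocess_recording(rec), "non-finite")
})
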