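const_epochs <- function(err_val, true_val, n_each = 3, n_ch = 2,
                         n_samp = 50, rate = 250) {
  labels <- rep(c("error", "true"), each = n_each)
  dat <- array(0, c(2 * n_each, n_ch, n_samp))
  dat[labels == "error", , ] <- err_val
  dat[labels == "true", , ] <- true_val
  epoch_set(dat, labels, rate, paste0("ch", 1:n_ch), onset_index = 1L)
}

test_that("grand average and difference wave on constant epochs", {
  ep <- const_epochs(1, -1)
  ga <- grand_average(ep, c("ch1", "ch2"))
  expect_equal(unique(ga$difference), 2)
  expect_equal(unique(ga$error), 1)
  expect_equal(ga$n_trials[["error"]], 3)
  expect_error(grand_average(ep, "Fz"), "Fz")
})

test_that("single-trial grand average is the identity", {
  dat <- array(rnorm(2 * 1 * 20), c(2, 1, 20))
  ep <- epoch_set(dat, c("error", "true"), 250, "ch1", 1L)
  ga <- grand_average(ep, "ch1")
  expect_equal(ga$error, dat[1, 1, ])
  expect_equal(ga$true, dat[2, 1, ])
})

test_that("synthetic difference wave has the built-in ErrP morphology", {
  rec <- generate_recording(montage("gel16"), errp_model(), 200, 0.5,
                            seed = 31)
  ep <- preprocess_recording(rec)
  ga <- grand_average(ep, c("Fz", "Cz"))
  early <- ga$times >= 0.1 & ga$times < 0.3
  late <- ga$times >= 0.3 & ga$times < 0.6
  expect_lt(min(ga$difference[early]), 0)   # negativity in 100-300 ms
  expect_gt(max(ga$difference[late]), 0)    # positivity in 300-600 ms
  t_min <- ga$times[which.min(ga$difference)]
  t_max <- ga$times[which.max(ga$difference)]
  expect_true(t_min > 0.1 && t_min < 0.3)
  expect_true(t_max > 0.3 && t_max < 0.6)
})

test_that("SNR matches direct arithmetic on a half-sine difference trace", {
  rate <- 250
  n <- 150
  tt <- (seq_len(n) - 1) / rate
  half_sine <- sin(pi * seq(0, 1, length.out = n))
  labels <- rep(c("error", "true"), each = 2)
  dat <- array(0, c(4, 1, n))
  dat[1, 1, ] <- half_sine; dat[2, 1, ] <- half_sine
  ep <- epoch_set(dat, labels, rate, "ch1", 1L)
  got <- erp_snr(ep, "ch1", interval = c(0, n / rate))
  expected <- abs(mean(half_sine)) / stats::sd(half_sine)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("SNR degenerate cases behave as specified", {
  # constant nonzero difference: zero variance must raise, not return Inf
  ep <- const_epochs(2, 0)
  expect_error(erp_snr(ep, c("ch1", "ch2"), interval = c(0, 0.1)),
               "zero variance")
  # identically zero difference: SNR 0
  ep0 <- const_epochs(0, 0)
  expect_equal(erp_snr(ep0, c("ch1", "ch2"), interval = c(0, 0.1)), 0)
  # too-short interval
  expect_error(erp_snr(ep0, "ch1", interval = c(0, 0.004)), "3 samples")
})

test_that("SNR is invariant to global rescaling of the epochs", {
  ep <- fixture_epochs()
  base <- erp_snr(ep, c("C3", "Cz", "C4"), interval = c(0.3, 0.6))
  scaled <- ep
  scaled$data <- ep$data * 7.3
  expect_equal(erp_snr(scaled, c("C3", "Cz", "C4"), interval = c(0.3, 0.6)),
               base, tolerance = 1e-10)
  expect_gt(base, 0)
})

test_that("bootstrap mean of a degenerate distribution collapses", {
  bs <- bootstrap_mean(rep(3.5, 10), n_boot = 200, seed = 1)
  expect_equal(bs$mean, 3.5)
  expect_equal(bs$ci_low, 3.5)
  expect_equal(bs$ci_high, 3.5)
})

test_that("bootstrap of a balanced binary sample brackets one half", {
  vals <- rep(c(0, 1), each = 50)
  bs <- bootstrap_mean(vals, n_boot = 5000, seed = 2)
  expect_equal(bs$mean, 0.5, tolerance = 0.02)
  expect_lt(bs$ci_low, 0.5)
  expect_gt(bs$ci_high, 0.5)
  # binomial oracle: percentile CI approximates mean +- 1.96 se
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_equal(bs$ci_high - bs$ci_low, 2 * 1.96 * se, tolerance = 0.2)
})

test_that("Bonferroni correction widens the bootstrap interval", {
  vals <- rnorm(40)
  b1 <- bootstrap_mean(vals, n_boot = 2000, bonferroni_m = 1, seed = 3)
  b2 <- bootstrap_mean(vals, n_boot = 2000, bonferroni_m = 2, seed = 3)
  expect_lte(b2$ci_low, b1$ci_low)
  expect_gte(b2$ci_high, b1$ci_high)
  expect_equal(b1$mean, b2$mean)
})

test_that("bootstrap CI width shrinks with sample size", {
  width <- function(n) {
    vals <- withr::with_seed(10, rnorm(n))
    bs <- bootstrap_mean(vals, n_boot = 2000, seed = 4)
    bs$ci_high - bs$ci_low
  }
  expect_lt(width(400), width(25))
})

test_that("CI-overlap verdicts follow the two-interval rule and are symmetric", {
  mk <- function(mean, lo, hi)
    structure(list(mean = mean, ci_low = lo, ci_high = hi, alpha = 0.05),
              class = "bootstrap_summary")
  a <- mk(0.5, 0, 1); b <- mk(2.5, 2, 3)
  expect_equal(ci_overlap_verdict(a, b), "p<0.01")
  a <- mk(1, 0, 2); b <- mk(2.5, 1.5, 3.5)
  expect_equal(ci_overlap_verdict(a, b), "p<0.05")
  a <- mk(1, 0, 2); b <- mk(1.5, 0.5, 2.5)
  expect_equal(ci_overlap_verdict(a, b), "n.s.")
  for (pair in list(list(mk(0.5, 0, 1), mk(2.5, 2, 3)),
                    list(mk(1, 0, 2), mk(2.5, 1.5, 3.5)),
                    list(mk(1, 0, 2), mk(1.5, 0.5, 2.5))))
    expect_equal(ci_overlap_verdict(pair[[1]], pair[[2]]),
                 ci_overlap_verdict(pair[[2]], pair[[1]]))
})
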