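test_that("trough-to-peak measurement works on crafted waveforms", {
  # trough at sample 10, peak at sample 20, 40 kHz: 10 samples x 25 us
  amp <- rep(0, 40)
  amp[11] <- -1 # sample index 10 on the 0-based grid
  amp[21] <- 0.5
  wf <- structure(list(amplitude = amp, sampling_khz = 40),
                  class = "cholattn_waveform")
  expect_equal(peak_to_trough(wf), 250, tolerance = 1e-6)

  monotone <- structure(list(amplitude = seq(-1, 1, length.out = 30),
                             sampling_khz = 40),
                        class = "cholattn_waveform")
  expect_true(is.na(peak_to_trough(monotone)))
})

test_that("width classification uses the 250 us boundary inclusively", {
  expect_equal(classify_cell_width(250), "narrow")
  expect_equal(classify_cell_width(251), "broad")
  expect_equal(classify_cell_width(415), "broad")
  expect_equal(classify_cell_width(210), "narrow")
  expect_true(is.na(classify_cell_width(NA)))
})

test_that("epoch rates count spikes in half-open windows", {
  trial <- data.frame(stim_on_ms = 0, cue_on_ms = 600, dim1_ms = 2500)
  w <- canonical_windows()$dim # [-500, 0) before dimming
  spikes <- c(1990, 2000, 2100, 2250, 2499.99, 2500)
  expect_equal(epoch_count(spikes, trial, w), 4) # 2500 excluded, 2000 included
  expect_equal(epoch_rate(spikes, trial, w), 8)
  expect_equal(epoch_rate(numeric(0), trial, w), 0)

  # cross-check against brute-force timestamp filtering on random trials
  set.seed(9)
  for (i in 1:20) {
    sp <- sort(runif(50, 0, 3000))
    t0 <- trial$dim1_ms + w$start_ms
    t1 <- trial$dim1_ms + w$end_ms
    expect_equal(epoch_count(sp, trial, w), sum(sp >= t0 & sp < t1))
  }
})

test_that("ISI statistics match hand computations and analytics", {
  # constant ISIs
  s <- isi_stats(list(c(0, 10, 20, 30, 40)))
  expect_equal(c(s$cv, s$cv2, s$lv), c(0, 0, 0))

  # ISIs [10, 10, 30]: Lv = (3/2) * (0 + (20/40)^2) = 0.375
  s <- isi_stats(list(cumsum(c(0, 10, 10, 30))))
  expect_equal(s$lv, 0.375)
  expect_equal(s$cv2, mean(c(0, 2 * 20 / 40)))
  expect_equal(s$cv, sd(c(10, 10, 30)) / mean(c(10, 10, 30)))

  # exponential ISIs: CV, CV2, Lv all near 1
  set.seed(2)
  s <- isi_stats(list(cumsum(rexp(10000))))
  expect_lt(abs(s$cv - 1), 0.05)
  expect_lt(abs(s$cv2 - 1), 0.05)
  expect_lt(abs(s$lv - 1), 0.05)

  # fewer than 3 ISIs is flagged
  expect_false(isi_stats(list(c(0, 1)))$valid)
})

test_that("CV2 and Lv are invariant to uniform time rescaling", {
  set.seed(3)
  train <- cumsum(rgamma(500, 2, 2))
  a <- isi_stats(list(train))
  b <- isi_stats(list(train * 7.3))
  expect_equal(a$cv2, b$cv2)
  expect_equal(a$lv, b$lv)
  expect_equal(a$cv, b$cv)
})

test_that("ISIs are never formed across trial boundaries", {
  # two trials whose concatenation would add a huge spurious ISI
  a <- isi_stats(list(c(0, 10, 20, 30), c(5000, 5010, 5020, 5030)))
  expect_equal(a$cv, 0)
  expect_equal(a$n_isis, 6)
  expect_equal(a$n_pairs, 4)
})

test_that("Fano factor behaves on known count distributions", {
  expect_equal(fano_factor(c(2, 2, 2)), 0)
  expect_true(is.na(fano_factor(c(0, 0, 0))))
  set.seed(4)
  expect_lt(abs(fano_factor(rpois(2000, 8)) - 1), 0.15)
  # gamma-Poisson: FF = 1 + sigma2_g * lambda = 1 + 0.25 * 20 = 6
  g <- rgamma(2000, 4, 4)
  expect_lt(abs(fano_factor(rpois(2000, 20 * g)) - 6), 1.2)
})

test_that("per-cell metrics carry rates consistent with integer counts", {
  design <- task_design(n_trials_per_condition = 4)
  cell <- simulate_cell(archetype_panel("ACh")$B1, design, seed = 77)
  tr <- trial_rates(cell)
  for (nm in c("stim", "cue", "dim")) {
    len <- 0.3
    if (nm == "dim") len <- 0.5
    counts <- tr[[paste0("rate_", nm)]] * len
    expect_equal(counts, round(counts), tolerance = 1e-9)
  }
  m <- cell_metrics(cell)
  expect_equal(m$cell_class, classify_cell_width(m$p2t_us))
  expect_true(all(c("cv", "cv2", "lv", "fr", "fano", "auroc") %in% names(m)))
})
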