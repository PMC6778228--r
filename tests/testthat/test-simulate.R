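test_that("waveform trough-to-peak matches the archetype width", {
  arch <- cell_archetype("a", p2t_mean_us = 400, p2t_sd_us = 0,
                         base_rate_hz = 10)
  wf <- simulate_waveform(arch, sampling_khz = 40, seed = 3)
  # one interpolated sample at 40 kHz x10 is 2.5 us
  expect_lt(abs(peak_to_trough(wf) - 400), 3)

  narrow <- cell_archetype("n", p2t_mean_us = 200, p2t_sd_us = 0,
                           base_rate_hz = 10)
  wfn <- simulate_waveform(narrow, sampling_khz = 40, seed = 3)
  expect_equal(classify_cell_width(peak_to_trough(wfn)), "narrow")

  wf2 <- simulate_waveform(arch, sampling_khz = 40, seed = 3)
  expect_identical(wf$amplitude, wf2$amplitude)
})

test_that("null cells produce chance-level AUROC and Poisson-like counts", {
  design <- task_design(n_trials_per_condition = 50, drug_states = "off")
  cell <- simulate_cell(null_archetype(12), design, seed = 21)
  tr <- trial_rates(cell, list(w = canonical_windows()$dim))
  a <- auroc(tr$rate_w[tr$attention == "RF"], tr$rate_w[tr$attention != "RF"])
  expect_lt(abs(a - 0.5), 0.1)
  expect_lt(abs(fano_factor(tr$count_w) - 1), 0.25)
})

test_that("attentional gain raises the ideal-observer AUROC", {
  arch <- cell_archetype("att", p2t_mean_us = 400, p2t_sd_us = 0,
                         base_rate_hz = 12, attention_gain = 1.3,
                         gain_var = 0, isi_shape = 1)
  design <- task_design(n_trials_per_condition = 100, drug_states = "off")
  cell <- simulate_cell(arch, design, seed = 8)
  tr <- trial_rates(cell, list(w = canonical_windows()$dim))
  a <- auroc(tr$rate_w[tr$attention == "RF"], tr$rate_w[tr$attention != "RF"])
  expect_gt(a, 0.55)
})

test_that("trial gains create the gamma-Poisson count variance", {
  # sigma2_g = 0.25 and mu*T = 20 expected counts: var = 20 + 0.25*400 = 120
  arch <- cell_archetype("gv", p2t_mean_us = 400, p2t_sd_us = 0,
                         base_rate_hz = 40, attention_gain = 1,
                         gain_var = 0.25, isi_shape = 1)
  design <- task_design(n_trials_per_condition = 170, drug_states = "off")
  cell <- simulate_cell(arch, design, seed = 31)
  tr <- trial_rates(cell, list(w = canonical_windows()$dim))
  expect_equal(mean(tr$count_w), 20, tolerance = 0.05)
  expect_lt(abs(var(tr$count_w) - 120), 30)
})

test_that("generator regularity follows the gamma-renewal Lv analytics", {
  design <- task_design(n_trials_per_condition = 60, drug_states = "off")
  for (kappa in c(0.5, 2)) {
    arch <- cell_archetype("k", p2t_mean_us = 400, p2t_sd_us = 0,
                           base_rate_hz = 25, attention_gain = 1,
                           gain_var = 0, isi_shape = kappa)
    cell <- simulate_cell(arch, design, seed = 100 + kappa * 10)
    s <- isi_stats(cell$spikes)
    expect_gt(s$n_pairs, 2000)
    expect_lt(abs(s$lv - 3 / (2 * kappa + 1)), 0.05)
  }
})

test_that("identical seeds reproduce identical populations bit-for-bit", {
  design <- task_design(n_trials_per_condition = 3)
  arch <- archetype_panel("ACh")[c("B1", "N3")]
  p1 <- simulate_population(arch, 2, design, seed = 5)
  p2 <- simulate_population(arch, 2, design, seed = 5)
  expect_identical(
    lapply(p1$cells, `[[`, "spikes"),
    lapply(p2$cells, `[[`, "spikes")
  )
  expect_identical(p1$ground_truth, p2$ground_truth)
})

test_that("population simulation validates its inputs", {
  design <- task_design(n_trials_per_condition = 2)
  expect_error(simulate_population(list(), 3, design, seed = 1))
  expect_error(simulate_population(archetype_panel("ACh"), 0, design, seed = 1))
  expect_error(task_design(n_trials_per_condition = 0))
})

test_that("behavioral generator hits its extreme operating points", {
  design <- task_design(n_trials_per_condition = 30)
  beh <- simulate_behavior(design, hit_p = 1, false_alarm_p = 0,
                           rt_mean_ms = 400, seed = 4)
  rates <- hit_cr_rates(beh)
  expect_equal(rates$hit_rate, 1)
  expect_equal(rates$cr_rate, 1)
  norm <- normalize_rts(beh)
  expect_equal(mean(norm$rt_norm), 1, tolerance = 1e-12)
})
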