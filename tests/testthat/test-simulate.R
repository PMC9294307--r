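cfg0 <- sim_config(n_epochs = 4, noise_sd = 0, artifact_amplitude = 0,
                   seed = 1)
times <- epoch_times(cfg0)

test_that("component waveforms have the planted morphology", {
  w <- make_component_waveform(times, "immature_NciPci")
  expect_equal(times[which.min(w)], 95)        # N(CI) trough at its latency
  expect_gt(max(w[times > 150]), 0)            # P(CI) follows
  expect_true(all(w[times <= -80] == 0))       # silent over the baseline
  wm <- make_component_waveform(times, "mature_P1N1P2")
  expect_equal(times[which.min(wm)], 100)      # N1 dominates
  expect_gt(wm[times == 60], 0)                # P1 present
  # zero amplitudes give the zero waveform; sign flip mirrors it
  expect_equal(make_component_waveform(times, "mature_P1N1P2",
                                       amplitudes = c(0, 0, 0)),
               numeric(length(times)))
  w1 <- suppressWarnings(make_component_waveform(
    times, "mature_P1N1P2", amplitudes = c(-10, 25, -12)))
  expect_equal(w1, -wm)
  expect_error(make_component_waveform(times, "mature_P1N1P2",
                                       latencies = c(-100, 100, 180)),
               "baseline")
})

test_that("the implant artifact is a bounded biphasic train", {
  a <- make_ci_artifact(times, duration = 36, amplitude = 500)
  expect_true(all(a[times < 0 | times >= 36] == 0))
  expect_lte(max(times[a != 0]), 36)
  expect_equal(max(abs(a)), 500)
  expect_equal(make_ci_artifact(times, amplitude = 0),
               numeric(length(times)))
  # alternating pulses are charge balanced (pedestal off)
  pure <- make_ci_artifact(times, pedestal_frac = 0)
  for (k in 0:8) {
    sel <- times >= k * 4 & times < (k + 1) * 4
    expect_equal(sum(pure[sel]), 0)
  }
  expect_error(make_ci_artifact(times, duration = 2000), "epoch end")
})

test_that("epoch simulation is deterministic, linear and baseline-silent", {
  g <- shared_geom()
  wf <- make_component_waveform(times, "immature_NciPci")
  src <- list(source_spec(c(-62, -18, 8), c(0, 0, 1), wf, "left_AC"))
  cfg <- sim_config(n_epochs = 3, noise_sd = 2, seed = 77)
  ep1 <- simulate_epochs(cfg, src, g$head, g$montage, "CI2_left")
  ep2 <- simulate_epochs(cfg, src, g$head, g$montage, "CI2_left")
  expect_identical(ep1$data, ep2$data)

  # noiseless: every trial equals the average; doubling sources doubles data
  src2 <- list(source_spec(c(-62, -18, 8), c(0, 0, 1), 2 * wf, "left_AC"))
  e1 <- simulate_epochs(cfg0, src, g$head, g$montage, "CI2_left")
  e2 <- simulate_epochs(cfg0, src2, g$head, g$montage, "CI2_left")
  expect_equal(e1$data[, , 1], rowMeans(e1$data, dims = 2))
  expect_equal(e2$data, 2 * e1$data, tolerance = 1e-12)
  # baseline window carries no source or artifact energy
  cfgA <- sim_config(n_epochs = 2, noise_sd = 0, artifact_amplitude = 500,
                     seed = 1)
  eA <- simulate_epochs(cfgA, src, g$head, g$montage, "CI2_left")
  expect_equal(max(abs(eA$data[, times <= -80, ])), 0)
  expect_error(simulate_epochs(cfg0, list(source_spec(c(0, 0, 120), c(0, 0, 1),
                                                      wf, "other")),
                               g$head, g$montage, "CI2_left"),
               "geometry error")
})

test_that("trial averaging reduces noise at the closed-form rate", {
  g <- shared_geom()
  cfg <- sim_config(n_epochs = 400, noise_sd = 5, artifact_amplitude = 0,
                    seed = 9)
  ep <- simulate_epochs(cfg, list(), g$head, g$montage, "CI1_right")
  avg <- rowMeans(ep$data, dims = 2)
  # residual SD of the average ~ 5/sqrt(400) = 0.25 uV
  expect_equal(sd(avg), 5 / sqrt(400), tolerance = 0.05)
})

test_that("longitudinal ground truth encodes the planted effects", {
  cohort <- load_cohort(cohort_fixture_path())
  g <- shared_geom()
  cfg <- sim_config(n_epochs = 2, seed = 1)
  # null effects: no delay dependence, no spread, no decay
  em0 <- effect_model(repr_slope = 0, repr_sd = 0, decay_rate = 0)
  sim0 <- simulate_longitudinal_cohort(cohort, em0, cfg, g$head, g$montage,
                                       n_sessions = 2, seed = 5)
  gt0 <- sim0$ground_truth
  expect_equal(length(unique(round(gt0$repr_baseline, 10))), 1L)
  s1 <- gt0[gt0$session == 1, ]; s2 <- gt0[gt0$session == 2, ]
  expect_equal(s1$amp_left_ac, s2$amp_left_ac)

  # planted negative slope appears exactly in the noise-free ground truth
  em <- effect_model(repr_slope = -5, repr_sd = 0)
  sim <- simulate_longitudinal_cohort(cohort, em, cfg, g$head, g$montage,
                                      n_sessions = 1, seed = 5)
  gt <- sim$ground_truth
  fit <- lm(repr_baseline ~ inter_implant_delay,
            data = gt[gt$condition == "CI1_right", ])
  expect_equal(unname(coef(fit)[2]), -5, tolerance = 1e-8)
  # ground truth always accompanies the generator, one row per cell
  expect_equal(nrow(gt), nrow(cohort) * 3)
  expect_true(all(c("true_lateralization", "true_representation_left",
                    "true_enh_left", "cell_seed") %in% names(gt)))
  # second-ear responses decay across sessions, first-ear stay constant
  sim2 <- simulate_longitudinal_cohort(cohort, effect_model(), cfg, g$head,
                                       g$montage, n_sessions = 4, seed = 5)
  gt2 <- sim2$ground_truth
  ci2 <- gt2[gt2$condition == "CI2_left" & gt2$participant_id == "1", ]
  ci1 <- gt2[gt2$condition == "CI1_right" & gt2$participant_id == "1", ]
  expect_true(all(diff(ci2$amp_left_ac[order(ci2$session)]) < 0))
  expect_equal(length(unique(ci1$amp_left_ac)), 1L)
})

test_that("speech scores are binomial percent-correct draws", {
  expect_equal(unname(simulate_speech_scores(c(x = 1), 50, seed = 1)), 100)
  expect_error(simulate_speech_scores(1.2, 50), "domain error")
  s1 <- simulate_speech_scores(c(l = 0.6, r = 0.8, b = 0.85), 50, seed = 3)
  s2 <- simulate_speech_scores(c(l = 0.6, r = 0.8, b = 0.85), 50, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 100))
  # binomial oracle: at n = 10^4 words the score concentrates near 50%
  big <- simulate_speech_scores(0.5, 1e4, seed = 8)
  expect_lt(abs(big - 50), 2)
})
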