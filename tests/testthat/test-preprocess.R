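test_that("the band-pass is unity in-band, strongly attenuating out of band, zero phase", {
  fs <- 1000
  tms <- seq(-200, 799)
  n <- length(tms)
  # 8 contiguous trials; gain measured on an interior trial (steady state)
  mk <- function(x) tiny_epochs(array(rep(x, each = 4), c(4, n, 8)), fs)
  mid <- tms > -100 & tms < 700
  gain <- function(f) {
    out <- bandpass_filter(mk(sin(2 * pi * f * tms / 1000)))
    sd(out$data[1, mid, 4]) / sd(sin(2 * pi * f * tms[mid] / 1000))
  }
  expect_equal(gain(10), 1, tolerance = 0.01)
  expect_lt(gain(60), 0.1)  # >= 90% attenuation one octave out
  # zero phase: a symmetric pulse keeps its peak latency
  pulse <- bandpass_filter(mk(exp(-0.5 * ((tms - 300) / 15)^2)))
  expect_equal(tms[which.max(pulse$data[1, , 4])], 300)
  expect_error(bandpass_filter(mk(tms * 0), low = 40, high = 30),
               "configuration error")
})

test_that("common average reference zeroes the channel mean and ignores offsets", {
  set.seed(2)
  ep <- tiny_epochs(array(rnorm(6 * 50 * 3), c(6, 50, 3)))
  car <- common_average_reference(ep)
  expect_lt(max(abs(colMeans(car$data))), 1e-12)
  ep_off <- ep
  ep_off$data <- ep$data + 7
  expect_equal(common_average_reference(ep_off)$data, car$data)
  # bad channels are excluded from the average
  ep_bad <- ep
  ep_bad$data[1, , ] <- 1e4
  car2 <- common_average_reference(ep_bad, bad_channels = c(TRUE, rep(FALSE, 5)))
  expect_lt(max(abs(colMeans(car2$data[-1, , ]))), 1e-12)
  single <- tiny_epochs(array(rnorm(50), c(1, 50, 1)))
  expect_error(common_average_reference(single), "at least 2")
})

test_that("epoch rejection applies the amplitude rule inside 100-800 ms only", {
  tms <- seq(-200, 799)
  d <- array(0, c(3, length(tms), 4))
  d[2, tms == 300, 2] <- 150    # excursion inside the window -> rejected
  d[1, tms == 50, 3] <- 150     # excursion before the window -> retained
  d[3, tms == 500, 4] <- 99     # below threshold -> retained
  ep <- tiny_epochs(d)
  out <- reject_epochs(ep, threshold = 100)
  expect_equal(out$log$rejected, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(dim(out$epochs$data)[3], 3L)
  # the log alone reproduces every decision
  expect_equal(out$log$rejected, abs(out$log$extremum_uV) > 100)
  expect_equal(out$log$channel[2], "ch2")
  expect_equal(out$log$latency_ms[2], 300)
  expect_error(reject_epochs(ep, threshold = -5), "configuration error")
})

test_that("flat and noisy channels are flagged, clean data are not", {
  set.seed(3)
  d <- array(rnorm(8 * 1000 * 2), c(8, 1000, 2))
  ep <- tiny_epochs(d)
  expect_equal(sum(detect_bad_channels(ep)), 0L)
  d[1, , ] <- 0                                  # flat
  d[2, , ] <- rnorm(2000, sd = sqrt(20))         # 20x median variance
  ep2 <- tiny_epochs(d)
  mask <- detect_bad_channels(ep2)
  expect_true(mask[1] && mask[2])
  expect_equal(sum(mask), 2L)
})

test_that("averaging is the sample-wise mean and warns below 100 epochs", {
  one <- matrix(rnorm(4 * 100), 4, 100)
  ep <- tiny_epochs(array(one, c(4, 100, 200)))
  ev <- average_epochs(ep)
  expect_equal(ev$data, one)
  expect_equal(ev$n_epochs_included, 200L)
  expect_warning(average_epochs(tiny_epochs(array(one, c(4, 100, 99)))),
                 "99 accepted epochs")
  # law of large numbers: the average converges on the clean signal
  set.seed(4)
  sig <- sin(seq(0, 4 * pi, length.out = 100))
  noisy <- array(rep(sig, each = 4), c(4, 100, 1000)) +
    array(rnorm(4 * 100 * 1000, sd = 2), c(4, 100, 1000))
  avg <- average_epochs(tiny_epochs(noisy), min_epochs = 1)
  se <- 2 / sqrt(1000)
  expect_lt(max(abs(avg$data - rep(sig, each = 4))), 5 * se)
})

test_that("global field power is the offset-free spatial RMS", {
  # channels split evenly at +a/-a: GFP = a at every sample
  a <- 3.7
  d <- rbind(matrix(a, 2, 50), matrix(-a, 2, 50))
  ev <- tiny_evoked(d)
  expect_equal(global_field_power(ev)$values, rep(a, 50))
  # homogeneity and invariance under common offsets (via CAR)
  set.seed(5)
  d2 <- matrix(rnorm(200), 4, 50)
  d2 <- sweep(d2, 2, colMeans(d2))
  g1 <- global_field_power(tiny_evoked(d2))$values
  g3 <- global_field_power(tiny_evoked(3 * d2))$values
  expect_equal(g3, 3 * g1)
  expect_equal(global_field_power(tiny_evoked(matrix(0, 4, 50)))$values,
               rep(0, 50))
  ev_raw <- tiny_evoked(d2, reference = "A2")
  expect_error(global_field_power(ev_raw), "average-referenced")
})

test_that("first-component detection finds peaks and reports absences", {
  tms <- seq(-200, 799)
  bump <- 2 * exp(-0.5 * ((tms - 95) / 12)^2)
  gfp <- structure(list(values = bump, times = tms), class = "gfp_series")
  out <- find_first_component(gfp, morphology = "immature_NciPci")
  expect_true(out$component_found)
  expect_equal(out$latency_ms, 95)
  expect_equal(out$label, "N_CI")
  flat <- structure(list(values = rep(1, length(tms)), times = tms),
                    class = "gfp_series")
  expect_false(find_first_component(flat)$component_found)
  # simulated mature first-ear response lands in the reported latency band
  g <- shared_geom()
  cfg <- sim_config(n_epochs = 60, seed = 21)
  times <- epoch_times(cfg)
  wf <- make_component_waveform(times, "mature_P1N1P2")
  src <- list(source_spec(c(-62, -18, 8), c(0, 0, 1),
                          wf / max(abs(wf)) * 60, "left_AC"))
  ep <- simulate_epochs(cfg, src, g$head, g$montage, "CI1_right")
  pp <- preprocess_epochs(ep, min_epochs = 10)
  A <- estimate_artifact_subspace(pp$evoked, rank = 1)
  ev <- pp$evoked
  ev$data <- ev$data - A %*% crossprod(A, ev$data)
  comp <- find_first_component(global_field_power(ev),
                               morphology = "mature_P1N1P2")
  expect_true(comp$component_found)
  expect_gt(comp$latency_ms, 93.6 - 2 * 12.9)
  expect_lt(comp$latency_ms, 93.6 + 2 * 12.9)
})

test_that("peak topographies average the requested window", {
  tms <- seq(-200, 799)
  const <- matrix(rep(1:4, length(tms)), 4, length(tms))
  ev <- tiny_evoked(const)
  expect_equal(unname(peak_topography(ev, 100, 5)), 1:4)
  # linear-in-time data: the window mean equals the center value
  lin <- outer(1:4, tms / 100)
  evl <- tiny_evoked(lin)
  expect_equal(unname(peak_topography(evl, 100, 4)), unname(lin[, tms == 100]))
  expect_equal(unname(peak_topography(evl, 250, 0)), unname(lin[, tms == 250]))
  expect_error(peak_topography(ev, 798, 10), "domain error")
})
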