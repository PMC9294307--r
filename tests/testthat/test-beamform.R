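# A shared moderately sized simulation: one left-AC source with the implant
# artifact, reused by several blocks below.
sim_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- shared_geom()
    cfg <- sim_config(n_epochs = 30, seed = 314, noise_sd = 8)
    times <- epoch_times(cfg)
    wf <- make_component_waveform(times, "immature_NciPci")
    src <- list(source_spec(c(-60, -15, 5), c(0, 0, 1),
                            wf / max(abs(wf)) * 90, "left_AC"))
    ep <- simulate_epochs(cfg, src, g$head, g$montage, "CI2_left")
    pp <- preprocess_epochs(ep, min_epochs = 10)
    cache <<- list(g = g, pp = pp, src_loc = c(-60, -15, 5))
    cache
  }
})

test_that("artifact subspace estimation recovers the planted topography", {
  fx <- sim_fixture()
  A <- estimate_artifact_subspace(fx$pp$evoked, rank = 2)
  expect_equal(crossprod(A), diag(2), tolerance = 1e-10)  # orthonormal
  topo <- artifact_topography(fx$g$montage, "left")
  topo <- topo - mean(topo)
  topo <- topo / sqrt(sum(topo^2))
  expect_gte(abs(sum(A[, 1] * topo)), 0.99)
  expect_error(estimate_artifact_subspace(fx$pp$evoked, rank = 62),
               "channel count")
})

test_that("beamformer weights satisfy unit-gain and artifact-null constraints", {
  fx <- sim_fixture()
  A <- estimate_artifact_subspace(fx$pp$evoked, rank = 1)
  filt <- tracs_weights(fx$pp$epochs, fx$g$lf20, artifact_subspace = A)
  nv <- nrow(filt$W)
  gains <- vapply(seq_len(nv), function(v) {
    l <- fx$g$lf20$K[, , v] %*% filt$orientations[v, ]
    drop(filt$W[v, ] %*% l)
  }, numeric(1))
  expect_lt(max(abs(gains - 1)), 1e-8)
  nulls <- abs(filt$W %*% A)
  expect_lt(max(nulls), 1e-8)
})

test_that("noiseless single dipoles localize to within one grid spacing", {
  g <- shared_geom()
  set.seed(50)
  errs <- replicate(12, {
    loc <- c(sample(c(-1, 1), 1) * runif(1, 55, 70), runif(1, -35, 5),
             runif(1, -10, 20))
    cfg <- sim_config(n_epochs = 40, seed = sample.int(1e6, 1),
                      noise_sd = 0.5, artifact_amplitude = 0)
    times <- epoch_times(cfg)
    wf <- make_component_waveform(times, "immature_NciPci")
    src <- list(source_spec(loc, c(0, 0, 1), wf / max(abs(wf)) * 80, "other"))
    ep <- simulate_epochs(cfg, src, g$head, g$montage, "CI2_left")
    pp <- preprocess_epochs(ep, min_epochs = 10)
    filt <- tracs_weights(pp$epochs, g$lf20, NULL)
    map <- pseudo_z_map(filt, pp$evoked, signal_window = c(92.5, 97.5),
                        epochs = pp$epochs)
    sqrt(sum((map$grid[which.max(map$pz), ] - loc)^2))
  })
  expect_lte(median(errs), 20)
})

test_that("pseudo-Z is a scale-invariant baseline-normalized ratio", {
  set.seed(6)
  n <- 1000
  tms <- seq(-200, 799)
  base_sd <- 2
  ch1 <- rnorm(n, sd = base_sd)
  ch1[tms >= 90 & tms <= 100] <- 5 * base_sd
  d <- rbind(ch1, matrix(rnorm(2 * n, sd = base_sd), 2, n))
  ev <- tiny_evoked(d)
  filt <- identity_filters(3, 3)
  map <- pseudo_z_map(filt, ev, signal_window = c(90, 100))
  # Monte-Carlo oracle: planted mean 5 sigma -> PZ about 5
  expect_equal(map$pz[1], 5, tolerance = 0.5)
  ev2 <- ev; ev2$data <- 3 * ev$data
  map2 <- pseudo_z_map(filt, ev2, signal_window = c(90, 100))
  expect_equal(map2$pz, map$pz, tolerance = 1e-12)
  # ratio identity: signal mean equal to the baseline SD gives PZ = 1
  ch <- rnorm(n); ch <- (ch - mean(ch[tms <= -80])) / sd(ch[tms <= -80])
  ch[tms >= 90 & tms <= 100] <- 1
  ev3 <- tiny_evoked(matrix(ch, 1, n))
  expect_equal(pseudo_z_map(identity_filters(1, 1), ev3,
                            signal_window = c(90, 100))$pz, 1,
               tolerance = 1e-9)
  flat <- tiny_evoked(matrix(0, 1, n))
  expect_error(pseudo_z_map(identity_filters(1, 1), flat,
                            signal_window = c(90, 100)), "zero baseline SD")
  expect_error(pseudo_z_map(filt, ev, signal_window = c(-150, -100)),
               "disjoint")
})

test_that("omnibus correction subtracts the threshold exactly and orders with alpha", {
  fx <- sim_fixture()
  filt <- tracs_weights(fx$pp$epochs, fx$g$lf20,
                        estimate_artifact_subspace(fx$pp$evoked, rank = 1))
  map <- pseudo_z_map(filt, fx$pp$evoked, signal_window = c(92.5, 97.5),
                      epochs = fx$pp$epochs)
  set.seed(1)
  om05 <- omnibus_threshold(filt, fx$pp$epochs, alpha = 0.05)
  set.seed(1)
  om_all <- omnibus_threshold(filt, fx$pp$epochs, alpha = 1)
  expect_lte(om_all, om05)   # alpha = 1 is the permissive quantile boundary
  map <- apply_omnibus(map, om05)
  expect_equal(map$pz_corrected, map$pz - om05)
})

test_that("a strongly planted source is detected above the omnibus threshold", {
  fx <- sim_fixture()
  loc <- localize_evoked(fx$pp$epochs, fx$pp$evoked, fx$g$lf20)
  expect_true(loc$peaks$left$significant)
  expect_lte(sqrt(sum((loc$peaks$left$voxel - fx$src_loc)^2)), 2 * 20)
  expect_equal(loc$component$latency_ms, 95, tolerance = 6)
})

test_that("ROI peak extraction is an argmax with documented tie-breaks", {
  grid <- as.matrix(expand.grid(x = c(-70, -60, 60, 70), y = c(-25, -5),
                                z = c(0, 10)))
  mp <- structure(list(pz = rep(1, nrow(grid)),
                       pz_corrected = rep(-0.5, nrow(grid)), grid = grid,
                       spacing = 10, omnibus_value = 1.5),
                  class = "source_map")
  # unique maximum inside the left box
  i <- which(grid[, 1] == -60 & grid[, 2] == -25 & grid[, 3] == 10)
  mp$pz_corrected[i] <- 1.4
  pk <- extract_roi_peak(mp, auditory_roi("left"))
  expect_equal(unname(pk$voxel), c(-60, -25, 10))
  expect_true(pk$significant)
  # all below threshold: reported, flagged not significant
  mp$pz_corrected[i] <- -0.1
  pk2 <- extract_roi_peak(mp, auditory_roi("left"))
  expect_false(pk2$significant)
  expect_lte(pk2$pz_corrected, 0)
  # uniform map: lowest voxel index wins
  mp$pz_corrected[] <- 0.2
  pk3 <- extract_roi_peak(mp, auditory_roi("right"))
  right_idx <- which(grid[, 1] >= 55)
  expect_equal(unname(pk3$voxel), unname(grid[min(right_idx), ]))
  # invariance to values outside the ROI
  mp$pz_corrected[grid[, 1] <= -55] <- 99
  pk4 <- extract_roi_peak(mp, auditory_roi("right"))
  expect_equal(pk4$voxel, pk3$voxel)
  empty <- mp; empty$grid <- matrix(c(0, 0, 0), 1); empty$pz <- 1
  empty$pz_corrected <- 1
  expect_error(extract_roi_peak(empty, auditory_roi("left")), "empty ROI")
})

test_that("suppression keeps estimates faithful while its absence corrupts them", {
  g <- shared_geom()
  d <- artifact_suppression_demo(21, head = g$head, montage = g$montage,
                                 leadfield = g$lf20)
  expect_lt(d$rel_suppressed, 0.10)
  expect_gt(d$rel_unsuppressed, 0.50)
})
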