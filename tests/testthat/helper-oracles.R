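# Independent oracles and small fixtures used across the suite.

# Closed-form surface potential of a dipole in a homogeneous conducting
# sphere (insulating exterior), assembled from the Legendre generating
# function: V = 2*V_inf + correction terms. SI units throughout.
homogeneous_sphere_potential <- function(R, sigma, r0, m, e) {
  f <- sqrt(sum(r0^2))
  u <- if (f > 1e-12) r0 / f else c(0, 0, 1)
  d <- e - r0
  dn <- sqrt(sum(d * d))
  A <- dn / R
  fh <- f / R
  eh <- e / sqrt(sum(e * e))
  x <- sum(eh * u)
  V_inf <- sum(m * d) / dn^3 / (4 * pi * sigma)
  pref <- 1 / (4 * pi * sigma * R^2)
  term_r <- if (f > 1e-12) sum(m * u) * ((1 / A - 1) / fh) else 0
  term_t <- (sum(m * eh) - sum(m * u) * x) * (A + 1) / (A * (1 - fh * x + A))
  2 * V_inf + pref * (term_r + term_t)
}

# epoch_set with hand-set data on a tiny montage-compatible geometry
tiny_epochs <- function(data, fs = 1000, times = NULL,
                        reference = "average") {
  nch <- dim(data)[1]
  if (is.null(times)) times <- seq(-200, by = 1000 / fs,
                                   length.out = dim(data)[2])
  pos <- cbind(seq_len(nch), 0, 92)
  rownames(pos) <- paste0("ch", seq_len(nch))
  epoch_set(data, times, fs, pos, reference = reference)
}

tiny_evoked <- function(data, fs = 1000, times = NULL,
                        reference = "average", condition = "CI2_left") {
  es <- tiny_epochs(array(data, c(dim(data), 1)), fs, times, reference)
  structure(list(data = data, times = es$times, fs = fs,
                 n_epochs_included = 1L, condition = condition,
                 channel_positions = es$channel_positions,
                 reference = reference,
                 bad_channels = rep(FALSE, dim(data)[1]),
                 metadata = list()),
            class = "evoked")
}

# trivial spatial filters picking out single channels (identity rows)
identity_filters <- function(n_voxels, n_channels, grid = NULL) {
  W <- diag(1, n_voxels, n_channels)
  if (is.null(grid)) grid <- cbind(seq_len(n_voxels) * 10 - 100, 0, 0)
  structure(list(W = W, orientations = matrix(0, n_voxels, 3),
                 grid = grid, spacing = 10,
                 flagged = rep(FALSE, n_voxels)),
            class = "spatial_filters")
}

cohort_fixture_path <- function() {
  system.file("extdata", "cohort_table1.csv", package = "cibalance")
}

# shared forward geometry, computed once per test run
shared_geom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      head <- build_head_model()
      montage <- ten_ten_montage()
      cache <<- list(head = head, montage = montage,
                     lf20 = compute_leadfield(head, montage,
                                              grid_spacing = 20))
    }
    cache
  }
})
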