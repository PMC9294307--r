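#' Zero-phase band-pass filter an epoch set
#'
#' 4th-order Butterworth band-pass applied with zero phase so component
#' latencies are preserved. The default realization applies the filter's
#' magnitude-squared response (identical to forward-backward filtering) in
#' the frequency domain with whole-epoch reflection padding, which processes
#' all channels and trials in one pass; `method = "filtfilt"` runs
#' [signal::filtfilt()] per channel and trial instead. The analysis band is
#' 1-30 Hz by default.
#'
#' @param epochs An [epoch_set()].
#' @param low,high Band edges in Hz; require `0 < low < high < fs/2`.
#' @param order Butterworth order of the prototype (default 4).
#' @param method `"fft"` (vectorized zero-phase, default) or `"filtfilt"`.
#' @return The filtered `epoch_set`.
#' @export
bandpass_filter <- function(epochs, low = 1, high = 30, order = 4,
                            method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("configuration error: need 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- epochs$data
  dm <- dim(d)
  if (method == "filtfilt") {
    m <- matrix(d, dm[1], dm[2] * dm[3])
    for (tr in seq_len(dm[3])) {
      cols <- ((tr - 1) * dm[2] + 1):(tr * dm[2])
      for (ch in seq_len(dm[1])) {
        m[ch, cols] <- signal::filtfilt(bf, m[ch, cols])
      }
    }
    epochs$data <- array(m, dm)
    return(epochs)
  }
  # At a 1 Hz stimulus rate with 1000 ms epochs the epochs are contiguous
  # segments of the continuous recording, so each channel is filtered as one
  # long record (with reflection padding at the record ends only); this
  # avoids per-epoch edge transients that would make the noise variance
  # non-stationary across the epoch.
  n <- dm[2] * dm[3]
  # columns = channels, rows = the channel's concatenated time series
  x <- matrix(aperm(d, c(2, 3, 1)), nrow = n)
  npad <- min(n, 4L * dm[2])
  xp <- rbind(x[npad:1, , drop = FALSE], x, x[n:(n - npad + 1), , drop = FALSE])
  N <- nrow(xp)
  w <- 2 * pi * (0:(N - 1)) / N
  ew <- exp(-1i * outer(w, 0:(length(bf$b) - 1)))
  H <- drop(ew %*% bf$b) / drop(ew %*% bf$a)
  H2 <- Mod(H)^2                       # zero-phase magnitude response
  Y <- stats::mvfft(xp) * H2
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / N
  out <- y[(npad + 1):(npad + n), , drop = FALSE]
  epochs$data <- aperm(array(out, c(dm[2], dm[3], dm[1])), c(3, 1, 2))
  epochs
}

#' Re-reference an epoch set to the common average
#'
#' Subtracts, at every sample of every trial, the mean over the included
#' (non-bad) channels. Bad channels do not enter the average but are kept in
#' the array (still re-referenced) so channel indexing is stable.
#'
#' @param epochs An [epoch_set()].
#' @param bad_channels Optional logical mask; defaults to the mask stored on
#'   the epoch set.
#' @return The re-referenced `epoch_set` (`reference = "average"`).
#' @export
common_average_reference <- function(epochs, bad_channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(bad_channels)) bad_channels <- epochs$bad_channels
  good <- !bad_channels
  if (sum(good) < 2L)
    stop("validation error: common average reference requires at least 2 good channels")
  d <- epochs$data
  mu <- colMeans(d[good, , , drop = FALSE])  # samples x trials
  epochs$data <- sweep(d, c(2, 3), mu, "-")
  epochs$reference <- "average"
  epochs$bad_channels <- bad_channels
  epochs
}

#' Reject epochs with large excursions in the response window
#'
#' An epoch is rejected iff any included channel exceeds `threshold`
#' microvolts in absolute value anywhere inside `window` (100-800 ms
#' post-stimulus by default). Returns the retained epochs together with a
#' per-epoch log from which every decision can be reproduced.
#'
#' @param epochs An [epoch_set()].
#' @param threshold Amplitude criterion in microvolts (default 100).
#' @param window Assessment window in ms (default `c(100, 800)`).
#' @return List with `epochs` (retained trials) and `log` (data.frame:
#'   `epoch`, `rejected`, `channel`, `extremum_uV`, `latency_ms`).
#' @export
reject_epochs <- function(epochs, threshold = 100, window = c(100, 800)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (threshold <= 0) stop("configuration error: threshold must be positive")
  if (window[1] < min(epochs$times) || window[2] > max(epochs$times) + 1)
    stop("configuration error: window outside epoch support")
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  good_ch <- which(!epochs$bad_channels)
  nt <- dim(epochs$data)[3]
  log <- data.frame(epoch = seq_len(nt), rejected = FALSE,
                    channel = NA_character_, extremum_uV = NA_real_,
                    latency_ms = NA_real_)
  labels <- rownames(epochs$channel_positions)
  if (is.null(labels)) labels <- as.character(seq_len(dim(epochs$data)[1]))
  for (tr in seq_len(nt)) {
    seg <- epochs$data[good_ch, sel, tr, drop = FALSE]
    i <- which.max(abs(seg))
    ext <- seg[i]
    log$extremum_uV[tr] <- ext
    ij <- arrayInd(i, dim(seg)[1:2])
    log$channel[tr] <- labels[good_ch[ij[1]]]
    log$latency_ms[tr] <- epochs$times[sel][ij[2]]
    log$rejected[tr] <- abs(ext) > threshold
  }
  keep <- !log$rejected
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  list(epochs = epochs, log = log)
}

#' Flag flat or noisy channels
#'
#' A channel is flagged if its pooled variance is below `flat_floor`
#' (zero-signal/flat channel) or exceeds `k` times the median channel
#' variance (consistently noisy channel, e.g. high impedance). Variance is
#' assessed inside `window` (100-800 ms by default) so the stimulus
#' artifact, which legitimately dominates implant-side channels early in the
#' epoch, does not masquerade as channel noise.
#'
#' @param epochs An [epoch_set()].
#' @param flat_floor Variance floor in microvolts squared.
#' @param k Noisy-channel multiplier on the median variance (default 10).
#' @param window Assessment window in ms.
#' @return Logical channel mask (`TRUE` = bad), with per-channel variances as
#'   attribute `"variance"`.
#' @export
detect_bad_channels <- function(epochs, flat_floor = 1e-8, k = 10,
                                window = c(100, 800)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  d <- epochs$data[, sel, , drop = FALSE]
  v <- apply(d, 1, function(x) stats::var(as.vector(x)))  # pooled over samples and trials
  med <- stats::median(v)
  mask <- v < flat_floor | (med > 0 & v > k * med)
  attr(mask, "variance") <- v
  mask
}

#' Average accepted epochs into an evoked response
#'
#' Sample-wise mean across trials. A warning is emitted when fewer than
#' `min_epochs` trials contribute (the protocol's minimum per average
#' is 100).
#'
#' @param epochs An [epoch_set()].
#' @param min_epochs Warning threshold on the trial count.
#' @return A list of class `evoked`: `data` (channels x samples), `times`,
#'   `fs`, `n_epochs_included`, `condition`, `channel_positions`,
#'   `reference`, `bad_channels`, `metadata`.
#' @export
average_epochs <- function(epochs, min_epochs = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  nt <- dim(epochs$data)[3]
  if (nt < 1L) stop("validation error: no accepted epochs to average")
  if (nt < min_epochs)
    warning(sprintf("only %d accepted epochs (minimum %d recommended)",
                    nt, min_epochs))
  structure(list(data = rowMeans(epochs$data, dims = 2),
                 times = epochs$times, fs = epochs$fs,
                 n_epochs_included = nt, condition = epochs$condition,
                 channel_positions = epochs$channel_positions,
                 reference = epochs$reference,
                 bad_channels = epochs$bad_channels,
                 metadata = epochs$metadata),
            class = "evoked")
}

#' Global field power of an evoked response
#'
#' Per-sample standard deviation across the included channels — under the
#' common average reference, the spatial root mean square. Requires
#' average-referenced input (GFP is only offset-free there).
#'
#' @param evoked An `evoked` object with `reference == "average"`.
#' @return A list of class `gfp_series`: `values` (microvolts, >= 0),
#'   `times`, plus the baseline summary used by component detection.
#' @export
global_field_power <- function(evoked) {
  stopifnot(inherits(evoked, "evoked"))
  if (!identical(evoked$reference, "average"))
    stop("validation error: global field power requires average-referenced data")
  good <- !evoked$bad_channels
  d <- evoked$data[good, , drop = FALSE]
  mu <- colMeans(d)
  values <- sqrt(colMeans(sweep(d, 2, mu, "-")^2))
  structure(list(values = values, times = evoked$times), class = "gfp_series")
}

#' Detect the first post-artifact component in a GFP waveform
#'
#' Finds the earliest local maximum of the global field power inside the
#' search window `(artifact_offset, search_end]` whose height exceeds the
#' baseline GFP mean plus `prominence` baseline SDs. Labelled `N1` for the
#' mature morphology and `N_CI` for the immature one. Absence of a
#' qualifying peak is an explicit outcome, not an error.
#'
#' @param gfp A `gfp_series` from [global_field_power()].
#' @param artifact_offset End of the stimulus artifact in ms (default 36).
#' @param search_end End of the search window in ms (default 250).
#' @param prominence Floor in baseline SD units above the baseline mean
#'   (default 2).
#' @param rel_height A qualifying peak must also reach this fraction of the
#'   largest GFP value in the search window (default 0.5) — the automated
#'   surrogate for "visually identifiable".
#' @param morphology Determines the component label.
#' @param baseline Baseline window in ms for the floor (default
#'   `c(-200, -80)`).
#' @return A list: `component_found`, `latency_ms`, `label`, `value`.
#' @export
find_first_component <- function(gfp, artifact_offset = 36, search_end = 250,
                                 prominence = 2, rel_height = 0.5,
                                 morphology = c("mature_P1N1P2",
                                                "immature_NciPci"),
                                 baseline = c(-200, -80)) {
  morphology <- match.arg(morphology)
  stopifnot(inherits(gfp, "gfp_series"))
  if (search_end <= artifact_offset)
    stop("configuration error: empty component search window")
  label <- if (morphology == "mature_P1N1P2") "N1" else "N_CI"
  v <- gfp$values; tms <- gfp$times
  base <- v[tms >= baseline[1] & tms <= baseline[2]]
  floor_val <- mean(base) + prominence * stats::sd(base)
  sel <- which(tms > artifact_offset & tms <= search_end)
  none <- list(component_found = FALSE, latency_ms = NA_real_,
               label = label, value = NA_real_)
  if (length(sel) < 3L) return(none)
  floor_val <- max(floor_val, rel_height * max(v[sel]))
  for (i in sel[-c(1, length(sel))]) {
    if (v[i] >= v[i - 1] && v[i] > v[i + 1] && v[i] > floor_val) {
      return(list(component_found = TRUE, latency_ms = tms[i],
                  label = label, value = v[i]))
    }
  }
  none
}

#' Scalp topography averaged around a peak latency
#'
#' Per-channel mean over the window `[latency - w/2, latency + w/2]`
#' (default 5 ms, the surface-map convention).
#'
#' @param evoked An `evoked` object.
#' @param latency Center latency in ms.
#' @param window Window width in ms (0 gives the single-sample map).
#' @return Named numeric vector, one value per channel (microvolts).
#' @export
peak_topography <- function(evoked, latency, window = 5) {
  stopifnot(inherits(evoked, "evoked"), window >= 0)
  lo <- latency - window / 2
  hi <- latency + window / 2
  if (lo < min(evoked$times) || hi > max(evoked$times))
    stop("domain error: topography window outside the epoch")
  sel <- evoked$times >= lo & evoked$times <= hi
  out <- rowMeans(evoked$data[, sel, drop = FALSE])
  names(out) <- rownames(evoked$channel_positions)
  out
}

#' Standard sensor-space preprocessing for one epoch set
#'
#' Applies the pipeline in its fixed order: band-pass filter, epoch
#' rejection, bad-channel detection, common average reference, averaging.
#'
#' @param epochs An [epoch_set()].
#' @param low,high Filter band (Hz).
#' @param threshold Rejection criterion (microvolts).
#' @param min_epochs Minimum trials before a warning.
#' @return List: `evoked`, `epochs` (the filtered, rejected,
#'   average-referenced trials), `rejection_log`, `bad_channels`.
#' @export
preprocess_epochs <- function(epochs, low = 1, high = 30, threshold = 100,
                              min_epochs = 100) {
  filt <- bandpass_filter(epochs, low, high)
  bad <- detect_bad_channels(filt)
  filt$bad_channels <- as.logical(bad)
  rej <- reject_epochs(filt, threshold = threshold)
  car <- common_average_reference(rej$epochs)
  evo <- average_epochs(car, min_epochs = min_epochs)
  list(evoked = evo, epochs = car, rejection_log = rej$log,
       bad_channels = bad)
}
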