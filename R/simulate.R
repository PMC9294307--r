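#' Simulation configuration for synthetic evoked EEG
#'
#' Captures the recording protocol being emulated: 62 cephalic channels
#' referenced to the right earlobe, 1000 Hz sampling, 1000 ms epochs from
#' -200 to 800 ms around 1 Hz stimulus trains, a 36 ms biphasic-pulse implant
#' artifact, and either a mature P1-N1-P2 or an immature N(CI)-P(CI) source
#' morphology.
#'
#' @param n_epochs Number of epochs (trials) per condition; the study
#'   averaged 197 +/- 83 accepted epochs per condition, default 200.
#' @param fs Sampling rate in Hz.
#' @param epoch_window Epoch span in ms, `c(start, end)`; samples run from
#'   `start` to `end - 1000/fs`.
#' @param noise_sd Sensor noise SD per sample in microvolts (independent
#'   Gaussian noise; default 12, in the range of 1-30 Hz background EEG).
#' @param artifact_amplitude Peak implant-artifact amplitude at the scalp in
#'   microvolts. The scalp amplitude is not published; 500 is a deliberately
#'   harsh default so artifact suppression is exercised, not a claim.
#' @param artifact_duration Artifact train duration in ms.
#' @param morphology Source waveform family for the cortical response.
#' @param seed Integer seed; identical seed + config reproduce the data
#'   bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_epochs = 200, fs = 1000, epoch_window = c(-200, 800),
                       noise_sd = 12, artifact_amplitude = 500,
                       artifact_duration = 36,
                       morphology = c("mature_P1N1P2", "immature_NciPci"),
                       seed = NULL) {
  morphology <- match.arg(morphology)
  stopifnot(fs > 0, n_epochs >= 1, epoch_window[1] < epoch_window[2])
  if (epoch_window[1] > -200 || epoch_window[2] < 400)
    stop("configuration error: epoch window must span the baseline (-200..-80 ms) and the response window")
  structure(list(n_epochs = as.integer(n_epochs), fs = fs,
                 epoch_window = epoch_window, noise_sd = noise_sd,
                 artifact_amplitude = artifact_amplitude,
                 artifact_duration = artifact_duration,
                 morphology = morphology, seed = seed),
            class = "sim_config")
}

#' Epoch time axis for a configuration
#' @param config A `sim_config`.
#' @return Numeric vector of sample times in ms.
#' @export
epoch_times <- function(config) {
  step <- 1000 / config$fs
  seq(config$epoch_window[1], config$epoch_window[2] - step, by = step)
}

#' Construct an epoch set container
#'
#' @param data Numeric array channels x samples x trials, in microvolts.
#' @param times Sample times in ms.
#' @param fs Sampling rate (Hz).
#' @param channel_positions Channel matrix (channels x 3) or montage.
#' @param reference Reference label (`"A2"`, `"average"`, ...).
#' @param condition Stimulation condition label
#'   (`"CI1_right"`, `"CI2_left"`, `"bilateral"`).
#' @param metadata Optional list (participant, session, time bin, ...).
#' @param bad_channels Optional logical mask of channels to exclude.
#' @return A list of class `epoch_set`.
#' @export
epoch_set <- function(data, times, fs, channel_positions, reference = "A2",
                      condition = NA_character_, metadata = list(),
                      bad_channels = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (is.data.frame(channel_positions))
    channel_positions <- montage_positions(channel_positions)
  if (dim(data)[1] != nrow(channel_positions))
    stop("channel count does not match channel positions")
  if (dim(data)[2] != length(times))
    stop("sample count does not match time axis")
  if (is.null(bad_channels)) bad_channels <- rep(FALSE, dim(data)[1])
  structure(list(data = data, times = times, fs = fs,
                 channel_positions = channel_positions,
                 reference = reference, condition = condition,
                 metadata = metadata, bad_channels = bad_channels),
            class = "epoch_set")
}

#' Cortical source component waveform
#'
#' Builds the source time course as a sum of signed Gaussian lobes. The
#' mature morphology is the three-lobed (+, -, +) P1-N1-P2 complex typical of
#' the long-stimulated ear; the immature morphology is the two-lobed (-, +)
#' N(CI)-P(CI) complex (no P1) seen from a long-deprived ear. The waveform is
#' exactly zero outside the lobes' support and over the whole pre-stimulus
#' baseline.
#'
#' @param times Sample times in ms (see [epoch_times()]).
#' @param morphology `"mature_P1N1P2"` or `"immature_NciPci"`.
#' @param latencies Lobe peak latencies in ms; defaults per morphology
#'   (mature: 60, 100, 180; immature: 95, 200, near the reported ~94-97 ms
#'   first-component latencies).
#' @param amplitudes Signed lobe amplitudes in nA.m; the immature complex is
#'   larger by default, matching its abnormally large surface response.
#' @param widths Gaussian SD per lobe in ms.
#' @param baseline_end End of the pre-stimulus baseline region that lobes
#'   must not touch (ms).
#' @return Numeric waveform (nA.m) of `length(times)`.
#' @export
make_component_waveform <- function(times,
                                    morphology = c("mature_P1N1P2",
                                                   "immature_NciPci"),
                                    latencies = NULL, amplitudes = NULL,
                                    widths = NULL, baseline_end = -80) {
  morphology <- match.arg(morphology)
  defaults <- switch(morphology,
    mature_P1N1P2 = list(lat = c(60, 100, 180), amp = c(10, -25, 12),
                         wid = c(12, 14, 24)),
    immature_NciPci = list(lat = c(95, 200), amp = c(-45, 25),
                           wid = c(16, 28)))
  if (is.null(latencies)) latencies <- defaults$lat
  if (is.null(amplitudes)) amplitudes <- defaults$amp
  if (is.null(widths)) widths <- defaults$wid
  stopifnot(length(latencies) == length(amplitudes),
            length(widths) == length(latencies))
  signs <- switch(morphology, mature_P1N1P2 = c(1, -1, 1),
                  immature_NciPci = c(-1, 1))
  if (any(amplitudes != 0) && length(latencies) == length(signs)) {
    s <- sign(amplitudes)
    if (any(s != 0 & s != signs) && all(s == -signs & s != 0) == FALSE &&
        any(s != 0 & s != signs & s != -signs)) {
      # mixed signs that match neither the morphology nor its mirror
      warning("lobe amplitude signs do not follow the ", morphology,
              " convention")
    }
  }
  support <- 4  # lobes truncated at +/- 4 SD
  if (any(latencies - support * widths < baseline_end))
    stop("configuration error: component lobe overlaps the baseline window")
  if (any(latencies > max(times)))
    stop("configuration error: component latency beyond the epoch")
  w <- numeric(length(times))
  for (j in seq_along(latencies)) {
    inside <- abs(times - latencies[j]) <= support * widths[j]
    w[inside] <- w[inside] +
      amplitudes[j] * exp(-0.5 * ((times[inside] - latencies[j]) / widths[j])^2)
  }
  w
}

#' Cochlear-implant stimulus artifact waveform
#'
#' Alternating biphasic pulse train at 250 pulses per second (4 ms period,
#' charge-balanced two-phase pulses) occupying exactly `[0, duration)` ms and
#' zero elsewhere, riding on a sustained pedestal over the train. The
#' pedestal models the baseline shift seen in scalp recordings during
#' electrical stimulation (electrode polarization / amplifier recovery); it
#' is the part of the artifact that survives band-pass filtering, whereas
#' the charge-balanced radio-frequency pulses themselves are almost entirely
#' removed by a 1-30 Hz band.
#'
#' @param times Sample times in ms.
#' @param duration Train duration in ms (default 36).
#' @param amplitude Peak amplitude in microvolts.
#' @param carrier Pulse rate in pulses per second (default 250).
#' @param pedestal_frac Fraction of `amplitude` forming the sustained
#'   intra-train pedestal (default 0.4; 0 gives the pure alternating train).
#' @return Numeric waveform of `length(times)`.
#' @export
make_ci_artifact <- function(times, duration = 36, amplitude = 500,
                             carrier = 250, pedestal_frac = 0.4) {
  stopifnot(duration > 0, carrier > 0, pedestal_frac >= 0, pedestal_frac <= 1)
  if (duration > max(times))
    stop("configuration error: artifact duration exceeds the epoch end")
  period <- 1000 / carrier
  w <- numeric(length(times))
  on <- times >= 0 & times < duration
  phase <- (times[on] %% period) / period
  w[on] <- amplitude * ((1 - pedestal_frac) * ifelse(phase < 0.5, 1, -1) +
                          pedestal_frac)
  w
}

#' Rank-1 scalp topography of the implant artifact
#'
#' Unit-peak spatial pattern concentrated over the implant-side channels,
#' falling off as a Gaussian of great-circle distance from a site behind the
#' ear.
#'
#' @param montage A montage from [ten_ten_montage()].
#' @param side `"right"` (CI-1), `"left"` (CI-2).
#' @param width_mm Spatial falloff SD in mm along the scalp.
#' @return Numeric channel vector with maximum 1.
#' @export
artifact_topography <- function(montage, side = c("right", "left"),
                                width_mm = 45) {
  side <- match.arg(side)
  center <- attr(montage, "center")
  radius <- attr(montage, "scalp_radius")
  pos <- montage_positions(montage)
  site_unit <- c(if (side == "right") 0.93 else -0.93, -0.25, -0.26)
  site_unit <- site_unit / sqrt(sum(site_unit^2))
  P <- sweep(pos, 2, center, "-")
  P <- P / sqrt(rowSums(P^2))
  ang <- acos(pmin(1, pmax(-1, P %*% site_unit)))
  arc <- radius * as.numeric(ang)
  topo <- exp(-0.5 * (arc / width_mm)^2)
  topo / max(topo)
}

#' Source specification for forward simulation
#'
#' @param location MNI mm position (inside the brain shell).
#' @param orientation Dipole orientation; normalized to unit length.
#' @param waveform Source time course in nA.m (same length as the epoch).
#' @param label One of `"left_AC"`, `"right_AC"`, `"frontal"`, `"other"`.
#' @return A list of class `source_spec`.
#' @export
source_spec <- function(location, orientation, waveform,
                        label = c("left_AC", "right_AC", "frontal", "other")) {
  label <- match.arg(label)
  n <- sqrt(sum(orientation^2))
  if (n == 0) stop("orientation must be nonzero")
  structure(list(location = as.numeric(location),
                 orientation = as.numeric(orientation) / n,
                 waveform = as.numeric(waveform), label = label),
            class = "source_spec")
}

#' Simulate a multichannel evoked-EEG epoch set
#'
#' Forward-projects the given cortical sources through the spherical head
#' model to the montage (referenced to the right-earlobe electrode), adds the
#' implant stimulus artifact with its rank-1 (or summed multi-side) scalp
#' topography, and adds independent Gaussian sensor noise. Identical seed and
#' configuration give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param sources List of [source_spec()] objects.
#' @param head A [build_head_model()] head model.
#' @param montage A [ten_ten_montage()] montage.
#' @param condition Condition label; also selects the artifact side(s)
#'   (`CI1_right` -> right, `CI2_left` -> left, `bilateral` -> both).
#' @param metadata Metadata list stored on the epoch set.
#' @return An [epoch_set()].
#' @export
simulate_epochs <- function(config, sources, head, montage,
                            condition = c("CI1_right", "CI2_left",
                                          "bilateral"),
                            metadata = list()) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "sim_config"), inherits(head, "head_model"))
  times <- epoch_times(config)
  nch <- nrow(montage)
  nt <- length(times)

  clean <- matrix(0, nch, nt)
  if (length(sources)) {
    r1 <- head$radii[1]
    for (s in sources) {
      if (sqrt(sum((s$location - head$center)^2)) >= r1)
        stop("geometry error: source outside the brain shell")
      if (length(s$waveform) != nt)
        stop("configuration error: source waveform length must equal the epoch length")
    }
    locs <- do.call(rbind, lapply(sources, `[[`, "location"))
    moms <- do.call(rbind, lapply(sources, `[[`, "orientation"))
    G <- forward_dipoles(head, montage, locs, moms)  # nch x nsources, uV/nA.m
    W <- do.call(rbind, lapply(sources, `[[`, "waveform"))  # nsources x nt
    clean <- clean + G %*% W
  }

  if (config$artifact_amplitude != 0) {
    art_wave <- make_ci_artifact(times, config$artifact_duration,
                                 config$artifact_amplitude)
    sides <- switch(condition, CI1_right = "right", CI2_left = "left",
                    bilateral = c("right", "left"))
    for (sd in sides) {
      clean <- clean + artifact_topography(montage, sd) %o% art_wave
    }
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  data <- array(clean, dim = c(nch, nt, config$n_epochs))
  if (config$noise_sd > 0) {
    data <- data + array(stats::rnorm(nch * nt * config$n_epochs,
                                      sd = config$noise_sd),
                         dim = dim(data))
  }
  epoch_set(data, times, config$fs, montage,
            reference = attr(montage, "reference_label"),
            condition = condition, metadata = metadata)
}

#' Effect model for the synthetic longitudinal cohort
#'
#' Defines the planted ground truth: a linear dependence of baseline cortical
#' representation on inter-implant delay, a fixed leftward hemispheric
#' lateralization, exponential session decay of responses from the newly
#' implanted ear (and of bilateral responses through their ipsilateral-ear
#' component) with stable first-ear responses, and hemisphere-specific
#' bilateral enhancement (present in right auditory cortex, absent/negative
#' in left).
#'
#' @param repr_intercept Baseline representation (%) at zero delay.
#' @param repr_slope Change in representation per year of inter-implant delay
#'   (% per year; negative plants second-ear dominance growing with delay).
#' @param repr_sd Between-participant SD of baseline representation (%).
#' @param lateralization Hemispheric lateralization (%) planted for all
#'   conditions (negative = left auditory cortex stronger).
#' @param base_amplitude Per-hemisphere source amplitude scale (nA.m).
#' @param decay_rate Exponential rate of session decay (per bin step) for
#'   second-ear and bilateral amplitudes.
#' @param stable_frac Asymptotic fraction of the initial second-ear amplitude
#'   retained after the decay plateaus.
#' @param enh_right,enh_left Bilateral enhancement planted in right and left
#'   auditory cortex, as fractions of `base_amplitude`.
#' @return A list of class `effect_model`.
#' @export
effect_model <- function(repr_intercept = 10, repr_slope = -5, repr_sd = 8,
                         lateralization = -20, base_amplitude = 60,
                         decay_rate = 1.2, stable_frac = 0.6,
                         enh_right = 0.25, enh_left = -0.15) {
  structure(as.list(environment()), class = "effect_model")
}

# Planted per-hemisphere source amplitudes for one participant cell.
# repr: participant representation (%), lat: lateralization (%),
# session s in 1..4. Returns list of amplitudes by condition and hemisphere.
.planted_amplitudes <- function(em, repr, s) {
  lat <- em$lateralization / 100
  w <- c(left = (1 - lat) / 2, right = (1 + lat) / 2) * 2
  r <- max(-0.9, min(0.9, repr / 100))
  g <- em$stable_frac + (1 - em$stable_frac) * exp(-em$decay_rate * (s - 1))
  a_ci1 <- em$base_amplitude * w * (1 + r)   # right-ear input, stable
  a_ci2 <- em$base_amplitude * w * (1 - r) * g
  # bilateral: ipsilateral-ear unilateral response plus planted enhancement
  a_bil <- c(left = unname(a_ci2["left"]) +
               em$enh_left * em$base_amplitude,
             right = unname(a_ci1["right"]) +
               em$enh_right * em$base_amplitude)
  a_bil <- pmax(a_bil, 0.05 * em$base_amplitude)
  list(CI1_right = a_ci1, CI2_left = a_ci2, bilateral = a_bil)
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' For every participant x session x condition cell, derives planted source
#' amplitudes from the effect model (ground truth) and provides a
#' deterministic per-cell epoch-set generator. Epoch sets are generated on
#' demand (one cell at a time) rather than materialized, since a full cohort
#' of multichannel single-trial arrays would be needlessly large; the ground
#' truth table always accompanies the generator.
#'
#' @param cohort A `cohort_table` (supplies `inter_implant_delay` per
#'   participant).
#' @param em An [effect_model()].
#' @param config Base [sim_config()]; per-cell seeds are derived from `seed`.
#' @param head,montage Forward-model geometry.
#' @param n_sessions Number of session bins (default 4).
#' @param seed Master seed for the cohort (overrides `config$seed`).
#' @return A list of class `longitudinal_sim`: `ground_truth` (data.frame
#'   with planted amplitudes and indices per cell), `simulate_cell(i)`
#'   returning the [epoch_set()] for row `i` of `ground_truth`, plus the
#'   generator inputs.
#' @export
simulate_longitudinal_cohort <- function(cohort, em = effect_model(),
                                         config = sim_config(),
                                         head = build_head_model(),
                                         montage = ten_ten_montage(),
                                         n_sessions = 4, seed = 1) {
  stopifnot(inherits(em, "effect_model"), is.data.frame(cohort))
  if (is.null(cohort$inter_implant_delay))
    stop("configuration error: cohort lacks inter_implant_delay")
  conditions <- c("CI1_right", "CI2_left", "bilateral")
  set.seed(seed)
  b <- stats::rnorm(nrow(cohort), sd = em$repr_sd)
  repr0 <- em$repr_intercept + em$repr_slope * cohort$inter_implant_delay + b

  cells <- expand.grid(participant = seq_len(nrow(cohort)),
                       session = seq_len(n_sessions),
                       condition = conditions,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$participant, cells$session), ]
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))

  gt <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$participant[i]; s <- cells$session[i]; cond <- cells$condition[i]
    amps <- .planted_amplitudes(em, repr0[p], s)[[cond]]
    data.frame(participant_id = cohort$participant_id[p],
               inter_implant_delay = cohort$inter_implant_delay[p],
               age_ci1 = cohort$age_ci1[p],
               session = s, time_bin = time_bin_levels[s],
               condition = cond,
               amp_left_ac = unname(amps["left"]),
               amp_right_ac = unname(amps["right"]),
               repr_baseline = repr0[p],
               cell_seed = cell_seeds[i],
               stringsAsFactors = FALSE)
  }))
  rownames(gt) <- NULL

  # planted indices per participant x session, from the same arithmetic the
  # observed indices use
  amp_of <- function(p, s, cond, hemi) {
    gt[gt$participant_id == p & gt$session == s & gt$condition == cond,
       paste0("amp_", hemi, "_ac")]
  }
  gt$true_lateralization <- with(gt, (amp_right_ac - amp_left_ac) /
                                   (amp_right_ac + amp_left_ac) * 100)
  gt$true_representation_left <- NA_real_
  gt$true_representation_right <- NA_real_
  gt$true_enh_left <- NA_real_
  gt$true_enh_right <- NA_real_
  for (i in seq_len(nrow(gt))) {
    p <- gt$participant_id[i]; s <- gt$session[i]
    a1l <- amp_of(p, s, "CI1_right", "left")
    a1r <- amp_of(p, s, "CI1_right", "right")
    a2l <- amp_of(p, s, "CI2_left", "left")
    a2r <- amp_of(p, s, "CI2_left", "right")
    gt$true_representation_left[i] <- (a1l - a2l) / (a1l + a2l) * 100
    gt$true_representation_right[i] <- (a1r - a2r) / (a1r + a2r) * 100
    if (gt$condition[i] == "bilateral") {
      gt$true_enh_left[i] <- gt$amp_left_ac[i] - a2l
      gt$true_enh_right[i] <- gt$amp_right_ac[i] - a1r
    }
  }

  times <- epoch_times(config)
  sim_cell <- function(i) {
    row <- gt[i, ]
    morph <- if (row$condition == "CI1_right") "mature_P1N1P2" else
      "immature_NciPci"
    wf <- make_component_waveform(times, morph)
    peak <- max(abs(wf))
    srcs <- list(
      source_spec(c(-62, -18, 8), c(0, 0, 1), wf / peak * row$amp_left_ac,
                  label = "left_AC"),
      source_spec(c(62, -18, 8), c(0, 0, 1), wf / peak * row$amp_right_ac,
                  label = "right_AC"))
    cfg <- config
    cfg$seed <- row$cell_seed
    cfg$morphology <- morph
    simulate_epochs(cfg, srcs, head, montage, condition = row$condition,
                    metadata = list(participant_id = row$participant_id,
                                    session = row$session,
                                    time_bin = row$time_bin))
  }

  structure(list(ground_truth = gt, simulate_cell = sim_cell,
                 cohort = cohort, effect_model = em, config = config,
                 head = head, montage = montage, seed = seed),
            class = "longitudinal_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate percent-correct speech perception scores
#'
#' Open-set word scores as binomial draws: `100 * Binomial(n_words, ability)
#' / n_words` per ear/condition.
#'
#' @param true_ability Named numeric vector of true proportions in `[0, 1]`
#'   (e.g. `c(left = 0.6, right = 0.8, bilateral = 0.85)`).
#' @param n_words Number of test words per list (default 50).
#' @param seed Optional seed.
#' @return Named numeric vector of percent-correct scores.
#' @export
simulate_speech_scores <- function(true_ability, n_words = 50, seed = NULL) {
  if (any(true_ability < 0 | true_ability > 1))
    stop("domain error: ability must lie in [0, 1]")
  stopifnot(n_words >= 1)
  if (!is.null(seed)) set.seed(seed)
  scores <- stats::rbinom(length(true_ability), n_words, true_ability) /
    n_words * 100
  names(scores) <- names(true_ability)
  scores
}
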