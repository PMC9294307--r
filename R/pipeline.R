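#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic analysis. Defaults are
#' the package's analysis-scale choices: 10 mm source grid, 60 epochs per
#' simulated condition, omnibus level 0.05.
#'
#' @param seed Master seed; `NULL` draws one and records it in the log.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   writing.
#' @param cohort_path Delimited-text cohort table; defaults to the packaged
#'   13-participant table.
#' @param grid_mm Source-grid spacing in mm.
#' @param n_epochs Simulated epochs per condition.
#' @param n_sessions Longitudinal sessions per participant.
#' @param alpha Omnibus level.
#' @param noise_sd Sensor noise SD (microvolts).
#' @param effects An [effect_model()].
#' @param n_resamples Omnibus resamples per evoked response.
#' @param write_figures Write trajectory figures (PNG) to `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = NULL, out_dir = NULL, cohort_path = NULL,
                            grid_mm = 10, n_epochs = 60, n_sessions = 4,
                            alpha = 0.05, noise_sd = 12,
                            effects = effect_model(), n_resamples = 200,
                            write_figures = FALSE) {
  if (is.null(cohort_path))
    cohort_path <- system.file("extdata", "cohort_table1.csv",
                               package = "cibalance")
  structure(list(seed = seed, out_dir = out_dir, cohort_path = cohort_path,
                 grid_mm = grid_mm, n_epochs = n_epochs,
                 n_sessions = n_sessions, alpha = alpha, noise_sd = noise_sd,
                 effects = effects, n_resamples = n_resamples,
                 write_figures = write_figures),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; an
#' `effects:` block maps onto [effect_model()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  eff <- do.call(effect_model, y$effects %||% list())
  y$effects <- NULL
  do.call(pipeline_config, c(y, list(effects = eff)))
}

#' Run the end-to-end synthetic analysis
#'
#' Executes the full chain: cohort ingest, longitudinal simulation with
#' known ground truth, sensor-space preprocessing, beamformer source
#' localization with omnibus correction, auditory-ROI peak extraction,
#' hemispheric index computation, and the four longitudinal mixed models
#' with estimated marginal means. Identical configuration and seed reproduce
#' the index table byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-stage progress.
#' @return A list of class `pipeline_result`: `cohort`, `ground_truth`,
#'   `peaks`, `indices` (wide + long), `models` (fits, anova tables, EMMs),
#'   `log` (character vector), `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  log <- c(sprintf("cibalance run, seed %d", seed),
           sprintf("R %s, grid %g mm, %d epochs, alpha %g",
                   getRversion(), config$grid_mm, config$n_epochs,
                   config$alpha),
           sprintf("time bins (days): %s",
                   paste(names(time_bin_breaks), time_bin_breaks,
                         sep = "<=", collapse = ", ")))
  say <- function(...) if (progress) message(sprintf(...))

  stage <- "cohort"
  result <- tryCatch({
    say("[cohort] loading %s", config$cohort_path)
    cohort <- load_cohort(config$cohort_path)

    stage <- "simulate"
    head <- build_head_model()
    montage <- ten_ten_montage()
    sim_cfg <- sim_config(n_epochs = config$n_epochs,
                          noise_sd = config$noise_sd)
    sim <- simulate_longitudinal_cohort(cohort, em = config$effects,
                                        config = sim_cfg, head = head,
                                        montage = montage,
                                        n_sessions = config$n_sessions,
                                        seed = seed)
    gt <- sim$ground_truth

    stage <- "localize"
    lf <- compute_leadfield(head, montage, grid_spacing = config$grid_mm)
    peak_rows <- vector("list", 2L * nrow(gt))
    for (i in seq_len(nrow(gt))) {
      say("[localize] cell %d/%d", i, nrow(gt))
      ep <- sim$simulate_cell(i)
      pp <- preprocess_epochs(ep, min_epochs = min(100, config$n_epochs))
      loc <- localize_evoked(pp$epochs, pp$evoked, lf,
                             alpha = config$alpha,
                             n_resamples = config$n_resamples)
      for (h in c("left", "right")) {
        pk <- loc$peaks[[h]]
        peak_rows[[2L * (i - 1L) + (h == "right") + 1L]] <- data.frame(
          participant_id = gt$participant_id[i], session = gt$session[i],
          time_bin = gt$time_bin[i], condition = gt$condition[i],
          hemisphere = h, x = pk$voxel[1], y = pk$voxel[2], z = pk$voxel[3],
          pz = pk$pz, pz_corrected = pk$pz_corrected,
          significant = pk$significant,
          component_latency = loc$component$latency_ms,
          stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, peak_rows)
    rownames(peaks) <- NULL

    stage <- "indices"
    idx <- build_index_table(peaks)
    covars <- cohort[c("participant_id", "age_ci1", "inter_implant_delay")]
    wide <- merge(idx$wide, covars, by = "participant_id", sort = FALSE)
    wide <- wide[order(wide$participant_id, wide$session), ]
    rownames(wide) <- NULL

    stage <- "models"
    models <- fit_standard_models(wide)

    list(cohort = cohort, ground_truth = gt, peaks = peaks,
         indices = list(wide = wide, long = idx$long), models = models,
         log = log, seed = seed)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wrt <- function(df, name)
      utils::write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
    wrt(result$peaks, "peaks.csv")
    wrt(result$indices$wide, "indices_wide.csv")
    wrt(result$indices$long, "indices_long.csv")
    wrt(summarize_cohort(result$cohort), "cohort_summary.csv")
    jsonlite::write_json(
      lapply(result$models, function(m)
        list(anova = m$anova, variance_components = m$fit$variance_components,
             converged = m$fit$converged)),
      file.path(config$out_dir, "models.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    writeLines(result$log, file.path(config$out_dir, "run_log.txt"))
    if (config$write_figures) {
      for (m in names(result$models)) {
        p <- plot_index_trajectories(result$indices$wide, result$models[[m]])
        if (!is.null(p))
          ggplot2::ggsave(file.path(config$out_dir, paste0(m, ".png")), p,
                          width = 7, height = 4, dpi = 120)
      }
    }
  }
  structure(result, class = "pipeline_result")
}

# stacks the wide index table into the long layouts the four standard
# longitudinal models use
.stack_measures <- function(wide, cols, factors) {
  do.call(rbind, lapply(seq_along(cols), function(j) {
    d <- wide[c("participant_id", "session", "time_bin", "age_ci1",
                "inter_implant_delay")]
    d$value <- wide[[cols[j]]]
    for (f in names(factors)) d[[f]] <- factors[[f]][j]
    d
  }))
}

#' Fit the four standard longitudinal models
#'
#' Model 1: cortical response strength (corrected pseudo-Z) ~
#' time x condition x hemisphere. Model 2: cortical lateralization ~
#' time x condition. Model 3: cortical representation ~ time x hemisphere.
#' Model 4: bilateral enhancement ~ time x hemisphere. All covary for age at
#' CI-1 and inter-implant delay with a participant random intercept, and
#' report Type-III Satterthwaite F tests plus estimated marginal means.
#'
#' @param wide Wide index table (from [run_pipeline()] internals or
#'   [build_index_table()] merged with cohort covariates).
#' @return Named list per model: `fit`, `anova`, `emm`.
#' @export
fit_standard_models <- function(wide) {
  pz_long <- .stack_measures(
    wide,
    c("pz_ci1_left", "pz_ci1_right", "pz_ci2_left", "pz_ci2_right",
      "pz_bil_left", "pz_bil_right"),
    list(condition = rep(c("CI1_right", "CI2_left", "bilateral"), each = 2),
         hemisphere = rep(c("left", "right"), 3)))
  lat_long <- .stack_measures(
    wide, c("lateralization_ci1", "lateralization_ci2", "lateralization_bil"),
    list(condition = c("CI1_right", "CI2_left", "bilateral")))
  rep_long <- .stack_measures(
    wide, c("representation_left", "representation_right"),
    list(hemisphere = c("left", "right")))
  enh_long <- .stack_measures(
    wide, c("enhancement_left", "enhancement_right"),
    list(hemisphere = c("left", "right")))

  fits <- list(
    activation = list(data = pz_long,
                      fixed = "time_bin * condition * hemisphere",
                      emm = c("time_bin", "condition")),
    lateralization = list(data = lat_long, fixed = "time_bin * condition",
                          emm = c("condition")),
    representation = list(data = rep_long, fixed = "time_bin * hemisphere",
                          emm = c("time_bin", "hemisphere")),
    enhancement = list(data = enh_long, fixed = "time_bin * hemisphere",
                       emm = c("hemisphere")))
  lapply(fits, function(f) {
    fit <- fit_lmm(f$data, "value", f$fixed)
    an <- tryCatch(anova_table(fit), error = function(e) {
      warning("F tests unavailable: ", conditionMessage(e))
      NULL
    })
    em <- tryCatch(estimated_marginal_means(fit, f$emm),
                   error = function(e) NULL)
    list(fit = fit, anova = an, emm = em)
  })
}

#' Plot index trajectories with estimated marginal means
#'
#' Per-participant values over the four time bins with the model EMMs
#' (white points, +/- 1 SE bars) overlaid — the longitudinal panel layout
#' used for all cortical indices.
#'
#' @param wide Wide index table.
#' @param model One element of [fit_standard_models()] output.
#' @return A ggplot object, or `NULL` when the model's EMMs lack a time
#'   factor.
#' @export
plot_index_trajectories <- function(wide, model) {
  emm <- model$emm
  if (!"time_bin" %in% names(emm)) return(NULL)
  d <- model$fit$data
  facet <- intersect(c("condition", "hemisphere"), names(emm))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_bin,
                                       y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_pointrange(
      data = emm,
      ggplot2::aes(y = .data$emmean, ymin = .data$emmean - .data$SE,
                   ymax = .data$emmean + .data$SE),
      shape = 21, fill = "white", linewidth = 0.8) +
    ggplot2::labs(x = "time since CI-2 activation",
                  y = model$fit$response) +
    ggplot2::theme_minimal()
  if (length(facet))
    p <- p + ggplot2::facet_wrap(stats::as.formula(
      paste("~", paste(facet, collapse = "+"))))
  p
}

#' End-to-end recovery of the representation-vs-delay slope
#'
#' Simulates the baseline session of a cohort (unilateral conditions only),
#' runs every epoch set through preprocessing, beamforming, omnibus
#' correction and ROI peak extraction, computes each participant's cortical
#' representation of input, and regresses it on inter-implant delay
#' (covarying for age at first implantation). Used to verify that the
#' planted negative dependence of second-ear dominance on delay survives the
#' whole measurement chain.
#'
#' @param seed Seed for the simulated cohort.
#' @param cohort A `cohort_table` (defaults to the packaged table).
#' @param em Effect model (defaults to [effect_model()]).
#' @param leadfield Optional precomputed lead field (saves time across
#'   repeated calls); must match `head`/`montage`.
#' @param head,montage Forward geometry.
#' @param grid_mm Grid spacing when `leadfield` is `NULL`.
#' @param n_epochs Epochs per condition.
#' @param noise_sd Sensor noise SD. The default pairs with `n_epochs` so the
#'   evoked-average noise level (`noise_sd / sqrt(n_epochs)` = 0.86 uV)
#'   matches a full-length session (about 200 epochs at 12 uV) at a fraction
#'   of the simulation cost.
#' @return A list: `slope` (fitted representation change per year of
#'   delay), `true_slope`, `table` (per participant x hemisphere), `model`.
#' @export
representation_slope_recovery <- function(seed, cohort = NULL,
                                          em = effect_model(),
                                          leadfield = NULL,
                                          head = build_head_model(),
                                          montage = ten_ten_montage(),
                                          grid_mm = 20, n_epochs = 16,
                                          noise_sd = 3.44) {
  if (is.null(cohort))
    cohort <- load_cohort(system.file("extdata", "cohort_table1.csv",
                                      package = "cibalance"))
  if (is.null(leadfield))
    leadfield <- compute_leadfield(head, montage, grid_spacing = grid_mm)
  cfg <- sim_config(n_epochs = n_epochs, noise_sd = noise_sd)
  sim <- simulate_longitudinal_cohort(cohort, em = em, config = cfg,
                                      head = head, montage = montage,
                                      n_sessions = 1, seed = seed)
  gt <- sim$ground_truth
  sel <- which(gt$condition %in% c("CI1_right", "CI2_left"))
  pz <- array(NA_real_, c(nrow(cohort), 2, 2),
              dimnames = list(cohort$participant_id, c("left", "right"),
                              c("CI1_right", "CI2_left")))
  for (i in sel) {
    ep <- sim$simulate_cell(i)
    pp <- preprocess_epochs(ep, min_epochs = min(100, n_epochs))
    loc <- localize_evoked(pp$epochs, pp$evoked, leadfield)
    for (h in c("left", "right")) {
      pk <- loc$peaks[[h]]
      pz[gt$participant_id[i], h, gt$condition[i]] <-
        apply_subthreshold_rule(pk, quiet = TRUE)
    }
  }
  tab <- do.call(rbind, lapply(c("left", "right"), function(h) {
    data.frame(participant_id = cohort$participant_id,
               hemisphere = h,
               representation = cortical_representation(
                 pz[, h, "CI1_right"], pz[, h, "CI2_left"]),
               inter_implant_delay = cohort$inter_implant_delay,
               age_ci1 = cohort$age_ci1,
               stringsAsFactors = FALSE)
  }))
  fit <- stats::lm(representation ~ inter_implant_delay + age_ci1,
                   data = tab)
  list(slope = unname(stats::coef(fit)["inter_implant_delay"]),
       true_slope = em$repr_slope, table = tab, model = fit)
}

#' Export an evoked average to delimited text
#'
#' @param evoked An `evoked` object.
#' @param path Output CSV path (first column `time_ms`, one column per
#'   channel).
#' @return `path`, invisibly.
#' @export
write_evoked <- function(evoked, path) {
  stopifnot(inherits(evoked, "evoked"))
  d <- t(evoked$data)
  colnames(d) <- rownames(evoked$channel_positions)
  utils::write.csv(cbind(time_ms = evoked$times, as.data.frame(d)), path,
                   row.names = FALSE)
  invisible(path)
}
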