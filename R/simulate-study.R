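# Whole-study simulation: participants x exercises x stages, simulated
# expert ratings, and the lightweight metric-level simulator used for
# statistical calibration.

#' Expert-rating simulation model
#'
#' Raters score a latent quality built from weighted, standardized
#' performance metrics, plus a small per-rater bias (absolute-agreement
#' structure) and per-score noise, cut at fixed ordered thresholds into
#' the 1-7 Likert scale.
#'
#' @param weights named per-metric contributions to the latent quality.
#'   Defaults reward elbow use, smoothness and synchronization and
#'   penalize bow-position distance, matching the direction of the
#'   metric-rating correlations reported for this task.
#' @param noise_sd latent-scale per-score rater noise.
#' @param rater_bias_sd SD of the per-rater constant bias.
#' @param thresholds 6 strictly increasing cutpoints mapping the latent
#'   score to the ordinal 1-7 scale.
#' @return object of class `rating_model`.
#' @export
rating_model <- function(weights = c(m2 = 0.8, m14 = -1, m15 = 0.6,
                                     m16 = 0.5),
                         noise_sd = 0.61, rater_bias_sd = 0.2,
                         thresholds = c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5)) {
  stopifnot(all(diff(thresholds) > 0), length(thresholds) == 6,
            noise_sd >= 0, rater_bias_sd >= 0)
  structure(list(weights = weights, noise_sd = noise_sd,
                 rater_bias_sd = rater_bias_sd, thresholds = thresholds),
            class = "rating_model")
}

#' Simulate expert panel ratings from a metric table
#'
#' Builds one video per (participant, exercise, stage in S1/S3) trial and
#' scores it with `n_raters` simulated raters under the given
#' [rating_model()].
#'
#' @param metric_table tidy metric table (see [metrics_to_table()]).
#' @param model a [rating_model()].
#' @param seed integer seed.
#' @param n_raters rater count (the study panel had 5).
#' @return a [rating_matrix()].
#' @export
simulate_ratings <- function(metric_table, model = rating_model(), seed = 1,
                             n_raters = 5) {
  mt <- metric_table[metric_table$stage %in% c("S1", "S3"), ]
  vids <- unique(mt[, c("participant", "group", "exercise", "stage")])
  vids <- vids[order(vids$participant, vids$exercise, vids$stage), ]
  latent <- rep(0, nrow(vids))
  key <- function(d) paste(d$participant, d$exercise, d$stage)
  vkey <- key(vids)
  for (id in names(model$weights)) {
    sub <- mt[mt$metric_id == id, ]
    v <- sub$value[match(vkey, key(sub))]
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    z[!is.finite(z)] <- 0
    latent <- latent + model$weights[[id]] * z
  }
  if (stats::sd(latent) > 0) latent <- latent / stats::sd(latent)
  set.seed(seed)
  bias <- stats::rnorm(n_raters, 0, model$rater_bias_sd)
  scores <- matrix(0L, nrow(vids), n_raters)
  for (r in seq_len(n_raters)) {
    x <- latent + bias[r] + stats::rnorm(nrow(vids), 0, model$noise_sd)
    scores[, r] <- as.integer(cut(x, c(-Inf, model$thresholds, Inf)))
  }
  rating_matrix(scores, vids)
}

#' Default deviation profiles of the simulated study
#'
#' The study conditions the generator emulates: both groups start as
#' equally poor novices at baseline, improve with training, and the
#' haptic group (AVE) trains under the viscous-elastic field and retains
#' a larger improvement at recall - the direction of the study's
#' Group-by-Stage findings. Magnitudes are modelling choices documented
#' in the methods vignette.
#'
#' @return nested list `profiles[[group]][[stage]]` of
#'   [participant_profile()] objects.
#' @export
default_study_profiles <- function() {
  list(
    AV = list(
      S1 = participant_profile(0.70, lag = 0.15, timing_jitter_sd = 0.08,
                               smoothness_noise_sd = 0.020,
                               profile_noise_sd = 3.5,
                               coordination_scale = 0.75,
                               coordination_jitter_sd = 4),
      S2 = participant_profile(0.80, lag = 0.10, timing_jitter_sd = 0.06,
                               smoothness_noise_sd = 0.015,
                               profile_noise_sd = 3.0,
                               coordination_scale = 0.85,
                               coordination_jitter_sd = 3.5),
      S3 = participant_profile(0.85, lag = 0.06, timing_jitter_sd = 0.05,
                               smoothness_noise_sd = 0.012,
                               profile_noise_sd = 3.0,
                               coordination_scale = 0.9,
                               coordination_jitter_sd = 3.5)),
    AVE = list(
      S1 = participant_profile(0.70, lag = 0.15, timing_jitter_sd = 0.08,
                               smoothness_noise_sd = 0.020,
                               profile_noise_sd = 3.5,
                               coordination_scale = 0.75,
                               coordination_jitter_sd = 4),
      S2 = participant_profile(0.80, lag = 0.10, timing_jitter_sd = 0.06,
                               smoothness_noise_sd = 0.015,
                               profile_noise_sd = 3.0,
                               coordination_scale = 0.85,
                               coordination_jitter_sd = 3.5,
                               guidance = guidance_params(200)),
      S3 = participant_profile(0.92, lag = 0.04, timing_jitter_sd = 0.04,
                               smoothness_noise_sd = 0.010,
                               profile_noise_sd = 2.5,
                               coordination_scale = 0.95,
                               coordination_jitter_sd = 3)))
}

# scale a profile's deviations by a participant skill factor
scale_profile <- function(p, f) {
  participant_profile(
    amplitude_scale = min(1, 1 - (1 - p$amplitude_scale) * f),
    lag = p$lag * f,
    timing_jitter_sd = p$timing_jitter_sd * f,
    smoothness_noise_sd = p$smoothness_noise_sd * f,
    profile_noise_sd = p$profile_noise_sd * f,
    coordination_scale = min(1, 1 - (1 - p$coordination_scale) * f),
    coordination_jitter_sd = p$coordination_jitter_sd * f,
    guidance = p$guidance)
}

# derive participant kinematics either from the emitted markers (the
# honest end-to-end path) or directly from the generated state
trial_kinematics <- function(gen, through_markers = TRUE) {
  if (through_markers) {
    list(angles = joint_angles(gen$markers), trace = bow_trace(gen$markers))
  } else {
    list(angles = gen$angles, trace = gen$trace)
  }
}

#' Simulate a complete study
#'
#' Generates the full factorial: `n_per_group` participants per group,
#' three exercises, three stages; AVE trains (stage S2) under the
#' viscous-elastic guidance field, AV without. Participant trajectories
#' are pushed through the analysis pipeline (markers, joint angles, bow
#' trace, metrics) against the teacher's reference; expert ratings are
#' produced for the S1/S3 videos by simulated raters. Per-participant
#' skill heterogeneity multiplies all deviation magnitudes by a
#' log-normal factor. Every generative parameter and analytic expected
#' metric value is logged in the ground-truth table.
#'
#' @param n_per_group participants per group (the study had 12).
#' @param profiles nested `[[group]][[stage]]` profile map, see
#'   [default_study_profiles()].
#' @param model a [rating_model()].
#' @param seed master seed; all substreams derive from it.
#' @param exercises exercise ids to include.
#' @param tempo stroke duration (s).
#' @param skill_sd SD of the log skill factor (0 disables heterogeneity).
#' @param through_markers run the marker-level pipeline (default);
#'   `FALSE` short-circuits to the generated kinematics (faster, used
#'   for exploratory work).
#' @param marker_noise_sd additive marker noise (mm).
#' @param trial_sink optional callback `function(gen, teacher, meta)`
#'   invoked for every generated trial, e.g. to write marker files.
#' @return list with `metrics` (tidy table), `ratings`
#'   ([rating_matrix()]), `truth` (tidy expected-value table), `teachers`
#'   (per-exercise teacher objects), `n_videos`.
#' @export
simulate_study <- function(n_per_group = 12,
                           profiles = default_study_profiles(),
                           model = rating_model(), seed = 1,
                           exercises = 1:3, tempo = 1.5, skill_sd = 0.15,
                           through_markers = TRUE, marker_noise_sd = 0,
                           trial_sink = NULL) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  set.seed(seed)
  groups <- c(rep("AVE", n_per_group), rep("AV", n_per_group))
  pids <- seq_len(2 * n_per_group)
  skill <- exp(stats::rnorm(length(pids), 0, skill_sd))
  trial_seeds <- sample.int(.Machine$integer.max - 1,
                            length(pids) * length(exercises) * 3)

  teachers <- lapply(exercises, function(e) {
    generate_teacher(exercise_script(e, tempo = tempo))
  })
  names(teachers) <- as.character(exercises)
  teacher_kin <- lapply(teachers, trial_kinematics, through_markers)

  stages <- c("S1", "S2", "S3")
  metrics <- list()
  truth_rows <- list()
  ti <- 0L
  for (p in seq_along(pids)) {
    for (e in seq_along(exercises)) {
      for (s in seq_along(stages)) {
        ti <- ti + 1L
        prof <- scale_profile(profiles[[groups[p]]][[stages[s]]], skill[p])
        gen <- generate_participant(teachers[[e]], prof,
                                    seed = trial_seeds[ti],
                                    marker_noise_sd = marker_noise_sd)
        kin <- trial_kinematics(gen, through_markers)
        meta <- trial_meta(pids[p], groups[p], exercises[e], stages[s])
        if (!is.null(trial_sink)) trial_sink(gen, teachers[[e]], meta)
        mv <- compute_all(kin, teacher_kin[[e]], meta)
        metrics[[ti]] <- mv
        truth_rows[[ti]] <- data.frame(
          participant = pids[p], group = groups[p],
          exercise = exercises[e], stage = stages[s],
          metric_id = METRIC_IDS, expected = as.numeric(gen$truth),
          guided = gen$guided)
      }
    }
  }
  metric_table <- metrics_to_table(metrics)
  ratings <- simulate_ratings(metric_table, model,
                              seed = seed + 104729, n_raters = 5)
  list(metrics = metric_table, ratings = ratings,
       truth = do.call(rbind, truth_rows), teachers = teachers,
       n_videos = nrow(ratings$scores))
}

#' Lightweight metric-level study simulator
#'
#' Draws per-trial values of a single metric from a linear model with
#' participant random effects: value = baseline + stage effect +
#' interaction bump for AVE at recall + participant effect + residual.
#' Used for statistical calibration of the bootstrap contrasts, where
#' hundreds of replicate studies are needed and the marker-level
#' generator would be needlessly slow.
#'
#' @param n_per_group participants per group.
#' @param delta Group-by-Stage interaction: extra S1->S3 improvement of
#'   AVE (in metric units; 0 gives a null study).
#' @param baseline grand mean at S1.
#' @param stage_effect named S1/S2/S3 additive stage effects common to
#'   both groups.
#' @param participant_sd SD of the participant random effect.
#' @param resid_sd residual SD per trial.
#' @param n_exercises trials per participant-stage.
#' @param seed integer seed.
#' @param metric_id metric id label for the output table.
#' @return tidy metric table compatible with [group_stage_contrasts()].
#' @export
simulate_metric_table <- function(n_per_group = 12, delta = 0, baseline = 60,
                                  stage_effect = c(S1 = 0, S2 = -8, S3 = -15),
                                  participant_sd = 8, resid_sd = 10,
                                  n_exercises = 3, seed = 1,
                                  metric_id = "m14") {
  set.seed(seed)
  groups <- c(rep("AVE", n_per_group), rep("AV", n_per_group))
  pids <- seq_len(2 * n_per_group)
  u <- stats::rnorm(length(pids), 0, participant_sd)
  rows <- expand.grid(exercise = seq_len(n_exercises),
                      stage = names(stage_effect), participant = pids,
                      stringsAsFactors = FALSE)
  rows$group <- groups[rows$participant]
  rows$value <- baseline + stage_effect[rows$stage] + u[rows$participant] +
    ifelse(rows$group == "AVE" & rows$stage == "S3", -delta, 0) +
    stats::rnorm(nrow(rows), 0, resid_sd)
  rows$metric_id <- metric_id
  rows$defined_flag <- TRUE
  rows[, c("participant", "group", "exercise", "stage", "metric_id",
           "value", "defined_flag")]
}
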