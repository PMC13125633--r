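# Pipeline orchestration: study configuration, the simulate / analyze /
# stats stages, and plain-text artifacts between them. Each stage is
# independently runnable (also via the thin command-line front end in
# inst/cli/bowkin.R) and writes a manifest sufficient to reproduce its
# outputs.

#' Study configuration
#'
#' Validated configuration for the pipeline stages. Unknown keys are
#' rejected; every threshold is checked against its documented valid
#' range.
#'
#' @param ... overrides of the defaults (see Details).
#' @details Fields: `n_per_group` (>= 2), `seed`, `exercises` (subset of
#'   1:3), `tempo` (s/stroke), `skill_sd`, `marker_noise_sd` (mm),
#'   `filter_cutoff` (Hz), `min_excursion` (bow-lengths),
#'   `min_interval` (s), `sparc_f_max`, `sparc_amp_threshold`,
#'   `sparc_pad_factor`, `n_boot`, `n_raters`, `always_include`
#'   (metric ids), `through_markers`.
#' @return validated config list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(n_per_group = 12, seed = 1, exercises = 1:3, tempo = 1.5,
              skill_sd = 0.15, marker_noise_sd = 0, filter_cutoff = 10,
              min_excursion = 0.05, min_interval = 0.25, sparc_f_max = 10,
              sparc_amp_threshold = 0.05, sparc_pad_factor = 4,
              n_boot = 2000, n_raters = 5,
              always_include = c("m3", "m10", "m11", "m12", "m13", "m17"),
              through_markers = TRUE)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  with(cfg, {
    if (n_per_group < 2) stop("n_per_group must be >= 2")
    if (!all(exercises %in% 1:3)) stop("exercises must be a subset of 1:3")
    if (tempo <= 0) stop("tempo must be positive")
    if (filter_cutoff <= 0 || filter_cutoff >= 60) {
      stop("filter_cutoff must lie in (0, 60) Hz")
    }
    if (min_excursion <= 0 || min_excursion >= 1) {
      stop("min_excursion must lie in (0, 1)")
    }
    if (min_interval < 0) stop("min_interval must be >= 0")
    if (n_boot < 1) stop("n_boot must be >= 1")
    if (!all(always_include %in% METRIC_IDS)) {
      stop("always_include must contain metric ids m1..m17")
    }
  })
  sparc_params(cfg$sparc_f_max, cfg$sparc_amp_threshold, cfg$sparc_pad_factor)
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with config keys (see [study_config()]).
#' @return validated `study_config`.
#' @export
read_study_config <- function(path) {
  study_config(yaml::read_yaml(path))
}

cfg_sparc <- function(config) {
  sparc_params(config$sparc_f_max, config$sparc_amp_threshold,
               config$sparc_pad_factor)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export a rating matrix as a long table
#'
#' @param ratings a [rating_matrix()].
#' @return data.frame `video_id`, `participant`, `group`, `exercise`,
#'   `stage`, `rater`, `score`.
#' @export
ratings_to_long <- function(ratings) {
  vm <- ratings$video_meta
  vid <- sprintf("p%02d_ex%d_%s", vm$participant, vm$exercise, vm$stage)
  do.call(rbind, lapply(seq_len(ncol(ratings$scores)), function(r) {
    data.frame(video_id = vid, participant = vm$participant,
               group = vm$group, exercise = vm$exercise, stage = vm$stage,
               rater = colnames(ratings$scores)[r],
               score = ratings$scores[, r])
  }))
}

#' Rebuild a rating matrix from a long table
#'
#' @param long data.frame as written by [ratings_to_long()].
#' @return a [rating_matrix()].
#' @export
ratings_from_long <- function(long) {
  raters <- sort(unique(long$rater))
  vids <- unique(long[, c("video_id", "participant", "group", "exercise",
                          "stage")])
  scores <- matrix(NA_real_, nrow(vids), length(raters),
                   dimnames = list(NULL, raters))
  for (r in seq_along(raters)) {
    sub <- long[long$rater == raters[r], ]
    scores[, r] <- sub$score[match(vids$video_id, sub$video_id)]
  }
  rating_matrix(scores, vids[, -1])
}

write_manifest <- function(dir, config, extra = list()) {
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  man <- c(list(config_md5 = unname(tools::md5sum(cfg_path)),
                seed = config$seed,
                package_version = as.character(utils::packageVersion("bowkin")),
                r_version = R.version.string,
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(man)
}

#' Materialize a synthetic study directory
#'
#' Runs [simulate_study()] under the given configuration and writes a
#' self-contained study directory: one marker TSV per trial plus the
#' teacher references, the ratings table, the ground-truth parameter
#' table, the simulate-time metric table, a config snapshot and a
#' manifest (config hash, seed, versions).
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @return the [simulate_study()] result, invisibly.
#' @export
run_simulate <- function(config = study_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- new.env()
  sink_fn <- function(gen, teacher, meta) {
    ex <- teacher$script$exercise_id
    tpath <- file.path(out_dir, sprintf("teacher_ex%d.tsv", ex))
    if (is.null(written[[as.character(ex)]])) {
      write_marker_tsv(teacher$markers, tpath)
      written[[as.character(ex)]] <- TRUE
    }
    write_marker_tsv(gen$markers,
                     file.path(out_dir, sprintf("trial_p%02d_ex%d_%s.tsv",
                                                meta$participant_id,
                                                meta$exercise, meta$stage)))
  }
  res <- simulate_study(n_per_group = config$n_per_group,
                        seed = config$seed, exercises = config$exercises,
                        tempo = config$tempo, skill_sd = config$skill_sd,
                        through_markers = config$through_markers,
                        marker_noise_sd = config$marker_noise_sd,
                        trial_sink = sink_fn)
  trials <- unique(res$metrics[, c("participant", "group", "exercise",
                                   "stage")])
  trials$file <- sprintf("trial_p%02d_ex%d_%s.tsv", trials$participant,
                         trials$exercise, trials$stage)
  write_tsv(trials, file.path(out_dir, "trials.tsv"))
  write_tsv(res$metrics, file.path(out_dir, "metrics.tsv"))
  write_tsv(res$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(ratings_to_long(res$ratings), file.path(out_dir, "ratings.tsv"))
  write_manifest(out_dir, config,
                 list(n_trials = nrow(trials), n_videos = res$n_videos))
  invisible(res)
}

#' Analyze a study directory of marker files
#'
#' Reads every trial listed in `trials.tsv`, cleans the streams
#' (gap filling, zero-phase low-pass at the configured cutoff), aligns
#' participant and teacher on the shared clock, reconstructs joint
#' angles and the bow trace and computes the 17-metric vector per trial.
#' Unreadable trials are skipped with a logged reason; the call fails
#' only when every trial fails.
#'
#' @param study_dir directory produced by [run_simulate()] (or
#'   hand-assembled with the same layout).
#' @param config a [study_config()].
#' @param out_path optional path for the tidy metric table TSV.
#' @return list with `metrics` (tidy table), `qc` (per-trial QC
#'   data.frame including skip reasons).
#' @export
run_analyze <- function(study_dir, config = study_config(),
                        out_path = NULL) {
  trials <- read_tsv(file.path(study_dir, "trials.tsv"))
  teacher_cache <- list()
  get_teacher <- function(ex) {
    key <- as.character(ex)
    if (is.null(teacher_cache[[key]])) {
      m <- read_marker_tsv(file.path(study_dir, sprintf("teacher_ex%d.tsv", ex)))
      m <- lowpass(fill_gaps(m), config$filter_cutoff)
      teacher_cache[[key]] <<- list(angles = joint_angles(m),
                                    trace = bow_trace(m), markers = m)
    }
    teacher_cache[[key]]
  }
  metrics <- list()
  qc_rows <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    res <- tryCatch({
      teach <- get_teacher(tr$exercise)
      m <- read_marker_tsv(file.path(study_dir, tr$file))
      m <- lowpass(fill_gaps(m), config$filter_cutoff)
      al <- align_pair(m, teach$markers)
      part <- list(angles = joint_angles(al$a), trace = bow_trace(al$a))
      teach_al <- list(angles = joint_angles(al$b), trace = bow_trace(al$b))
      meta <- trial_meta(tr$participant, tr$group, tr$exercise, tr$stage)
      mv <- compute_all(part, teach_al, meta,
                        min_excursion = config$min_excursion,
                        min_interval = config$min_interval,
                        sparc_par = cfg_sparc(config))
      list(ok = TRUE, mv = mv)
    }, error = function(e) list(ok = FALSE, reason = conditionMessage(e)))
    if (res$ok) {
      metrics[[length(metrics) + 1]] <- res$mv
      q <- attr(res$mv, "qc")
      qc_rows[[i]] <- data.frame(file = tr$file, status = "ok",
                                 reason = "", n_strokes = q$n_strokes,
                                 clip_rate = q$clip_rate,
                                 unmatched_events = q$unmatched_events,
                                 n_undefined = sum(is.na(as.numeric(res$mv))))
    } else {
      message(sprintf("skipping %s: %s", tr$file, res$reason))
      qc_rows[[i]] <- data.frame(file = tr$file, status = "skipped",
                                 reason = res$reason, n_strokes = NA,
                                 clip_rate = NA, unmatched_events = NA,
                                 n_undefined = NA)
    }
  }
  if (length(metrics) == 0) stop("all trials failed to analyze")
  out <- list(metrics = metrics_to_table(metrics),
              qc = do.call(rbind, qc_rows))
  if (!is.null(out_path)) write_tsv(out$metrics, out_path)
  out
}

#' Run the statistical layer on a metric table and ratings
#'
#' Produces the correlation screen with retained flags, the inter-rater
#' ICC report, the Group-by-Stage bootstrap contrast table for the
#' retained metrics and the expert-rating contrasts. When ratings are
#' missing the correlation/ICC/rating-contrast sections are skipped with
#' a warning and the metric contrasts are still run (over all metrics).
#'
#' @param metric_table tidy metric table (from [run_analyze()] or
#'   [simulate_study()]).
#' @param ratings a [rating_matrix()], or `NULL`.
#' @param config a [study_config()].
#' @param out_dir optional directory for the TSV reports.
#' @return list with `correlations`, `icc`, `metric_contrasts`,
#'   `rating_contrasts` (entries `NULL` where skipped).
#' @export
run_stats <- function(metric_table, ratings = NULL,
                      config = study_config(), out_dir = NULL) {
  correlations <- icc_report <- rcontr <- NULL
  if (is.null(ratings)) {
    warning("no ratings supplied; correlation, ICC and rating contrasts skipped")
    retained <- intersect(METRIC_IDS, unique(metric_table$metric_id))
  } else {
    correlations <- metric_rating_correlations(
      metric_table, ratings, always_include = config$always_include)
    icc_report <- icc(ratings)
    rcontr <- rating_contrasts(ratings, n_boot = config$n_boot,
                               seed = config$seed)
    retained <- correlations$metric_id[correlations$retained_flag]
  }
  mcontr <- group_stage_contrasts(metric_table, n_boot = config$n_boot,
                                  seed = config$seed, metrics = retained)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(correlations)) {
      write_tsv(correlations, file.path(out_dir, "correlations.tsv"))
    }
    write_tsv(mcontr, file.path(out_dir, "metric_contrasts.tsv"))
    if (!is.null(rcontr)) {
      write_tsv(rcontr, file.path(out_dir, "rating_contrasts.tsv"))
    }
    if (!is.null(icc_report)) {
      yaml::write_yaml(list(icc_single = icc_report$icc_single,
                            icc_average = icc_report$icc_average,
                            ci_single = icc_report$ci_single,
                            ci_average = icc_report$ci_average),
                       file.path(out_dir, "icc.yaml"))
    }
    write_manifest(out_dir, config)
  }
  list(correlations = correlations, icc = icc_report,
       metric_contrasts = mcontr, rating_contrasts = rcontr)
}
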