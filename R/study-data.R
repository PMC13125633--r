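# Published summary tables of the reference teacher-learner exoskeleton
# study that this pipeline models. These are inputs (printed,
# per-participant characteristics and group-stage metric summaries), used
# for descriptive statistics, calibration bands and protocol arithmetic.

#' Participant characteristics of the reference study cohort
#'
#' Per-participant age, weight, body height and Goldsmiths Musical
#' Sophistication Index (MSI) score of the 24 novices (12 haptic / AVE,
#' 12 control / AV), plus the teacher, as published by the reference
#' study.
#'
#' @param include_teacher append the teacher's row.
#' @return data.frame with columns `participant`, `group`, `age_years`,
#'   `weight_kg`, `length_cm`, `msi`.
#' @export
study_participants <- function(include_teacher = FALSE) {
  ave <- data.frame(
    participant = 1:12, group = "AVE",
    age_years = c(38, 63, 39, 35, 28, 40, 42, 40, 22, 50, 23, 27),
    weight_kg = c(82, 80, 80, 64, 67, 85, 71, 75, 73, 95, 75, 85),
    length_cm = c(185, 192, 197, 184, 169, 185, 181, 183, 175, 178, 183, 187),
    msi = c(4.4, 5.4, 4.9, 3.1, 4.4, 4.3, 3.3, 4.1, 3.3, 4.8, 2.9, 3.8))
  av <- data.frame(
    participant = 13:24, group = "AV",
    age_years = c(28, 21, 36, 40, 38, 29, 25, 30, 31, 53, 28, 45),
    weight_kg = c(70, 70, 72, 70, 95, 81, 61, 75, 85, 75, 84, 79),
    length_cm = c(175, 185, 182, 180, 186, 185, 176, 178, 194, 184, 198, 185),
    msi = c(4.0, 4.2, 3.3, 4.6, 2.9, 4.6, 3.9, 3.3, 3.9, 4.3, 5.1, 4.2))
  out <- rbind(ave, av)
  if (include_teacher) {
    out <- rbind(out, data.frame(participant = 0, group = "teacher",
                                 age_years = 42, weight_kg = 80,
                                 length_cm = 181, msi = NA))
  }
  out
}

#' Published group-stage metric summaries of the reference study
#'
#' Mean and SD of the 13 retained metrics per group (AV control, AVE
#' haptic) at baseline (S1) and recall (S3), and for the teacher, as
#' published by the reference study. Units follow the metric definitions
#' (deg for ROMs and variability, s for timing, arbitrary units for
#' ratios/distance, dimensionless for SPARC/synchronization). Used for
#' calibration bands (e.g. the teacher SPARC) and derived protocol
#' quantities such as percent improvements.
#'
#' @return data.frame with columns `metric_id`, `group` (`AV`, `AVE`,
#'   `teacher`), `stage` (`S1`, `S3` or `NA` for the teacher), `mean`,
#'   `sd`.
#' @export
reference_metric_summaries <- function() {
  rows <- list(
    c("m2", 36.7, 8.6, 45.8, 8.6, 36, 11, 46.9, 7.8, 45.4, 2.5),
    c("m3", 62, 16, 61, 18, 55, 20, 52, 25, 64.1, 5.0),
    c("m4", 1.29, 0.59, 2.7, 2.1, 1.42, 0.81, 2.7, 1.8, 2.11, 0.37),
    c("m6", 13.4, 3.5, 22, 13, 14.8, 5.9, 23, 12, 16.5, 2.5),
    c("m8", 12.05, 4.37, 9.7, 2.6, 12.8, 7.9, 8.9, 1.3, 7.86, 0.26),
    c("m10", 2.2, 1.1, 2.3, 1.2, 2.1, 1.1, 1.86, 0.65, 1.25, 0.23),
    c("m11", 3.6, 1.9, 3.7, 1.8, 2.6, 1.0, 2.3, 1.1, 1.49, 0.38),
    c("m12", 34, 34, 29, 24, 20, 18, 17, 16, 6.2, 1.8),
    c("m13", 19, 20, 0, 27, 6, 7, 13, 14, NA, NA),
    c("m14", 66, 24, 49, 23, 78, 38, 42, 17, NA, NA),
    c("m15", -1.90, 0.13, -1.795, 0.086, -1.89, 0.12, -1.791, 0.065,
      -1.758, 0.019),
    c("m16", 0.896, 0.062, 0.923, 0.075, 0.82, 0.20, 0.935, 0.048, NA, NA),
    c("m17", -0.07, 0.15, 0.04, 0.24, -0.16, 0.77, -0.04, 0.17, NA, NA))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(metric_id = r[1],
               group = c("AV", "AV", "AVE", "AVE", "teacher"),
               stage = c("S1", "S3", "S1", "S3", NA),
               mean = as.numeric(r[c(2, 4, 6, 8, 10)]),
               sd = as.numeric(r[c(3, 5, 7, 9, 11)]))
  }))
}
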