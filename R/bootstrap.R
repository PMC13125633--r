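# Participant-level cluster-bootstrap Group-by-Stage contrasts.
#
# The study's learning effects are difference-in-differences estimands on
# group-by-stage cell means. Uncertainty is obtained by resampling
# participants with replacement within each group, keeping all of a
# participant's exercises and stages together (cluster bootstrap), which
# respects the repeated-measures structure without any distributional
# model.

did_contrasts <- function() {
  list(
    list(label = "(AV S1 - AV S2) - (AVE S1 - AVE S2)",
         terms = data.frame(group = c("AV", "AV", "AVE", "AVE"),
                            stage = c("S1", "S2", "S1", "S2"),
                            w = c(1, -1, -1, 1))),
    list(label = "(AV S2 - AV S3) - (AVE S2 - AVE S3)",
         terms = data.frame(group = c("AV", "AV", "AVE", "AVE"),
                            stage = c("S2", "S3", "S2", "S3"),
                            w = c(1, -1, -1, 1))),
    list(label = "(AV S1 - AV S3) - (AVE S1 - AVE S3)",
         terms = data.frame(group = c("AV", "AV", "AVE", "AVE"),
                            stage = c("S1", "S3", "S1", "S3"),
                            w = c(1, -1, -1, 1))))
}

rating_contrast_defs <- function() {
  list(
    list(label = "AV S1 - AVE S1",
         terms = data.frame(group = c("AV", "AVE"), stage = c("S1", "S1"),
                            w = c(1, -1))),
    list(label = "AV S1 - AV S3",
         terms = data.frame(group = c("AV", "AV"), stage = c("S1", "S3"),
                            w = c(1, -1))),
    list(label = "AVE S1 - AVE S3",
         terms = data.frame(group = c("AVE", "AVE"), stage = c("S1", "S3"),
                            w = c(1, -1))),
    list(label = "AV S3 - AVE S3",
         terms = data.frame(group = c("AV", "AVE"), stage = c("S3", "S3"),
                            w = c(1, -1))),
    list(label = "(AV S1 - AV S3) - (AVE S1 - AVE S3)",
         terms = data.frame(group = c("AV", "AV", "AVE", "AVE"),
                            stage = c("S1", "S3", "S1", "S3"),
                            w = c(1, -1, -1, 1))))
}

# Core cluster bootstrap over a (participant, group, stage, value) table.
# Returns one row per contrast definition.
cluster_boot_contrasts <- function(df, defs, n_boot, seed, conf = 0.95) {
  stopifnot(n_boot >= 1)
  stages <- sort(unique(df$stage))
  parts <- unique(df[, c("participant", "group")])
  parts <- parts[order(parts$participant), ]
  p_idx <- match(df$participant, parts$participant)
  s_idx <- match(df$stage, stages)
  ok <- !is.na(df$value)
  np <- nrow(parts)
  ns <- length(stages)
  S <- matrix(0, np, ns)  # per-participant sums of defined values
  C <- matrix(0, np, ns)  # per-participant counts
  for (r in which(ok)) {
    S[p_idx[r], s_idx[r]] <- S[p_idx[r], s_idx[r]] + df$value[r]
    C[p_idx[r], s_idx[r]] <- C[p_idx[r], s_idx[r]] + 1
  }
  groups <- c("AV", "AVE")
  cell_mean <- function(w_by_group) {
    # w_by_group: named list of participant weight vectors
    out <- matrix(NA_real_, 2, ns, dimnames = list(groups, stages))
    for (g in groups) {
      rows <- which(parts$group == g)
      if (length(rows) == 0) next
      w <- w_by_group[[g]]
      num <- w %*% S[rows, , drop = FALSE]
      den <- w %*% C[rows, , drop = FALSE]
      out[g, ] <- ifelse(den > 0, num / den, NA_real_)
    }
    out
  }
  eval_defs <- function(cells) {
    vapply(defs, function(d) {
      v <- mapply(function(g, s, w) w * cells[g, s],
                  d$terms$group, d$terms$stage, d$terms$w)
      sum(v)
    }, 0)
  }
  obs_cells <- cell_mean(lapply(groups, function(g) {
    rep(1, sum(parts$group == g))
  }) |> stats::setNames(groups))
  obs <- eval_defs(obs_cells)

  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, length(defs))
  for (bi in seq_len(n_boot)) {
    w_by_group <- stats::setNames(lapply(groups, function(g) {
      ng <- sum(parts$group == g)
      tabulate(sample.int(ng, ng, replace = TRUE), nbins = ng)
    }), groups)
    reps[bi, ] <- eval_defs(cell_mean(w_by_group))
  }
  alpha <- 1 - conf
  out <- do.call(rbind, lapply(seq_along(defs), function(j) {
    rj <- reps[, j]
    defined <- is.finite(obs[j]) && any(is.finite(rj))
    qs <- if (defined) {
      stats::quantile(rj, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                      names = FALSE)
    } else c(NA_real_, NA_real_)
    data.frame(contrast = defs[[j]]$label,
               estimate = if (defined) obs[j] else NA_real_,
               ci_low = qs[1], ci_high = qs[2],
               prob = if (defined) {
                 # ties at exactly zero count one half, so a perfectly
                 # null dataset reports prob = 0.5
                 mean(rj > 0, na.rm = TRUE) + 0.5 * mean(rj == 0, na.rm = TRUE)
               } else NA_real_)
  }))
  attr(out, "low_precision") <- n_boot < 100
  attr(out, "n_boot") <- n_boot
  out
}

#' Group-by-Stage bootstrap contrasts for the metric table
#'
#' For each metric, estimates the three difference-in-differences
#' contrasts between the control (AV) and haptic (AVE) groups across
#' baseline, training and recall stages, with percentile bootstrap
#' confidence intervals from a participant-level cluster bootstrap and
#' the bootstrap probability that the contrast exceeds zero. Undefined
#' metric values are excluded; a metric undefined for an entire
#' group-stage cell yields undefined contrasts for that metric.
#'
#' @param metric_table tidy metric table (see [metrics_to_table()]).
#' @param n_boot bootstrap replicate count (>= 1; >= 1000 recommended,
#'   fewer is flagged low-precision).
#' @param seed integer seed; fixed seeds give bit-reproducible results.
#' @param metrics metric ids to analyze (default: all present).
#' @param conf confidence level.
#' @return data.frame with columns `metric_id`, `contrast`, `estimate`,
#'   `ci_low`, `ci_high`, `prob`.
#' @export
group_stage_contrasts <- function(metric_table, n_boot = 2000, seed = 1,
                                  metrics = NULL, conf = 0.95) {
  ids <- metrics %||% intersect(METRIC_IDS, unique(metric_table$metric_id))
  per_group <- table(unique(metric_table[, c("participant", "group")])$group)
  if (any(per_group < 2)) stop("need at least 2 participants per group")
  out <- do.call(rbind, lapply(seq_along(ids), function(k) {
    id <- ids[k]
    d <- metric_table[metric_table$metric_id == id,
                      c("participant", "group", "stage", "value")]
    res <- cluster_boot_contrasts(d, did_contrasts(), n_boot,
                                  seed = seed + k - 1, conf = conf)
    cbind(metric_id = id, res)
  }))
  rownames(out) <- NULL
  out
}

#' Bootstrap contrasts of expert panel ratings
#'
#' Applies the participant-level cluster bootstrap to per-video mean
#' expert ratings: between-group baseline and recall differences, the
#' within-group baseline-recall improvements, and the Group-by-Stage
#' interaction (difference-in-differences).
#'
#' @param ratings a [rating_matrix()] whose video metadata covers both
#'   stages for each group.
#' @param n_boot,seed,conf as in [group_stage_contrasts()].
#' @return data.frame with `contrast`, `estimate`, `ci_low`, `ci_high`,
#'   `prob`.
#' @export
rating_contrasts <- function(ratings, n_boot = 2000, seed = 1, conf = 0.95) {
  mr <- mean_ratings(ratings)
  d <- data.frame(participant = mr$participant, group = mr$group,
                  stage = mr$stage, value = mr$mean_rating)
  for (g in c("AV", "AVE")) {
    st <- unique(d$stage[d$group == g])
    if (!all(c("S1", "S3") %in% st)) {
      stop(sprintf("group %s does not cover both S1 and S3", g))
    }
  }
  out <- cluster_boot_contrasts(d, rating_contrast_defs(), n_boot, seed, conf)
  rownames(out) <- NULL
  out
}
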