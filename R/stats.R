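# Statistical layer: metric-rating Spearman screening with Bonferroni
# correction, metric retention, two-way random-effects intraclass
# correlation, and descriptive statistics.

#' Spearman rank correlation with pairwise deletion
#'
#' Average ranks for ties; two-sided p-value via the t approximation.
#' Pairs where either value is an undefined (NA) marker are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p` and `n` (complete pairs). `rho` is `NA`
#'   when either vector is constant after deletion.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman() needs at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level.
#' @param m number of tests.
#' @return `alpha / m`. With the study's 17 metrics at alpha = 0.05 this
#'   is 0.00294, i.e. the threshold 0.003 at 3 decimals.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 17) {
  stopifnot(m >= 1, alpha > 0)
  alpha / m
}

#' Retain metrics by correlation screening
#'
#' Metrics whose p-value falls below the threshold, unioned with an
#' always-include list. The study design keeps `m3`, `m10`, `m11`,
#' `m12`, `m13` and `m17` regardless of screening, to track shoulder
#' use, variability and timing under guidance.
#'
#' @param correlations data.frame with columns `metric_id` and `p`.
#' @param threshold significance threshold, e.g.
#'   [bonferroni_threshold()].
#' @param always_include metric ids retained regardless of p.
#' @return character vector of retained metric ids (in `m1`..`m17`
#'   order).
#' @export
select_metrics <- function(correlations,
                           threshold = bonferroni_threshold(0.05, 17),
                           always_include = c("m3", "m10", "m11", "m12",
                                              "m13", "m17")) {
  hits <- correlations$metric_id[!is.na(correlations$p) &
                                   correlations$p < threshold]
  keep <- union(hits, always_include)
  METRIC_IDS[METRIC_IDS %in% keep]
}

#' Correlate every metric with mean expert ratings
#'
#' Joins the per-trial metric table with per-video mean ratings on
#' (participant, exercise, stage) and computes [spearman()] per metric.
#'
#' @param metric_table tidy metric table (see [metrics_to_table()]).
#' @param ratings a rating matrix object from [rating_matrix()].
#' @param threshold significance threshold for the retained flag.
#' @param always_include metric ids always retained.
#' @return data.frame: `metric_id`, `rho`, `p`, `n`, `retained_flag`.
#' @export
metric_rating_correlations <- function(metric_table, ratings,
                                       threshold = bonferroni_threshold(0.05, 17),
                                       always_include = c("m3", "m10", "m11",
                                                          "m12", "m13", "m17")) {
  mr <- mean_ratings(ratings)
  key <- function(d) paste(d$participant, d$exercise, d$stage)
  out <- do.call(rbind, lapply(METRIC_IDS, function(id) {
    mt <- metric_table[metric_table$metric_id == id, ]
    idx <- match(key(mt), key(mr))
    ok <- !is.na(idx)
    sp <- spearman(mt$value[ok], mr$mean_rating[idx[ok]])
    data.frame(metric_id = id, rho = sp$rho, p = sp$p, n = sp$n)
  }))
  out$retained_flag <- out$metric_id %in%
    select_metrics(out, threshold, always_include)
  out
}

#' Expert rating matrix
#'
#' Ordinal 1-7 scores of `n_raters` raters for a set of videos (trials at
#' baseline and recall).
#'
#' @param scores numeric matrix `videos x raters`, values in 1..7.
#' @param video_meta data.frame with one row per video: `participant`,
#'   `group`, `exercise`, `stage`.
#' @return object of class `rating_matrix`.
#' @export
rating_matrix <- function(scores, video_meta) {
  scores <- as.matrix(scores)
  if (!all(scores %in% 1:7)) stop("scores must be integers in 1..7")
  stopifnot(nrow(scores) == nrow(video_meta))
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("rater", seq_len(ncol(scores)))
  }
  structure(list(scores = scores, video_meta = video_meta),
            class = "rating_matrix")
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d videos x %d raters\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Per-video mean expert ratings
#'
#' @param ratings a [rating_matrix()].
#' @return the video metadata with an added `mean_rating` column.
#' @export
mean_ratings <- function(ratings) {
  out <- ratings$video_meta
  out$mean_rating <- rowMeans(ratings$scores)
  out
}

#' Two-way random-effects absolute-agreement ICC
#'
#' ICC(2,1) for single raters and ICC(2,k) for the k-rater average, from
#' the two-way ANOVA mean squares (rows = videos, columns = raters), with
#' F-based 95% confidence bounds.
#'
#' @param ratings a [rating_matrix()] or a complete numeric matrix
#'   `videos x raters`.
#' @param conf confidence level for the bounds.
#' @return list with `icc_single`, `icc_average`, `ci_single`,
#'   `ci_average`, and the mean squares `ms`.
#' @export
icc <- function(ratings, conf = 0.95) {
  x <- if (inherits(ratings, "rating_matrix")) ratings$scores else as.matrix(ratings)
  n <- nrow(x)   # videos (targets)
  k <- ncol(x)   # raters
  if (n < 2 || k < 2) stop("icc() needs at least 2 videos and 2 raters")
  if (any(is.na(x))) stop("icc() requires a complete rating matrix")
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)

  alpha <- 1 - conf
  # ICC(2,1) bounds via the Satterthwaite-style F approximation
  fj <- msc / mse
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v_num <- (a * msc + b * mse)^2
  v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  v <- v_num / v_den
  f_low <- stats::qf(1 - alpha / 2, n - 1, v)
  f_up <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f_low * mse) /
    (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f_up * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_up * msr)
  sf <- function(p) {
    # Spearman-Brown step-up from single-rater bounds
    k * p / (1 + (k - 1) * p)
  }
  list(icc_single = icc1, icc_average = icck,
       ci_single = c(lo1, up1), ci_average = c(sf(lo1), sf(up1)),
       ms = c(msr = msr, msc = msc, mse = mse, fj = unname(fj)))
}

#' Median and interquartile range
#'
#' Even-n median as the mean of the two central order statistics; IQR as
#' Q3 - Q1 with the linear-interpolation quantile convention (R type 7).
#'
#' @param values non-empty numeric vector.
#' @return named vector `median`, `iqr`.
#' @export
median_iqr <- function(values) {
  stopifnot(length(values) >= 1)
  c(median = stats::median(values), iqr = unname(stats::IQR(values, type = 7)))
}
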