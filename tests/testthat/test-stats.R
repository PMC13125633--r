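# Statistical layer: Spearman screening, metric retention, ICC,
# descriptive statistics and the cluster-bootstrap contrasts.

test_that("spearman handles monotone, antitone and tied data", {
  expect_equal(spearman(c(1, 2, 3, 4), c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman(c(1, 2, 3, 4), c(4, 3, 2, 1))$rho, -1)
  # tied-data oracle: average ranks computed by hand
  x <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 8)
  set.seed(41)
  y <- x + rnorm(12, 0, 0.5)
  got <- spearman(x, y)
  rx <- rank(x); ry <- rank(y)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, rho_hand, tolerance = 1e-12)
  # pair deletion of undefined values
  x2 <- c(x, NA); y2 <- c(y, 100)
  expect_equal(spearman(x2, y2)$n, 12)
  # constant vector: undefined marker
  expect_true(is.na(spearman(rep(1, 10), 1:10)$rho))
  expect_error(spearman(1:3, 1:3), "4 complete")
})

test_that("Bonferroni threshold reproduces the protocol arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 17) * 17, 0.05)
  expect_equal(round(bonferroni_threshold(0.05, 17), 3), 0.003)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
})

test_that("metric retention filters by p and unions the always-include set", {
  cor_tab <- data.frame(metric_id = paste0("m", 1:17), p = rep(0.5, 17))
  expect_length(select_metrics(cor_tab, always_include = character()), 0)
  cor_tab$p[c(2, 4, 6, 8, 14, 15, 16)] <- 1e-5
  hits <- select_metrics(cor_tab, always_include = character())
  expect_setequal(hits, paste0("m", c(2, 4, 6, 8, 14, 15, 16)))
  full <- select_metrics(cor_tab)
  expect_setequal(full, paste0("m", c(2, 3, 4, 6, 8, 10, 11, 12, 13, 14,
                                      15, 16, 17)))
  expect_length(full, 13)
})

test_that("ICC matches the two-way ANOVA decomposition", {
  # perfect agreement
  x <- matrix(rep(1:6, 3), 6, 3)
  r <- icc(x)
  expect_equal(r$icc_single, 1)
  expect_equal(r$icc_average, 1)
  # 6 x 3 worked example against aov mean squares
  set.seed(42)
  x2 <- matrix(sample(1:7, 18, replace = TRUE), 6, 3)
  r2 <- icc(x2)
  d <- data.frame(y = as.vector(x2), video = factor(rep(1:6, 3)),
                  rater = factor(rep(1:3, each = 6)))
  msq <- summary(stats::aov(y ~ video + rater, d))[[1]]$"Mean Sq"
  msr <- msq[1]; msc <- msq[2]; mse <- msq[3]
  n <- 6; k <- 3
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icc2k <- (msr - mse) / (msr + (msc - mse) / n)
  expect_equal(r2$icc_single, icc21, tolerance = 1e-12)
  expect_equal(r2$icc_average, icc2k, tolerance = 1e-12)
  expect_error(icc(x2[, 1, drop = FALSE]), "at least 2")
})

test_that("ICC recovers a known variance ratio generatively", {
  set.seed(43)
  n <- 500; k <- 5
  rho <- 0.7
  truth <- rnorm(n, 0, sqrt(rho))
  x <- truth + matrix(rnorm(n * k, 0, sqrt(1 - rho)), n, k)
  r <- icc(x)
  expect_equal(r$icc_single, rho, tolerance = 0.05)
  expect_true(r$ci_single[1] < rho && rho < r$ci_single[2])
  # with agreement present, averaging raters raises reliability
  expect_lt(r$icc_single, r$icc_average)
})

test_that("median and IQR reproduce the cohort descriptives", {
  sp <- study_participants()
  ave <- sp[sp$group == "AVE", ]
  av <- sp[sp$group == "AV", ]
  expect_equal(unname(median_iqr(ave$length_cm)["median"]), 183.5)
  expect_equal(unname(median_iqr(ave$msi)["median"]), 4.2)
  expect_equal(unname(median_iqr(av$weight_kg)["median"]), 75)
  expect_equal(unname(median_iqr(av$length_cm)["median"]), 184.5)
  expect_equal(unname(median_iqr(av$msi)["median"]), 4.1)
  expect_equal(unname(median_iqr(c(1, 2, 3, 100))["median"]), 2.5)
  expect_equal(unname(median_iqr(c(1, 2, 3, 100))["iqr"]),
               unname(stats::quantile(c(1, 2, 3, 100), 0.75) -
                        stats::quantile(c(1, 2, 3, 100), 0.25)))
})

test_that("null data give zero contrasts with prob near one half", {
  mt <- expand.grid(participant = 1:8, exercise = 1:2,
                    stage = c("S1", "S2", "S3"), stringsAsFactors = FALSE)
  mt$group <- ifelse(mt$participant <= 4, "AVE", "AV")
  mt$metric_id <- "m2"
  mt$value <- 5
  mt$defined_flag <- TRUE
  gc_ <- group_stage_contrasts(mt, n_boot = 200, seed = 1)
  expect_true(all(gc_$estimate == 0))
  expect_true(all(gc_$prob == 0.5))  # ties at zero count one half
  expect_true(all(gc_$ci_low <= gc_$estimate & gc_$estimate <= gc_$ci_high))
})

test_that("bootstrap contrasts recover a scripted interaction", {
  delta <- 12
  mt <- simulate_metric_table(12, delta = delta, seed = 7)
  gc_ <- group_stage_contrasts(mt, n_boot = 1000, seed = 8)
  int <- gc_[gc_$contrast == "(AV S1 - AV S3) - (AVE S1 - AVE S3)", ]
  # AVE decreases by delta more at recall, so (AV S1-S3) - (AVE S1-S3)
  # targets -delta (AVE's baseline-minus-recall difference is larger)
  expect_equal(int$estimate, -delta, tolerance = 0.5 * delta)
  expect_true(int$ci_low < -delta && -delta < int$ci_high)
  # fixed seed: bit-reproducible
  gc2 <- group_stage_contrasts(mt, n_boot = 1000, seed = 8)
  expect_identical(gc_, gc2)
})

test_that("degenerate bootstrap settings are flagged, undefined cells marked", {
  mt <- simulate_metric_table(4, seed = 9)
  one <- bowkin:::cluster_boot_contrasts(
    mt[, c("participant", "group", "stage", "value")],
    bowkin:::did_contrasts(), n_boot = 1, seed = 1)
  expect_true(attr(one, "low_precision"))
  expect_equal(one$ci_low, one$ci_high)
  # a metric undefined in an entire group-stage cell
  mt2 <- mt
  mt2$value[mt2$group == "AVE" & mt2$stage == "S3"] <- NA
  gc_ <- group_stage_contrasts(mt2, n_boot = 50, seed = 2)
  expect_true(anyNA(gc_$estimate))
  s1s2 <- gc_[gc_$contrast == "(AV S1 - AV S2) - (AVE S1 - AVE S2)", ]
  expect_false(is.na(s1s2$estimate))
})

test_that("rating contrasts run the same machinery on mean ratings", {
  set.seed(44)
  vm <- expand.grid(participant = 1:8, exercise = 1:2,
                    stage = c("S1", "S3"), stringsAsFactors = FALSE)
  vm$group <- ifelse(vm$participant <= 4, "AVE", "AV")
  scores <- matrix(4L, nrow(vm), 5)
  rm_ <- rating_matrix(scores, vm)
  rc <- rating_contrasts(rm_, n_boot = 100, seed = 1)
  expect_true(all(rc$estimate == 0))
  # scripted group-specific improvement appears in the interaction
  lat <- ifelse(vm$stage == "S3", 2, 0) +
    ifelse(vm$stage == "S3" & vm$group == "AVE", 1, 0)
  scores2 <- matrix(pmin(7, 2 + rep(lat, 5) +
                           sample(0:1, nrow(vm) * 5, TRUE)), nrow(vm), 5)
  rc2 <- rating_contrasts(rating_matrix(scores2, vm), n_boot = 500, seed = 2)
  int <- rc2[rc2$contrast == "(AV S1 - AV S3) - (AVE S1 - AVE S3)", ]
  expect_equal(int$estimate, 1, tolerance = 0.5)
  expect_error(rating_contrasts(
    rating_matrix(scores[vm$stage == "S1", ], vm[vm$stage == "S1", ]),
    n_boot = 10, seed = 1), "S3")
})

test_that("fewer raters widen the interval on the same truth", {
  set.seed(45)
  vm <- expand.grid(participant = 1:12, exercise = 1:3,
                    stage = c("S1", "S3"), stringsAsFactors = FALSE)
  vm$group <- ifelse(vm$participant <= 6, "AVE", "AV")
  lat <- 3 + ifelse(vm$stage == "S3", 1.5, 0) + rnorm(nrow(vm), 0, 0.3)
  mk <- function(k) {
    s <- vapply(seq_len(k), function(i) {
      pmin(7L, pmax(1L, as.integer(round(lat + rnorm(nrow(vm), 0, 1.2)))))
    }, integer(nrow(vm)))
    rating_matrix(s, vm)
  }
  width <- function(r) {
    int <- r[r$contrast == "(AV S1 - AV S3) - (AVE S1 - AVE S3)", ]
    int$ci_high - int$ci_low
  }
  w1 <- median(vapply(1:6, function(i) {
    width(rating_contrasts(mk(1), n_boot = 200, seed = i))
  }, 0))
  w5 <- median(vapply(1:6, function(i) {
    width(rating_contrasts(mk(5), n_boot = 200, seed = i))
  }, 0))
  expect_lt(w5, w1 * 1.2)  # averaging raters must not widen the interval
})
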