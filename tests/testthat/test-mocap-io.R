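# Marker I/O: TSV dialect, C3D container, gap filling, filtering,
# clock alignment.

test_that("well-formed TSV parses with declared rate and labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("NO_OF_FRAMES\t2", "FREQUENCY\t120",
               "MARKER_NAMES\tA\tB",
               paste(c(1, 2, 3, 4, 5, 6), collapse = "\t"),
               paste(c(7, 8, 9, 10, 11, 12), collapse = "\t")), path)
  s <- read_marker_tsv(path)
  expect_equal(n_frames(s), 2)
  expect_equal(s$rate, 120)
  expect_equal(s$labels, c("A", "B"))
  expect_equal(marker_xyz(s, "B")[2, ], c(x = 10, y = 11, z = 12))
})

test_that("blank and 0,0,0 coordinate triples are flagged occluded", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("NO_OF_FRAMES\t2", "FREQUENCY\t120",
               "MARKER_NAMES\tA\tB",
               "1\t2\t3\t\t\t",
               "4\t5\t6\t0\t0\t0"), path)
  s <- read_marker_tsv(path)
  expect_equal(unname(s$occluded[, 2]), c(TRUE, TRUE))
  expect_false(any(s$occluded[, 1]))
  expect_true(all(is.na(s$positions[, 2, ])))
})

test_that("malformed headers and ragged rows raise named errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("NO_OF_FRAMES\t1", "MARKER_NAMES\tA", "1\t2\t3"), path)
  expect_error(read_marker_tsv(path), "FREQUENCY")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("NO_OF_FRAMES\t1", "FREQUENCY\t120", "MARKER_NAMES\tA\tB",
               "1\t2\t3\t4\t5\t6\t7"), path2)
  expect_error(read_marker_tsv(path2), "columns")
})

test_that("TSV write/read round trip is lossless to 1e-6 mm", {
  s <- make_series(n = 12, m = 4, seed = 3, occlude = list(c(5, 2)),
                   start_time = 1.25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_tsv(s, path)
  s2 <- read_marker_tsv(path)
  expect_lt(max(abs(s2$positions - s$positions), na.rm = TRUE), 1e-6)
  expect_identical(unname(s2$occluded), unname(s$occluded))
  expect_equal(s2$start_time, 1.25)
  expect_equal(s2$rate, s$rate)
})

test_that("C3D cross-format twin matches TSV content", {
  s <- make_series(n = 10, m = 3, seed = 5, occlude = list(c(2, 1)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  c3d <- withr::local_tempfile(fileext = ".c3d")
  write_marker_tsv(s, tsv)
  write_c3d(s, c3d)
  a <- read_marker_tsv(tsv)
  b <- read_c3d(c3d)
  # C3D stores float32: lossless at that precision (~1e-4 mm at 1 m scale)
  expect_lt(max(abs(a$positions - b$positions), na.rm = TRUE), 5e-4)
  expect_identical(unname(a$occluded), unname(b$occluded))
  expect_equal(b$labels, s$labels)
  expect_equal(b$rate, s$rate)
})

test_that("C3D POINT:UNITS = m converts positions to mm", {
  s <- make_series(n = 6, m = 2, seed = 6)
  path <- withr::local_tempfile(fileext = ".c3d")
  write_c3d(s, path, units = "m")
  b <- read_c3d(path)
  expect_lt(max(abs(b$positions - s$positions)), 5e-4)
})

test_that("degenerate C3D containers raise format errors", {
  path <- withr::local_tempfile(fileext = ".c3d")
  writeBin(as.raw(1:100), path)
  expect_error(read_c3d(path), "C3D")
  expect_error(read_c3d(tempfile()), "not found")
})

test_that("fill_gaps interpolates short gaps and preserves long ones", {
  n <- 60
  pos <- array(NA_real_, c(n, 2, 3))
  for (k in 1:3) {
    pos[, 1, k] <- 10 * seq_len(n) + k        # linear motion
    pos[, 2, k] <- sin(seq_len(n) / 5) * 50 + k
  }
  occ <- matrix(FALSE, n, 2)
  occ[20:22, 1] <- TRUE                        # 3-frame gap
  occ[30:39, 2] <- TRUE                        # 10-frame gap
  truth <- pos
  for (k in 1:3) {
    pk <- pos[, , k]
    pk[occ] <- NA
    pos[, , k] <- pk
  }
  s <- marker_series(pos, c("lin", "sine"), 120, occ)
  f <- fill_gaps(s, max_gap = 5)
  expect_false(any(f$occluded[, 1]))
  expect_lt(max(abs(f$positions[20:22, 1, ] - truth[20:22, 1, ])), 1e-6)
  expect_true(all(f$occluded[30:39, 2]))        # beyond max_gap: preserved
  # non-occluded samples never modified
  expect_identical(f$positions[-(20:22), 1, ], s$positions[-(20:22), 1, ])
})

test_that("edge gaps are extrapolated only when short enough", {
  n <- 40
  pos <- array(rep(10 * seq_len(n), 3), c(n, 1, 3))
  occ <- matrix(FALSE, n, 1)
  occ[1:3, 1] <- TRUE
  truth <- pos
  pos[1:3, 1, ] <- NA
  s <- marker_series(pos, "A", 120, occ)
  f <- fill_gaps(s, max_gap = 5)
  expect_false(any(f$occluded))
  expect_lt(max(abs(f$positions[1:3, 1, ] - truth[1:3, 1, ])), 1e-6)
  f2 <- fill_gaps(s, max_gap = 2)
  expect_true(all(f2$occluded[1:3, 1]))
})

test_that("fully occluded marker is left untouched with a warning", {
  pos <- array(1, c(5, 1, 3))
  occ <- matrix(TRUE, 5, 1)
  pos[] <- NA
  s <- marker_series(pos, "A", 120, occ)
  expect_warning(f <- fill_gaps(s, 3), "entire trial")
  expect_true(all(f$occluded))
})

test_that("lowpass preserves DC, passes 1 Hz and kills 50 Hz", {
  n <- 1200
  t <- (seq_len(n) - 1) / 120
  mk <- function(x) {
    marker_series(array(rep(x, 3), c(n, 1, 3)), "A", 120)
  }
  const <- lowpass(mk(rep(7, n)), 10)
  expect_lt(max(abs(const$positions - 7)), 1e-9)
  lo <- lowpass(mk(100 + 20 * sin(2 * pi * 1 * t)), 10)
  mid <- 200:1000  # avoid edge transients
  amp_lo <- (max(lo$positions[mid, 1, 1]) - min(lo$positions[mid, 1, 1])) / 2
  expect_gt(amp_lo / 20, 0.99)
  hi <- lowpass(mk(100 + 20 * sin(2 * pi * 50 * t)), 10)
  amp_hi <- (max(hi$positions[mid, 1, 1]) - min(hi$positions[mid, 1, 1])) / 2
  expect_lt(amp_hi / 20, 0.01)
  # idempotent on already-filtered content
  twice <- lowpass(lo, 10)
  a1 <- lo$positions[mid, 1, 1]
  a2 <- twice$positions[mid, 1, 1]
  expect_lt(max(abs(a2 - a1)) / (max(a1) - min(a1)), 1e-3)
})

test_that("lowpass validates cutoff and occlusions", {
  s <- make_series(n = 20)
  expect_error(lowpass(s, 60), "cutoff")
  s2 <- make_series(n = 20, occlude = list(c(1, 1)))
  expect_error(lowpass(s2, 10), "occluded")
})

test_that("align_pair crops to the shared clock window", {
  a <- make_series(n = 240, seed = 1, start_time = 0)
  b <- make_series(n = 240, seed = 2, start_time = 1.0)
  al <- align_pair(a, b)
  expect_equal(n_frames(al$a), 120)
  expect_equal(n_frames(al$b), 120)
  expect_equal(al$a$start_time, 1.0)
  # frame i corresponds to the same clock time within half a frame
  expect_lt(max(abs(frame_times(al$a) - frame_times(al$b))), 0.5 / 120)
  # identical windows: identity
  id <- align_pair(a, a)
  expect_identical(id$a$positions, a$positions)
  # disjoint windows: error
  c_ <- make_series(n = 12, seed = 3, start_time = 100)
  expect_error(align_pair(a, c_), "overlap")
})
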