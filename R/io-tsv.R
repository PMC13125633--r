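# Qualisys-style tab-separated marker export.
#
# Dialect: header lines `NO_OF_FRAMES <n>`, `FREQUENCY <hz>`, optional
# `START_TIME <s>`, `MARKER_NAMES <name> <name> ...` (tab separated),
# followed by one row per frame of X Y Z triples in mm, markers in header
# order. An occluded sample is exported as the sentinel triple 0,0,0 or as
# blank fields; real markers never sit exactly at the origin of the
# calibrated volume, so the sentinel is unambiguous.

#' Read a Qualisys-style tab-separated marker file
#'
#' @param path file path.
#' @return a [marker_series()]; coordinate triples equal to the 0,0,0
#'   sentinel or left blank are flagged occluded.
#' @export
read_marker_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  header <- list()
  i <- 1
  while (i <= length(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    key <- toupper(fields[1])
    if (key %in% c("NO_OF_FRAMES", "FREQUENCY", "START_TIME")) {
      header[[key]] <- as.numeric(fields[2])
      i <- i + 1
    } else if (key == "MARKER_NAMES") {
      header[[key]] <- fields[-1]
      i <- i + 1
    } else {
      break
    }
  }
  for (need in c("NO_OF_FRAMES", "FREQUENCY", "MARKER_NAMES")) {
    if (is.null(header[[need]])) {
      stop(sprintf("malformed header in %s: missing %s", path, need))
    }
  }
  labels <- header$MARKER_NAMES
  m <- length(labels)
  nf <- as.integer(header$NO_OF_FRAMES)
  data_lines <- lines[seq(i, length.out = length(lines) - i + 1)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nf) {
    stop(sprintf("declared NO_OF_FRAMES %d but found %d data rows",
                 nf, length(data_lines)))
  }
  pos <- array(NA_real_, c(nf, m, 3))
  occ <- matrix(FALSE, nf, m)
  for (r in seq_len(nf)) {
    fields <- strsplit(data_lines[r], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3 * m) fields <- c(fields, rep("", 3 * m - length(fields)))
    if (length(fields) != 3 * m) {
      stop(sprintf("row %d of %s: expected %d columns, found %d",
                   r + i - 1, path, 3 * m, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    blank <- !nzchar(trimws(fields))
    if (any(is.na(vals) & !blank)) {
      stop(sprintf("row %d of %s: non-numeric coordinate", r + i - 1, path))
    }
    for (k in seq_len(m)) {
      tri <- vals[(3 * k - 2):(3 * k)]
      if (any(is.na(tri)) || all(tri == 0)) {
        occ[r, k] <- TRUE
      } else {
        pos[r, k, ] <- tri
      }
    }
  }
  marker_series(pos, labels, header$FREQUENCY, occ,
                start_time = header$START_TIME %||% 0)
}

#' Write a marker series as a Qualisys-style tab-separated file
#'
#' Inverse of [read_marker_tsv()]: occluded entries are exported as the
#' 0,0,0 sentinel. Positions survive a round trip to better than 1e-6 mm.
#'
#' @param series a [marker_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_tsv <- function(series, path) {
  n <- n_frames(series)
  m <- length(series$labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NO_OF_FRAMES\t%d", n),
               sprintf("FREQUENCY\t%s", format(series$rate, digits = 15)),
               sprintf("START_TIME\t%s", format(series$start_time, digits = 15)),
               paste(c("MARKER_NAMES", series$labels), collapse = "\t")),
             con)
  flat <- matrix(aperm(series$positions, c(3, 2, 1)), nrow = 3 * m)
  flat[is.na(flat)] <- 0
  rows <- apply(flat, 2, function(v) {
    paste(formatC(v, format = "f", digits = 7), collapse = "\t")
  })
  writeLines(rows, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
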