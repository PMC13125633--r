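# Minimal C3D container support (3-D POINT data only).
#
# Implements the subset of the C3D standard the pipeline needs: Intel
# processor type, floating-point POINT data, POINT group parameters USED /
# FRAMES / RATE / SCALE / UNITS / LABELS / DATA_START. Analog channels,
# integer-scaled data and multi-section parameter records are out of scope.
# POINT:UNITS is respected: files stored in metres are converted to mm on
# read. A negative residual marks an invalid (occluded) sample.

C3D_PROC_INTEL <- 84L

#' Read a C3D motion-capture file
#'
#' Reads 3-D POINT data from a C3D container into a [marker_series()].
#' Positions are converted to millimetres according to `POINT:UNITS`;
#' samples with a negative residual are flagged occluded.
#'
#' @param path file path.
#' @return a [marker_series()].
#' @export
read_c3d <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 512) stop(sprintf("not a C3D container: %s (too short)", path))
  if (as.integer(raw[2]) != 0x50) {
    stop(sprintf("not a C3D container: %s (bad magic byte)", path))
  }
  u16 <- function(off) {
    as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  }
  f32 <- function(off) readBin(raw[(off + 1):(off + 4)], "double", size = 4,
                               endian = "little")
  param_block <- as.integer(raw[1])
  n_points_hdr <- u16(2)
  first_frame <- u16(6)
  last_frame <- u16(8)
  data_start_hdr <- u16(16)
  rate_hdr <- f32(20)

  # parameter section
  poff <- (param_block - 1) * 512
  if (as.integer(raw[poff + 4]) != C3D_PROC_INTEL) {
    stop(sprintf("unsupported C3D processor type %d (only Intel supported)",
                 as.integer(raw[poff + 4])))
  }
  params <- list()
  groups <- character()
  pos <- poff + 4  # 0-based offset of first group/parameter record
  repeat {
    if (pos + 2 > length(raw)) break
    name_len <- readBin(raw[pos + 1], "integer", size = 1, signed = TRUE)
    gid <- readBin(raw[pos + 2], "integer", size = 1, signed = TRUE)
    nl <- abs(name_len)
    if (nl == 0) break
    name <- rawToChar(raw[(pos + 3):(pos + 2 + nl)])
    off_pos <- pos + 2 + nl
    nxt <- u16(off_pos)
    if (gid < 0) {
      groups[as.character(-gid)] <- toupper(name)
    } else {
      dpos <- off_pos + 2
      dtype <- readBin(raw[dpos + 1], "integer", size = 1, signed = TRUE)
      ndim <- as.integer(raw[dpos + 2])
      dims <- if (ndim > 0) as.integer(raw[(dpos + 3):(dpos + 2 + ndim)]) else integer()
      dstart <- dpos + 2 + ndim
      nel <- if (ndim > 0) prod(dims) else 1L
      width <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)[as.character(dtype)]
      bytes <- raw[(dstart + 1):(dstart + nel * width)]
      val <- switch(as.character(dtype),
        `-1` = rawToChar(bytes),
        `1` = as.integer(bytes),
        `2` = readBin(bytes, "integer", size = 2, n = nel, endian = "little"),
        `4` = readBin(bytes, "double", size = 4, n = nel, endian = "little"))
      if (dtype == -1 && length(dims) == 2) {
        # char matrix: dims = c(width, count)
        val <- substring(val, seq(1, nel, by = dims[1]),
                         seq(dims[1], nel, by = dims[1]))
      }
      params[[paste0(gid, ":", toupper(name))]] <- list(value = val, dims = dims)
    }
    if (nxt == 0) break
    pos <- off_pos + nxt
  }
  point_gid <- names(groups)[groups == "POINT"]
  getp <- function(nm) {
    if (length(point_gid) == 0) return(NULL)
    p <- params[[paste0(point_gid, ":", nm)]]
    if (is.null(p)) NULL else p$value
  }
  n_points <- getp("USED") %||% n_points_hdr
  n_points <- as.integer(n_points[1])
  if (is.na(n_points) || n_points < 1) {
    stop(sprintf("empty POINT section in %s", path))
  }
  nf <- as.integer((getp("FRAMES") %||% (last_frame - first_frame + 1))[1])
  rate <- as.numeric((getp("RATE") %||% rate_hdr)[1])
  scale <- as.numeric((getp("SCALE") %||% -1)[1])
  if (scale >= 0) {
    stop(sprintf("integer-scaled C3D data in %s not supported (POINT:SCALE >= 0)",
                 path))
  }
  units <- trimws((getp("UNITS") %||% "mm")[1])
  labels <- trimws(getp("LABELS") %||% sprintf("M%03d", seq_len(n_points)))
  labels <- labels[seq_len(min(length(labels), n_points))]
  if (length(labels) < n_points) {
    labels <- c(labels, sprintf("M%03d", seq(length(labels) + 1, n_points)))
  }
  data_start <- as.integer((getp("DATA_START") %||% data_start_hdr)[1])

  doff <- (data_start - 1) * 512
  nvals <- nf * n_points * 4L
  if (doff + 4 * nvals > length(raw)) {
    stop(sprintf("truncated C3D data section in %s", path))
  }
  vals <- readBin(raw[(doff + 1):(doff + 4 * nvals)], "double", size = 4,
                  n = nvals, endian = "little")
  arr <- array(vals, c(4, n_points, nf))
  unit_scale <- switch(tolower(units), m = 1000, cm = 10, mm = 1,
                       stop(sprintf("unknown POINT:UNITS '%s' in %s", units, path)))
  pos3 <- aperm(arr[1:3, , , drop = FALSE], c(3, 2, 1)) * unit_scale
  occ <- matrix(arr[4, , ] < 0, n_points, nf)
  occ <- t(occ)
  for (k in 1:3) {
    pk <- pos3[, , k]
    pk[occ] <- NA_real_
    pos3[, , k] <- pk
  }
  marker_series(pos3, labels, rate, occ)
}

#' Write a marker series as a C3D file
#'
#' Writes floating-point POINT data (Intel processor type) with the POINT
#' group parameters required by [read_c3d()]. Occluded samples are stored
#' with residual -1 and zero coordinates.
#'
#' @param series a [marker_series()].
#' @param path output path.
#' @param units `"mm"` (default) or `"m"`; coordinates are converted.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(series, path, units = "mm") {
  units <- match.arg(units, c("mm", "m"))
  nf <- n_frames(series)
  np <- length(series$labels)
  scale <- if (units == "m") 1 / 1000 else 1

  i8 <- function(x) as.raw(bitwAnd(as.integer(x), 0xFF))
  u16r <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  f32r <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

  param_entry <- function(gid, name, dtype, dims, data_raw, last = FALSE) {
    name_r <- charToRaw(name)
    body <- c(i8(dtype), i8(length(dims)), i8(dims), data_raw, i8(0))
    off <- if (last) 0L else length(body) + 2L
    c(i8(length(name_r)), i8(gid), name_r, u16r(off), body)
  }
  group_entry <- function(gid, name) {
    name_r <- charToRaw(name)
    body <- i8(0)  # zero-length description
    c(i8(length(name_r)), i8(-gid), name_r, u16r(length(body) + 2L), body)
  }

  labs <- series$labels
  w <- max(nchar(labs), 4)
  labs_pad <- formatC(labs, width = -w)
  entries <- c(
    group_entry(1, "POINT"),
    param_entry(1, "USED", 2, integer(), u16r(np)),
    param_entry(1, "FRAMES", 2, integer(), u16r(nf)),
    param_entry(1, "RATE", 4, integer(), f32r(series$rate)),
    param_entry(1, "SCALE", 4, integer(), f32r(-1)),
    param_entry(1, "UNITS", -1, length(charToRaw(units)),
                charToRaw(units)),
    param_entry(1, "LABELS", -1, c(w, np), charToRaw(paste(labs_pad, collapse = "")))
  )
  # DATA_START depends on parameter section length; 2 passes
  ds_entry <- function(ds, last = TRUE) {
    param_entry(1, "DATA_START", 2, integer(), u16r(ds), last = last)
  }
  plen <- 4 + length(entries) + length(ds_entry(0))
  n_param_blocks <- ceiling(plen / 512)
  data_start <- 2L + n_param_blocks
  param_sec <- c(i8(1), as.raw(0x50), i8(n_param_blocks), i8(C3D_PROC_INTEL),
                 entries, ds_entry(data_start))
  param_sec <- c(param_sec, raw(n_param_blocks * 512 - length(param_sec)))

  header <- c(i8(2), as.raw(0x50), u16r(np), u16r(0), u16r(1), u16r(nf),
              u16r(0), f32r(-1), u16r(data_start), u16r(0), f32r(series$rate))
  header <- c(header, raw(512 - length(header)))

  pos <- series$positions * scale
  resid <- ifelse(t(series$occluded), -1, 0)       # np x nf
  arr <- array(0, c(4, np, nf))
  arr[1:3, , ] <- aperm(ifelse(is.na(pos), 0, pos), c(3, 2, 1))
  arr[4, , ] <- resid
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, param_sec), con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}
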