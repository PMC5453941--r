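#' Read a trajectory file
#'
#' Two formats are supported: the package's plain-text multi-frame layout
#' (see Details) and binary DCD through a thin adapter over
#' `bio3d::read.dcd`.
#'
#' @details The text layout is: line 1 `natoms <N>`; then per frame one
#' header line `frame <time_ps> <bx> <by> <bz>` followed by N lines of
#' `x y z` in Angstrom.  Frames must be complete; a truncated final frame
#' is an error, not a silent short read.
#'
#' @param path File path.
#' @param top A [topology()] whose particle count must match the file.
#' @param format "auto" (from extension: .trj/.txt text, .dcd binary),
#'   "text" or "dcd".
#' @param temperature Temperature tag for the returned trajectory (K).
#' @return A [trajectory()], frames ordered by time.
#' @export
read_trajectory <- function(path, top, format = c("auto", "text", "dcd"),
                            temperature = 310) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- guess_format(path, c(trj = "text", txt = "text", dcd = "dcd"))
  }
  frames <- if (format == "text") read_text_frames(path) else read_dcd_frames(path)
  n <- n_particles(top)
  sizes <- vapply(frames, function(f) nrow(f$xyz), integer(1))
  if (any(sizes != n)) {
    abort(sprintf("Trajectory particle count mismatch: expected %d, found %d (frame %d).",
                  n, sizes[which(sizes != n)[1]], which(sizes != n)[1]))
  }
  frames <- frames[order(vapply(frames, `[[`, numeric(1), "time"))]
  trajectory(top, frames, temperature = temperature)
}

read_text_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^natoms\\s+\\d+", lines[1])) {
    abort(sprintf("Malformed trajectory %s: missing 'natoms N' header (line 1).", path))
  }
  n <- as.integer(sub("^natoms\\s+(\\d+).*$", "\\1", lines[1]))
  body <- lines[-1]
  per_frame <- n + 1L
  if (length(body) %% per_frame != 0L) {
    abort(sprintf("Truncated trajectory %s: %d lines after header is not a multiple of %d.",
                  path, length(body), per_frame))
  }
  n_fr <- length(body) %/% per_frame
  lapply(seq_len(n_fr), function(i) {
    off <- (i - 1L) * per_frame
    hdr <- strsplit(trimws(body[off + 1L]), "\\s+")[[1]]
    if (hdr[1] != "frame" || length(hdr) < 5L) {
      abort(sprintf("Malformed trajectory %s: bad frame header at frame %d.", path, i))
    }
    vals <- suppressWarnings(as.numeric(hdr[2:5]))
    m <- matrix(
      suppressWarnings(as.numeric(unlist(strsplit(trimws(body[off + 1L + seq_len(n)]), "\\s+")))),
      ncol = 3, byrow = TRUE
    )
    if (any(is.na(m)) || nrow(m) != n) {
      abort(sprintf("Malformed trajectory %s: unreadable coordinates in frame %d.", path, i))
    }
    frame(m, box = vals[2:4], time = vals[1])
  })
}

read_dcd_frames <- function(path) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  lapply(seq_len(nrow(xyz)), function(i) {
    frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE), time = i - 1)
  })
}

#' Write a trajectory in the plain-text multi-frame layout
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param digits Coordinate precision (decimal digits).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("natoms %d", n_particles(traj$topology)), con)
  fmt <- sprintf("%%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in traj$frames) {
    writeLines(sprintf("frame %g %g %g %g", f$time, f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf(fmt, f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
  }
  invisible(path)
}
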