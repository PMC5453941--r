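#' Build a particle table
#'
#' Particles are rows of a tibble; this constructor fills defaults and
#' validates the fields shared by all system components (protein beads or
#' atoms, lipids, ions).  `index` is a 0-based unique particle identifier
#' (I/O files carry 1-based residue numbers); row order defines coordinate
#' order in frames.
#'
#' @param name Particle/atom name (e.g. "BB", "CA", "PO4").
#' @param resid 1-based residue number.
#' @param resname Residue name (three-letter code for amino acids).
#' @param chain Chain identifier (single character).
#' @param group Group tag: one of "pore", "cargo", "lipid", "ion", "water"
#'   or any user label.
#' @param polarity Polarity class; if `NULL`, derived from `resname` via
#'   [classify_polarity()].
#' @param element Element symbol (all-atom structures); guessed from the
#'   atom name when `NULL`.
#' @param quiet Passed to [classify_polarity()].
#' @return A tibble with one row per particle.
#' @export
particles <- function(name, resid, resname, chain = "A", group = "pore",
                      polarity = NULL, element = NULL, quiet = FALSE) {
  n <- max(length(name), length(resid), length(resname))
  name <- rep_len(as.character(name), n)
  resid <- rep_len(as.integer(resid), n)
  resname <- rep_len(as.character(resname), n)
  chain <- rep_len(as.character(chain), n)
  group <- rep_len(as.character(group), n)
  if (is.null(polarity)) polarity <- classify_polarity(resname, quiet = quiet)
  if (is.null(element)) element <- guess_element(name)
  tibble(
    index = seq_len(n) - 1L, name = name, resid = resid, resname = resname,
    chain = chain, group = group,
    polarity = rep_len(as.character(polarity), n),
    element = rep_len(as.character(element), n)
  )
}

guess_element <- function(name) {
  # first alphabetic character of the atom name; CG bead names (BB, SC1,
  # PO4, W, NA+, ...) fall out as a plain letter and only matter for
  # all-atom radius lookup
  el <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
  toupper(el)
}

#' Construct a topology
#'
#' A topology couples the particle table with the structural annotations
#' the analyses need: the partition of pore particles into dimers (for the
#' ellipticity shape coordinate) and helix segment definitions (for
#' back-mapping).
#'
#' @param particles Tibble from [particles()].
#' @param dimers Named list mapping dimer label ("1".."n") to integer row
#'   positions (1-based) of that dimer's particles; must partition the
#'   "pore" rows if supplied.
#' @param helices List of helix segment definitions (see
#'   [helix_segments()]).
#' @return Object of class `topology`.
#' @export
topology <- function(particles, dimers = NULL, helices = NULL) {
  stopifnot(is.data.frame(particles))
  if (anyDuplicated(particles$index) > 0L) {
    abort("Particle `index` must be unique within a topology.")
  }
  if (!is.null(dimers)) {
    pore_rows <- which(particles$group == "pore")
    all_rows <- sort(unlist(dimers, use.names = FALSE))
    if (!identical(as.integer(all_rows), as.integer(sort(pore_rows)))) {
      abort("`dimers` must partition the rows tagged group == \"pore\".")
    }
  }
  structure(
    list(particles = as_tibble(particles), dimers = dimers,
         helices = helices),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  grp <- table(x$particles$group)
  cat(sprintf(
    "<topology> %d particles, %d residues (%s)%s\n",
    nrow(x$particles), length(unique(paste(x$particles$chain, x$particles$resid))),
    paste(sprintf("%s: %d", names(grp), as.integer(grp)), collapse = ", "),
    if (!is.null(x$dimers)) sprintf(", %d dimers", length(x$dimers)) else ""
  ))
  invisible(x)
}

n_particles <- function(top) nrow(top$particles)

#' Resolve a particle selection to row positions
#'
#' Selections accept: an integer vector of row positions; a logical vector
#' over rows; a character vector matched against group tags; or a
#' predicate function of the particle tibble returning a logical vector.
#'
#' @param top A [topology()].
#' @param sel Selection (see Details).
#' @param allow_empty If `FALSE` (default), an empty selection is an error.
#' @return Sorted integer row positions.
#' @export
select_particles <- function(top, sel, allow_empty = FALSE) {
  p <- top$particles
  rows <-
    if (is.numeric(sel)) as.integer(sel)
    else if (is.logical(sel)) {
      if (length(sel) != nrow(p)) abort("Logical selection has wrong length.")
      which(sel)
    } else if (is.character(sel)) which(p$group %in% sel)
    else if (is.function(sel)) which(sel(p))
    else abort("Unsupported selection type.")
  if (length(rows) && (min(rows) < 1L || max(rows) > nrow(p))) {
    abort("Selection indices out of range.")
  }
  if (!allow_empty && length(rows) == 0L) {
    abort("Selection is empty.")
  }
  sort(unique(rows))
}

#' Construct a coordinate frame
#'
#' @param xyz N x 3 numeric matrix of coordinates in Angstrom.
#' @param box Length-3 orthorhombic box lengths in Angstrom.
#' @param time Time stamp in ps.
#' @return Object of class `frame`.
#' @export
frame <- function(xyz, box = c(100, 100, 100), time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) abort("`xyz` must be an N x 3 matrix.")
  storage.mode(xyz) <- "double"
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    abort("`box` must be three positive lengths (orthorhombic boxes only).")
  }
  structure(list(xyz = xyz, box = box, time = as.numeric(time)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> %d particles, box %.1f x %.1f x %.1f A, t = %g ps\n",
              nrow(x$xyz), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Construct a trajectory
#'
#' An ordered sequence of frames over one topology, carrying the sampling
#' temperature used for Boltzmann inversion (default 310 K, body
#' temperature — the temperature at which analysis trajectories are
#' taken).
#'
#' @param topology A [topology()].
#' @param frames List of [frame()] objects, all with the topology's
#'   particle count.
#' @param temperature Temperature in K, > 0.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, temperature = 310) {
  stopifnot(inherits(topology, "topology"))
  if (!length(frames)) abort("A trajectory needs at least one frame.")
  n <- n_particles(topology)
  ok <- vapply(frames, function(f) nrow(f$xyz) == n, logical(1))
  if (!all(ok)) {
    abort(sprintf(
      "Frame particle count mismatch: topology has %d, frame(s) %s differ.",
      n, paste(which(!ok), collapse = ", ")
    ))
  }
  if (!is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be positive (K).")
  }
  structure(list(topology = topology, frames = frames,
                 temperature = as.numeric(temperature)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d particles at %g K\n",
              length(x$frames), n_particles(x$topology), x$temperature))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

frame_times <- function(traj) vapply(traj$frames, `[[`, numeric(1), "time")

#' Extract per-frame coordinates of a selection as a tibble
#'
#' Long-format view of a trajectory: one row per frame and particle, for
#' piping into dplyr/ggplot2 workflows.
#'
#' @param x A [trajectory()].
#' @param sel Optional selection (see [select_particles()]).
#' @param ... Unused.
#' @return Tibble with columns `frame`, `time`, `index`, `name`, `resid`,
#'   `resname`, `group`, `x`, `y`, `z`.
#' @export
tidy.trajectory <- function(x, sel = NULL, ...) {
  rows <- if (is.null(sel)) seq_len(n_particles(x$topology))
          else select_particles(x$topology, sel)
  p <- x$topology$particles[rows, c("index", "name", "resid", "resname", "group")]
  purrr::map_dfr(seq_along(x$frames), function(i) {
    xyz <- x$frames[[i]]$xyz[rows, , drop = FALSE]
    dplyr::bind_cols(
      tibble(frame = i, time = x$frames[[i]]$time), p,
      tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    )
  })
}
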