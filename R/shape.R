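#' Pore ellipticity (opposite-dimer distance spread)
#'
#' The pore-shape reaction coordinate: the difference between the longest
#' and shortest center-of-mass distance over the n/2 opposite dimer pairs
#' of the ring (pairing dimer i with dimer i + n/2).  Zero for a regular
#' polygon; grows as the ring deforms toward an ellipse.  Invariant under
#' rigid transforms.
#'
#' @param fr A [frame()].
#' @param top A [topology()] with `dimers` populated (or a named list of
#'   row-index vectors passed directly).
#' @return Delta-d in Angstrom (>= 0).
#' @export
pore_ellipticity <- function(fr, top) {
  dimers <- if (inherits(top, "topology")) top$dimers else top
  if (is.null(dimers)) abort("Topology has no dimer assignments.")
  n <- length(dimers)
  if (n %% 2 != 0) abort("Opposite-pair ellipticity needs an even number of dimers.")
  coms <- t(vapply(dimers, function(rows) colMeans(fr$xyz[rows, , drop = FALSE]),
                   numeric(3)))
  half <- n %/% 2
  d <- vapply(seq_len(half), function(i) {
    sqrt(sum((coms[i, ] - coms[i + half, ])^2))
  }, numeric(1))
  max(d) - min(d)
}

#' Per-frame ellipticity series
#'
#' @param traj A [trajectory()] whose topology carries dimer assignments.
#' @return Tibble with columns `frame`, `time`, `ellipticity` (A).
#' @export
ellipticity_series <- function(traj) {
  purrr::map_dfr(seq_len(n_frames(traj)), function(i) {
    tibble(frame = i, time = traj$frames[[i]]$time,
           ellipticity = pore_ellipticity(traj$frames[[i]], traj$topology))
  })
}

#' Central cavity diameter
#'
#' Twice the largest radius (on a `probe_step` grid) of a pore-axis
#' centered cylinder at z = 0 that contains no pore bead center, using
#' the beads within `slab_halfwidth` of the midplane.  Assumes a
#' pore-centered frame.
#'
#' @param fr A [frame()] (pore-centered).
#' @param top Topology (for the selection).
#' @param sel Pore selection.
#' @param probe_step Radius grid resolution, A.
#' @param slab_halfwidth Half-width of the z = 0 slab, A; `Inf` uses all
#'   selected beads.
#' @return Diameter in Angstrom.
#' @export
cavity_diameter <- function(fr, top, sel = "pore", probe_step = 0.5,
                            slab_halfwidth = Inf) {
  rows <- select_particles(top, sel)
  xyz <- fr$xyz[rows, , drop = FALSE]
  xyz <- xyz[abs(xyz[, 3]) <= slab_halfwidth, , drop = FALSE]
  if (!nrow(xyz)) abort("No pore beads in the z = 0 slab.")
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  2 * probe_step * floor(min(r) / probe_step)
}
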