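#' Recenter a trajectory on the pore axis and bilayer midplane
#'
#' Per frame, translates coordinates so that the xy center of mass of the
#' pore selection sits at the origin and z = 0 lies at the midpoint
#' between the mean z of the two leaflet planes (upper/lower split of the
#' leaflet selection, typically the PO4 headgroup beads).  The pore COM is
#' computed under the minimum-image convention, so a pore split across the
#' periodic boundary is handled as its unwrapped copy.  All axial ("z
#' distance") and radial ("xy distance") reaction coordinates downstream
#' assume this framing.
#'
#' @param traj A [trajectory()].
#' @param pore_sel Selection for the pore particles (default the "pore"
#'   group tag).
#' @param leaflet_sel Selection for the headgroup beads defining the two
#'   leaflet planes; `NULL` keeps the current z origin (pore COM z is used
#'   instead).
#' @return A recentered [trajectory()].
#' @export
recenter <- function(traj, pore_sel = "pore", leaflet_sel = NULL) {
  pore_rows <- select_particles(traj$topology, pore_sel)
  leaf_rows <- if (!is.null(leaflet_sel)) select_particles(traj$topology, leaflet_sel)
  frames <- lapply(traj$frames, function(f) {
    com <- com_min_image(f$xyz[pore_rows, , drop = FALSE], f$box)
    z0 <- if (is.null(leaf_rows)) com[3] else {
      z <- f$xyz[leaf_rows, 3]
      mid <- mean(z)
      upper <- z[z >= mid]; lower <- z[z < mid]
      if (!length(lower)) mid else (mean(upper) + mean(lower)) / 2
    }
    frame(sweep(f$xyz, 2, c(com[1], com[2], z0)), box = f$box, time = f$time)
  })
  trajectory(traj$topology, frames, temperature = traj$temperature)
}

#' Per-frame radius of gyration and RMSD series
#'
#' RMSD is computed after optimal rigid superposition ([kabsch_fit()])
#' onto the reference; Rg is mass-unweighted.
#'
#' @param traj A [trajectory()].
#' @param sel Selection (see [select_particles()]).
#' @param reference Reference: a frame number (default 1) or a [frame()]
#'   with the same selection size.
#' @return Tibble with columns `frame`, `time`, `rg`, `rmsd` (Angstrom).
#' @export
rg_rmsd_series <- function(traj, sel = "pore", reference = 1L) {
  rows <- select_particles(traj$topology, sel)
  ref_xyz <- if (inherits(reference, "frame")) {
    if (nrow(reference$xyz) == length(rows)) reference$xyz
    else if (nrow(reference$xyz) >= max(rows)) reference$xyz[rows, , drop = FALSE]
    else abort(sprintf(
      "Reference size %d does not match selection size %d.",
      nrow(reference$xyz), length(rows)))
  } else traj$frames[[reference]]$xyz[rows, , drop = FALSE]
  purrr::map_dfr(seq_along(traj$frames), function(i) {
    xyz <- traj$frames[[i]]$xyz[rows, , drop = FALSE]
    tibble(frame = i, time = traj$frames[[i]]$time,
           rg = radius_of_gyration(xyz), rmsd = rmsd_fit(xyz, ref_xyz))
  })
}

#' Pairwise frame-frame RMSD matrix
#'
#' Symmetric zero-diagonal matrix of superposed RMSD between all frame
#' pairs (after striding), as used to monitor structural equilibration.
#'
#' @param traj A [trajectory()].
#' @param sel Selection.
#' @param stride Keep every `stride`-th frame.
#' @return Symmetric matrix (Angstrom) with frame indices as dimnames.
#' @export
rmsd_matrix <- function(traj, sel = "pore", stride = 1L) {
  rows <- select_particles(traj$topology, sel)
  keep <- seq(1L, n_frames(traj), by = stride)
  if (length(keep) < 2L) abort("Need at least 2 frames after striding.")
  coords <- lapply(keep, function(i) traj$frames[[i]]$xyz[rows, , drop = FALSE])
  m <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (i in seq_along(keep)) {
    for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- rmsd_fit(coords[[i]], coords[[j]])
    }
  }
  m
}
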