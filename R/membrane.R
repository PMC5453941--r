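#' Axial density profile
#'
#' Normalized histogram of particle z positions over all frames of a
#' (pore-centered) trajectory; the density integrates to 1 over z.
#'
#' @param traj A [trajectory()].
#' @param sel Selection (e.g. a predicate picking PO4 beads, or "ion").
#' @param bin_width Bin width, A.
#' @param range Optional `c(lo, hi)` z range (defaults to the data extent).
#' @param species Label stored in the `species` column.
#' @return Object of class `axial_profile` (a tibble with columns
#'   `species`, `z`, `count`, `density`; bin width kept as an attribute).
#' @export
axial_density <- function(traj, sel, bin_width = 1, range = NULL,
                          species = "all") {
  rows <- select_particles(traj$topology, sel)
  z <- unlist(lapply(traj$frames, function(f) f$xyz[rows, 3]))
  if (is.null(range)) {
    range <- c(floor(min(z) / bin_width), ceiling(max(z) / bin_width)) * bin_width
    if (range[2] <= range[1]) range[2] <- range[1] + bin_width
  }
  edges <- seq(range[1], range[2], by = bin_width)
  idx <- findInterval(z, edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= length(edges) - 1L
  counts <- tabulate(idx[inside], nbins = length(edges) - 1L)
  out <- tibble(
    species = species,
    z = (edges[-1] + edges[-length(edges)]) / 2,
    count = counts,
    density = counts / (sum(counts) * bin_width)
  )
  structure(out, class = c("axial_profile", class(out)),
            bin_width = bin_width, n_obs = sum(counts))
}

#' Detect peaks in an axial profile and the implied bilayer thickness
#'
#' Local maxima after a 3-bin moving-average smoothing; the thickness is
#' the peak-to-peak distance of the two dominant peaks (e.g. the two
#' headgroup planes, expected near +-24 A), `NA` when fewer than two
#' peaks survive `min_separation`.
#'
#' @param profile An [axial_density()] result.
#' @param min_separation Minimum z distance between reported peaks, A.
#' @return List with `peaks` (tibble `z`, `density`, ordered by height)
#'   and `thickness` (A or `NA`).
#' @export
profile_peaks <- function(profile, min_separation = 10) {
  if (!nrow(profile)) abort("Empty profile.")
  d <- profile$density
  n <- length(d)
  sm <- if (n >= 3) stats::filter(d, rep(1 / 3, 3), sides = 2) else d
  sm[is.na(sm)] <- d[is.na(sm)]
  sm <- as.numeric(sm)
  is_peak <- vapply(seq_len(n), function(k) {
    (k == 1 || sm[k] >= sm[k - 1]) && (k == n || sm[k] > sm[k + 1]) && sm[k] > 0
  }, logical(1))
  cand <- order(sm, decreasing = TRUE)
  cand <- cand[is_peak[cand]]
  keep <- integer(0)
  for (k in cand) {
    if (!length(keep) || all(abs(profile$z[k] - profile$z[keep]) >= min_separation)) {
      keep <- c(keep, k)
    }
  }
  peaks <- tibble(z = profile$z[keep], density = profile$density[keep])
  thickness <- if (nrow(peaks) >= 2) abs(peaks$z[1] - peaks$z[2]) else NA_real_
  list(peaks = peaks, thickness = thickness)
}

#' Second-rank lipid chain order parameter
#'
#' For each lipid, the chain vector runs from its first to its last chain
#' bead (bead names matching `chain_pattern`); the order parameter is
#' `P2 = 0.5 (3 cos^2 tau - 1)` of the angle tau between that vector and
#' the membrane normal: 1 for perfectly aligned chains, 0 for an
#' isotropic melt, -0.5 for chains lying in the membrane plane.  `P2` is
#' averaged over lipids within each frame and over frames for the
#' trajectory mean.
#'
#' @param traj A [trajectory()].
#' @param sel Lipid selection (default the "lipid" group).
#' @param chain_pattern Regex picking the chain beads within each lipid
#'   residue (default `"^C"`).
#' @param normal Membrane normal (default +z).
#' @return List with `mean` (trajectory mean P2) and `per_frame` (tibble
#'   `frame`, `time`, `px`).
#' @export
chain_order_parameter <- function(traj, sel = "lipid", chain_pattern = "^C",
                                  normal = c(0, 0, 1)) {
  rows <- select_particles(traj$topology, sel)
  p <- traj$topology$particles[rows, ]
  chain_rows <- rows[grepl(chain_pattern, p$name)]
  if (!length(chain_rows)) abort("No chain beads match `chain_pattern` in the selection.")
  cp <- traj$topology$particles[chain_rows, ]
  key <- paste(cp$chain, cp$resid)
  uk <- unique(key)
  first <- chain_rows[match(uk, key)]
  last <- chain_rows[length(key) + 1L - match(uk, rev(key))]
  normal <- normal / sqrt(sum(normal^2))
  per_frame <- purrr::map_dfr(seq_len(n_frames(traj)), function(i) {
    f <- traj$frames[[i]]
    v <- f$xyz[last, , drop = FALSE] - f$xyz[first, , drop = FALSE]
    len <- sqrt(rowSums(v^2))
    bad <- len == 0
    if (any(bad)) warn(sprintf("%d zero-length chain vector(s) skipped in frame %d.",
                               sum(bad), i))
    ct <- (v[!bad, , drop = FALSE] %*% normal) / len[!bad]
    tibble(frame = i, time = f$time, px = mean(0.5 * (3 * ct^2 - 1)))
  })
  list(mean = mean(per_frame$px), per_frame = per_frame)
}
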