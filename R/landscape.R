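#' Reaction-coordinate values of a trajectory
#'
#' Supported coordinates: `"xy"` (planar radial distance of the selection
#' COM from the pore axis), `"z"` (axial distance), `"x"`/`"y"` (raw COM
#' components), and `"shape"` (pore ellipticity of the frame, see
#' [pore_ellipticity()]; requires dimer assignments in the topology).
#' Assumes a pore-centered trajectory (see [recenter()]).
#'
#' @param traj A [trajectory()].
#' @param sel Selection whose COM defines the positional coordinates
#'   (default the "cargo" group).
#' @param coords Character vector of coordinate names.
#' @return Tibble with columns `frame` plus one per coordinate.
#' @export
reaction_coords <- function(traj, sel = "cargo", coords = c("xy", "z")) {
  ok <- coords %in% c("xy", "z", "x", "y", "shape")
  if (!all(ok)) abort(sprintf("Unknown coordinate(s): %s", paste(coords[!ok], collapse = ", ")))
  rows <- select_particles(traj$topology, sel)
  out <- tibble(frame = seq_len(n_frames(traj)))
  coms <- t(vapply(traj$frames, function(f) colMeans(f$xyz[rows, , drop = FALSE]),
                   numeric(3)))
  for (cc in coords) {
    out[[cc]] <- switch(cc,
      xy = sqrt(coms[, 1]^2 + coms[, 2]^2),
      z = coms[, 3], x = coms[, 1], y = coms[, 2],
      shape = vapply(traj$frames, function(f) pore_ellipticity(f, traj$topology),
                     numeric(1))
    )
  }
  out
}

#' Bin a trajectory into a 2D probability histogram
#'
#' First half of Boltzmann inversion: the normalized positional histogram
#' `P` over two reaction coordinates.  Pair with [free_energy()] to get
#' `F = -RT ln P`.
#'
#' @inheritParams reaction_coords
#' @param bin_width Bin widths for the two coordinates, A (defaults 2 A;
#'   use 1 A for the "shape" coordinate).
#' @param ranges Optional list of two `c(lo, hi)` ranges; defaults snap to
#'   the data extent on a grid aligned to multiples of the bin width.
#' @return Object of class `landscape_grid`: tibble of bins (`i`, `j`,
#'   centers, `count`, `p`) with edges, coordinate names and the
#'   trajectory temperature attached.
#' @export
bin_probability <- function(traj, sel = "cargo", coords = c("xy", "z"),
                            bin_width = c(2, 2), ranges = NULL) {
  if (!n_frames(traj)) abort("Empty trajectory.")
  bin_width <- rep_len(bin_width, 2)
  vals <- reaction_coords(traj, sel, coords)
  v1 <- vals[[coords[1]]]; v2 <- vals[[coords[2]]]
  edges <- purrr::map2(list(v1, v2), bin_width, function(v, w) {
    if (!is.null(ranges)) return(NULL)
    lo <- floor(min(v) / w) * w
    hi <- ceiling(max(v) / w) * w
    if (hi <= lo) hi <- lo + w
    seq(lo, hi, by = w)
  })
  if (!is.null(ranges)) {
    edges <- purrr::map2(ranges, bin_width, function(r, w) seq(r[1], r[2], by = w))
  }
  i <- findInterval(v1, edges[[1]], rightmost.closed = TRUE)
  j <- findInterval(v2, edges[[2]], rightmost.closed = TRUE)
  n1 <- length(edges[[1]]) - 1L; n2 <- length(edges[[2]]) - 1L
  inside <- i >= 1 & i <= n1 & j >= 1 & j <= n2
  counts <- matrix(0L, n1, n2)
  tt <- table(factor(i[inside], levels = seq_len(n1)),
              factor(j[inside], levels = seq_len(n2)))
  counts[] <- as.integer(tt)
  total <- sum(counts)
  if (!total) abort("No samples fall inside the requested ranges.")
  ctr1 <- (edges[[1]][-1] + edges[[1]][-(n1 + 1)]) / 2
  ctr2 <- (edges[[2]][-1] + edges[[2]][-(n2 + 1)]) / 2
  bins <- tidyr::expand_grid(j = seq_len(n2), i = seq_len(n1))
  bins <- bins[, c("i", "j")]
  bins[[coords[1]]] <- ctr1[bins$i]
  bins[[coords[2]]] <- ctr2[bins$j]
  bins$count <- as.integer(counts[cbind(bins$i, bins$j)])
  bins$p <- bins$count / total
  structure(
    list(bins = as_tibble(bins), edges = edges, coords = coords,
         temperature = traj$temperature, n_samples = total,
         reference = NA_character_),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %s x %s, %d x %d bins, %d samples%s\n",
              x$coords[1], x$coords[2], length(x$edges[[1]]) - 1L,
              length(x$edges[[2]]) - 1L, x$n_samples,
              if (!is.na(x$reference)) sprintf(", F ref = %s", x$reference) else ""))
  invisible(x)
}

#' @export
tidy.landscape_grid <- function(x, ...) x$bins

#' Boltzmann-invert a probability grid into free energies
#'
#' `F = -RT ln P` over the occupied bins, shifted according to the
#' reference convention:
#' \describe{
#'   \item{plateau}{never-sampled bins define the zero of free energy
#'     (F = 0, flagged unsampled); occupied bins are shifted so the
#'     least-sampled occupied bin sits at 0 and may therefore be
#'     negative.  This matches taking the unsampled plateau far from the
#'     pore as the energy reference.}
#'   \item{max_F}{same shift, but unsampled bins are `NA`.}
#'   \item{global_min}{the deepest occupied bin is 0; unsampled bins `NA`.}
#' }
#' Free-energy differences between occupied bins are invariant to the
#' choice.
#'
#' @param grid A [bin_probability()] result.
#' @param temperature Temperature, K (defaults to the grid's trajectory
#'   temperature).
#' @param reference Reference convention (see Details).
#' @return The grid with columns `f` (kcal/mol) and `sampled` added.
#' @export
free_energy <- function(grid, temperature = NULL,
                        reference = c("plateau", "max_F", "global_min")) {
  stopifnot(inherits(grid, "landscape_grid"))
  reference <- match.arg(reference)
  if (is.null(temperature)) temperature <- grid$temperature
  if (!is.finite(temperature) || temperature <= 0) abort("`temperature` must be positive (K).")
  rt <- R_KCAL * temperature
  p <- grid$bins$p
  occ <- p > 0
  f <- rep(NA_real_, length(p))
  f[occ] <- -rt * log(p[occ])
  shift <- switch(reference,
    plateau = max(f[occ]), max_F = max(f[occ]), global_min = min(f[occ]))
  f <- f - shift
  if (reference == "plateau") f[!occ] <- 0
  grid$bins$f <- f
  grid$bins$sampled <- occ
  grid$temperature <- temperature
  grid$reference <- reference
  grid
}

#' Define a rectangular region over two reaction coordinates
#'
#' @param name Region label.
#' @param ... Named `c(lo, hi)` windows, one per coordinate (e.g.
#'   `xy = c(25, 40), z = c(15, 30)`).
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(name, ...) {
  wins <- list(...)
  ok <- vapply(wins, function(w) length(w) == 2 && w[2] > w[1], logical(1))
  if (!length(wins) || !all(ok)) abort("Each window must be a non-degenerate c(lo, hi).")
  structure(list(name = name, windows = wins), class = "region_spec")
}

#' The three release-stage regions
#'
#' Shipped defaults for the three stages of cargo release through the
#' pore: stage 1 at the wider (entry) mouth, stage 2 in the inner cavity,
#' stage 3 at the narrower (exit) mouth, specified as (xy, z) windows in
#' Angstrom.
#'
#' @return List of three [region_spec()] objects named "1", "2", "3".
#' @export
stage_regions <- function() {
  list(
    region_spec("1", xy = c(25, 40), z = c(15, 30)),
    region_spec("2", xy = c(0, 10), z = c(-5, 5)),
    region_spec("3", xy = c(10, 25), z = c(-30, -20))
  )
}

#' Decompose a 2D landscape into stage-wise 1D PMF profiles
#'
#' For each region, the probability is marginalized over the other
#' coordinate inside the region's windows, then Boltzmann-inverted with
#' the grid's reference convention.  A region whose windows fall outside
#' the grid yields an empty segment with a warning.  A region list of
#' `NULL` uses the full grid as one region.
#'
#' @param grid A [free_energy()] grid (probability grids are accepted and
#'   inverted with the plateau convention).
#' @param axis Which grid coordinate the profile runs along.
#' @param regions List of [region_spec()]s (default one region covering
#'   the whole grid).
#' @return Object of class `pmf_profile`: tibble with columns `region`,
#'   `center`, `count`, `p`, `f`, `sampled`; axis, temperature and
#'   reference kept as attributes.
#' @export
pmf_1d <- function(grid, axis = "z", regions = NULL) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (!axis %in% grid$coords) {
    abort(sprintf("Axis '%s' not in grid coordinates (%s).", axis,
                  paste(grid$coords, collapse = ", ")))
  }
  if (is.na(grid$reference)) grid <- free_energy(grid)
  rt <- R_KCAL * grid$temperature
  other <- setdiff(grid$coords, axis)
  if (is.null(regions)) {
    regions <- list(structure(list(name = "all", windows = list()), class = "region_spec"))
  }
  segs <- purrr::map_dfr(regions, function(rg) {
    b <- grid$bins
    for (cc in names(rg$windows)) {
      w <- rg$windows[[cc]]
      b <- b[b[[cc]] >= w[1] & b[[cc]] <= w[2], , drop = FALSE]
    }
    if (!nrow(b)) {
      warn(sprintf("Region '%s' lies outside the grid; empty segment.", rg$name))
      return(tibble(region = character(), center = numeric(), count = integer(),
                    p = numeric(), f = numeric(), sampled = logical()))
    }
    m <- dplyr::summarise(dplyr::group_by(b, center = .data[[axis]]),
                          count = sum(.data$count), .groups = "drop")
    m <- dplyr::arrange(m, .data$center)
    tot <- sum(m$count)
    m$p <- if (tot > 0) m$count / tot else 0
    occ <- m$p > 0
    f <- rep(NA_real_, nrow(m))
    if (any(occ)) {
      f[occ] <- -rt * log(m$p[occ])
      shift <- if (grid$reference == "global_min") min(f[occ]) else max(f[occ])
      f <- f - shift
    }
    if (grid$reference == "plateau") f[!occ] <- 0
    tibble(region = rg$name, center = m$center, count = as.integer(m$count),
           p = m$p, f = f, sampled = occ)
  })
  structure(segs, class = c("pmf_profile", class(segs)),
            axis = axis, temperature = grid$temperature,
            reference = grid$reference)
}

#' Locate basins and inter-basin barriers on a 1D PMF profile
#'
#' Basins are local minima of the finite free-energy profile (below the
#' reference under the plateau convention); the barrier from basin A to
#' basin B is the maximum free energy on the profile between them minus
#' F(A), reported for both directions of each adjacent pair.
#'
#' @param profile A [pmf_1d()] result.
#' @return List with tibbles `basins` (`region`, `center`, `f`) and
#'   `barriers` (`from`, `to`, `barrier` in kcal/mol, >= 0).
#' @export
basin_barriers <- function(profile) {
  stopifnot(inherits(profile, "pmf_profile"))
  f <- profile$f
  fin <- is.finite(f) & profile$sampled
  if (!any(fin)) abort("Profile has no finite sampled bins.")
  idx <- which(fin)
  fv <- f[idx]
  n <- length(fv)
  is_min <- vapply(seq_len(n), function(k) {
    left <- if (k > 1) fv[k] < fv[k - 1] else TRUE
    right <- if (k < n) fv[k] < fv[k + 1] else TRUE
    left && right
  }, logical(1))
  if (attr(profile, "reference") %in% c("plateau", "max_F")) {
    is_min <- is_min & fv < 0
  }
  basins <- idx[is_min]
  btab <- tibble(region = profile$region[basins],
                 center = profile$center[basins], f = f[basins])
  if (length(basins) < 2L) {
    return(list(basins = btab,
                barriers = tibble(from = numeric(), to = numeric(),
                                  barrier = numeric())))
  }
  bar <- purrr::map_dfr(seq_len(length(basins) - 1L), function(k) {
    a <- basins[k]; b <- basins[k + 1L]
    seg <- f[seq(a, b)]
    top <- max(seg[is.finite(seg)])
    tibble(from = profile$center[c(a, b)], to = profile$center[c(b, a)],
           barrier = c(top - f[a], top - f[b]))
  })
  list(basins = btab, barriers = bar)
}
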