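#' Generate a synthetic coarse-grained bilayer
#'
#' Each lipid is one PO4 headgroup bead near its leaflet plane plus a
#' short chain of beads along a direction drawn from a von Mises-Fisher
#' distribution about the membrane normal.  The defaults emulate the
#' reference membrane geometry: headgroup planes at +-24 A (i.e. a
#' 48 A peak-to-peak thickness).  `tilt_kappa = Inf` gives perfectly
#' aligned chains (order parameter exactly 1); `tilt_kappa = 0` gives
#' isotropic chains (order parameter 0 in expectation).  Use
#' [kappa_for_order()] to target a mean order parameter such as 0.60.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (>= 1).
#' @param headgroup_z Leaflet plane position, A (planes at `+-headgroup_z`).
#' @param z_sigma Gaussian spread of headgroup z about its plane, A.
#' @param tilt_kappa von Mises-Fisher concentration of the chain direction
#'   about the normal (0 = isotropic, Inf = aligned).
#' @param n_chain_beads Beads per chain (>= 2).
#' @param bead_spacing Distance between consecutive chain beads, A.
#' @param box Box lengths, A; `NULL` sizes xy from ~65 A^2 per lipid.
#' @param seed Integer seed.
#' @return List with `topology` and `frame`.
#' @export
make_bilayer <- function(n_lipids_per_leaflet, headgroup_z = 24, z_sigma = 1,
                         tilt_kappa = 10, n_chain_beads = 4, bead_spacing = 3.5,
                         box = NULL, seed = NULL) {
  stopifnot(n_lipids_per_leaflet >= 1, n_chain_beads >= 2)
  if (is.null(box)) {
    side <- max(20, sqrt(2 * n_lipids_per_leaflet * 65 / 2))
    box <- c(side, side, max(2.5 * headgroup_z + 20, 100))
  }
  gen <- function() {
    n <- 2L * as.integer(n_lipids_per_leaflet)
    leaflet <- rep(c(1, -1), each = n_lipids_per_leaflet)
    hx <- runif(n, 0, box[1]); hy <- runif(n, 0, box[2])
    hz <- leaflet * headgroup_z + rnorm(n, 0, z_sigma)
    dirs <- rvmf(n, tilt_kappa)
    beads_per <- 1L + n_chain_beads
    xyz <- matrix(0, n * beads_per, 3)
    for (i in seq_len(n)) {
      o <- (i - 1L) * beads_per
      xyz[o + 1L, ] <- c(hx[i], hy[i], hz[i])
      # chain extends from the headgroup toward the midplane
      for (k in seq_len(n_chain_beads)) {
        xyz[o + 1L + k, ] <- c(hx[i], hy[i], hz[i]) -
          leaflet[i] * k * bead_spacing * dirs[i, ]
      }
    }
    nm <- rep(c("PO4", paste0("C", seq_len(n_chain_beads))), n)
    p <- particles(name = nm, resid = rep(seq_len(n), each = beads_per),
                   resname = "DSPC", chain = rep(ifelse(leaflet > 0, "U", "L"), each = beads_per),
                   group = "lipid", polarity = "polar_uncharged", quiet = TRUE)
    list(topology = topology(p), frame = frame(xyz, box = box))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# von Mises-Fisher unit vectors about +z; kappa = 0 is uniform on the
# sphere, kappa = Inf exactly (0,0,1).
rvmf <- function(n, kappa) {
  if (is.infinite(kappa)) {
    return(matrix(rep(c(0, 0, 1), each = n), n, 3))
  }
  w <- if (kappa == 0) runif(n, -1, 1) else {
    xi <- runif(n)
    1 + log(xi + (1 - xi) * exp(-2 * kappa)) / kappa
  }
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  cbind(s * cos(phi), s * sin(phi), w)
}

#' Mean second-rank order parameter of a von Mises-Fisher tilt distribution
#'
#' Closed form `1 - 3 L(kappa)/kappa` with the Langevin function
#' `L(kappa) = coth(kappa) - 1/kappa`; limits 0 (kappa = 0) and 1
#' (kappa = Inf).
#'
#' @param kappa Concentration parameter (>= 0).
#' @return Expected `P2 = 0.5(3 cos^2 - 1)` of the chain tilt.
#' @export
order_parameter_mean <- function(kappa) {
  ifelse(is.infinite(kappa), 1,
         ifelse(kappa < 1e-8, 0,
                1 - 3 * (1 / tanh(kappa) - 1 / kappa) / kappa))
}

#' Invert the mean order parameter for the tilt concentration
#'
#' @param p2 Target mean order parameter in (0, 1).
#' @return `kappa` such that `order_parameter_mean(kappa) == p2`.
#' @export
kappa_for_order <- function(p2) {
  if (p2 <= 0 || p2 >= 1) abort("`p2` must be strictly inside (0, 1).")
  stats::uniroot(function(k) order_parameter_mean(k) - p2,
                 lower = 1e-6, upper = 1e6, tol = 1e-10)$root
}

#' Generate a ring-of-dimers pore assembly
#'
#' Dimer centers of mass are placed at the vertices of a regular n-gon of
#' radius `ring_radius`, optionally stretched by `stretch` along x (so the
#' ring becomes an ellipse and the shape coordinate [pore_ellipticity()]
#' becomes positive).  Each dimer is `beads_per_dimer` beads arranged
#' symmetrically about its vertex, so the dimer COM sits exactly on the
#' vertex.  Defaults emulate a six-dimer ring whose opposite-vertex
#' distance is the ~48 A inner cavity.
#'
#' @param n_dimers Even number of dimers (default 6; 8 for the larger pore).
#' @param ring_radius Ring radius, A (default 24).
#' @param stretch Unitless x-scaling >= 1 (1 = regular polygon).
#' @param beads_per_dimer Beads per dimer (>= 2).
#' @param bead_spread Radius of the per-dimer bead circle, A.
#' @param z_extent Half-extent of the bead stack along z, A.
#' @param resnames Residue names cycled over beads (defaults mix polarity
#'   classes); each bead is its own residue.
#' @param jitter_sigma Gaussian positional noise on beads, A (0 keeps COMs
#'   exactly on the vertices).
#' @param seed Integer seed (only used when `jitter_sigma > 0`).
#' @return List with `topology` (dimer assignments populated) and `frame`.
#' @export
make_pore_assembly <- function(n_dimers = 6, ring_radius = 24, stretch = 1,
                               beads_per_dimer = 12, bead_spread = 2,
                               z_extent = 8, resnames = NULL,
                               jitter_sigma = 0, seed = NULL) {
  if (n_dimers %% 2 != 0) {
    abort("`n_dimers` must be even: opposite-vertex pairing requires it.")
  }
  stopifnot(n_dimers >= 2, beads_per_dimer >= 2, stretch >= 1)
  if (is.null(resnames)) resnames <- c("LYS", "GLU", "SER", "LEU", "ALA", "THR")
  gen <- function() {
    theta <- 2 * pi * (seq_len(n_dimers) - 1) / n_dimers
    vx <- stretch * ring_radius * cos(theta)
    vy <- ring_radius * sin(theta)
    phi <- 2 * pi * (seq_len(beads_per_dimer) - 1) / beads_per_dimer
    zoff <- if (beads_per_dimer > 1) seq(-z_extent, z_extent, length.out = beads_per_dimer) else 0
    zoff <- zoff - mean(zoff)
    xyz <- matrix(0, n_dimers * beads_per_dimer, 3)
    dimers <- list()
    for (d in seq_len(n_dimers)) {
      o <- (d - 1L) * beads_per_dimer
      xyz[o + seq_len(beads_per_dimer), ] <- cbind(
        vx[d] + bead_spread * cos(phi), vy[d] + bead_spread * sin(phi), zoff
      )
      dimers[[as.character(d)]] <- o + seq_len(beads_per_dimer)
    }
    if (jitter_sigma > 0) xyz <- xyz + rnorm(length(xyz), 0, jitter_sigma)
    n <- nrow(xyz)
    p <- particles(name = "BB", resid = seq_len(n),
                   resname = rep_len(resnames, n),
                   chain = rep(LETTERS[(seq_len(n_dimers) - 1) %% 26 + 1],
                               each = beads_per_dimer),
                   group = "pore", quiet = TRUE)
    side <- 2 * (stretch * ring_radius + bead_spread) + 40
    list(topology = topology(p, dimers = dimers),
         frame = frame(xyz, box = c(side, side, 120)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Place cargo replicas along the pore axis with random orientations
#'
#' Emulates the replica seeding of the reference setup: the cargo is
#' placed at `n_axial` z positions spaced `axial_spacing` apart (13 A by
#' default), centered on z = 0, with `n_orientations` uniformly random
#' rigid orientations at each position (6 x 8 = 48 initial frames by
#' default).  When a pore frame is supplied, placements at the two mouth
#' positions are re-rolled (up to `max_retries`) until no cargo bead comes
#' within `min_dist` of a pore bead.
#'
#' @param cargo List with `topology` and `frame` (e.g. from
#'   [read_structure()]), or a [frame()] alone.
#' @param n_axial Number of axial positions (default 6).
#' @param axial_spacing Axial spacing, A (default 13).
#' @param n_orientations Orientations per position (default 8).
#' @param seed Integer seed.
#' @param pore Optional list with `topology`/`frame` of the pore for the
#'   mouth-clash check.
#' @param min_dist Clash distance, A.
#' @param max_retries Re-roll cap per placement.
#' @return Tibble with columns `position` (1..n_axial), `orientation`
#'   (1..n_orientations), `z` and `frame` (list column of [frame()]s).
#' @export
place_cargo_replicas <- function(cargo, n_axial = 6, axial_spacing = 13,
                                 n_orientations = 8, seed = NULL, pore = NULL,
                                 min_dist = 3, max_retries = 100) {
  stopifnot(n_axial >= 1, n_orientations >= 1, axial_spacing > 0)
  fr <- if (inherits(cargo, "frame")) cargo else cargo$frame
  if (!nrow(fr$xyz)) abort("Cargo has no particles.")
  pore_xyz <- if (!is.null(pore)) (if (inherits(pore, "frame")) pore else pore$frame)$xyz
  zs <- (seq_len(n_axial) - (n_axial + 1) / 2) * axial_spacing
  mouth <- c(1L, n_axial)
  base <- sweep(fr$xyz, 2, colMeans(fr$xyz))
  gen <- function() {
    purrr::map_dfr(seq_len(n_axial), function(i) {
      purrr::map_dfr(seq_len(n_orientations), function(j) {
        for (try in seq_len(max_retries)) {
          R <- random_rotation()
          xyz <- sweep(base %*% t(R), 2, c(0, 0, zs[i]), `+`)
          clash <- !is.null(pore_xyz) && i %in% mouth &&
            min_pair_dist(xyz, pore_xyz) < min_dist
          if (!clash) {
            return(tibble(position = i, orientation = j, z = zs[i],
                          frame = list(frame(xyz, box = fr$box, time = 0))))
          }
        }
        abort(sprintf("Placement failed: %d retries exhausted at position %d.",
                      max_retries, i))
      })
    })
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Uniform random rotation matrix (Shoemake quaternion method).
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

min_pair_dist <- function(a, b) {
  m <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sqrt(colSums((t(b) - a[i, ])^2))
    m <- min(m, min(d))
  }
  m
}

#' Add counter ions to a system
#'
#' Ion counts follow `round(c * N_A * V)` per species.  Divalent calcium
#' is placed with a two-slab acceptance bias enriching it near the leaflet
#' planes (emulating the observed surface accumulation statistically, not
#' mechanistically); chloride is added automatically to bring the net
#' charge of the added ions to zero.  Default concentrations are the
#' 0.035 M NaCl + 0.035 M CaCl2 of the emulated setup.
#'
#' @param top A [topology()].
#' @param fr The matching [frame()]; ions are placed inside its box.
#' @param concentrations Named vector, mol/L; names among "NA", "CA", "K",
#'   "MG".
#' @param surface_enrichment Density factor (>= 1) for Ca2+ in the two
#'   slabs of half-width `slab_halfwidth` around `+-headgroup_z`.
#' @param headgroup_z Leaflet plane position, A.
#' @param slab_halfwidth Enrichment slab half-width, A.
#' @param seed Integer seed.
#' @return List with the augmented `topology` and `frame`, plus `counts`
#'   (named ion counts including CL).
#' @export
add_ions <- function(top, fr, concentrations = c("NA" = 0.035, "CA" = 0.035),
                     surface_enrichment = 1, headgroup_z = 24,
                     slab_halfwidth = 5, seed = NULL) {
  if (any(concentrations < 0)) abort("Concentrations must be non-negative.")
  v_l <- prod(fr$box) * 1e-27          # A^3 -> litres
  if (v_l <= 0) abort("Box volume must be positive.")
  charges <- c("NA" = 1, "CA" = 2, "K" = 1, "MG" = 2)
  unknown <- setdiff(names(concentrations), names(charges))
  if (length(unknown)) abort(sprintf("Unknown ion species: %s", paste(unknown, collapse = ", ")))
  counts <- round(concentrations * 6.02214076e23 * v_l)
  n_cl <- sum(counts * charges[names(counts)])
  gen <- function() {
    place <- function(n, enrich) {
      if (n == 0) return(matrix(0, 0, 3))
      out <- matrix(0, n, 3)
      k <- 0L
      while (k < n) {
        z <- runif(1, -fr$box[3] / 2, fr$box[3] / 2)
        in_slab <- abs(abs(z) - headgroup_z) <= slab_halfwidth
        if (enrich <= 1 || in_slab || runif(1) < 1 / enrich) {
          k <- k + 1L
          out[k, ] <- c(runif(1, 0, fr$box[1]), runif(1, 0, fr$box[2]), z)
        }
      }
      out
    }
    species <- c(names(counts), "CL")
    ns <- c(counts, CL = n_cl)
    xyz <- do.call(rbind, lapply(species, function(s) {
      place(ns[[s]], if (s == "CA") surface_enrichment else 1)
    }))
    pol <- ifelse(species == "CL", "negative", "positive")
    p_ion <- particles(
      name = rep(species, ns), resid = max(top$particles$resid, 0) + seq_len(sum(ns)),
      resname = rep(species, ns), chain = "I", group = "ion",
      polarity = rep(pol, ns), quiet = TRUE
    )
    p_all <- dplyr::bind_rows(top$particles, p_ion)
    p_all$index <- seq_len(nrow(p_all)) - 1L
    list(topology = topology(p_all, dimers = top$dimers, helices = top$helices),
         frame = frame(rbind(fr$xyz, xyz), box = fr$box, time = fr$time),
         counts = setNames(as.integer(ns), species),
         charge = sum(c(charges[names(counts)], CL = -1)[species] * ns))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Build an ideal C-alpha helix (synthetic reference fragment)
#'
#' Canonical alpha-helix C-alpha trace (rise 1.5 A, 100 degrees per
#' residue, radius 2.3 A) along +z, used as a synthetic all-atom
#' reference fragment for back-mapping tests and demos.
#'
#' @param n_res Number of residues.
#' @param resnames Residue names (recycled; default "ALA").
#' @param chain Chain id.
#' @param group Group tag.
#' @return List with `topology` and `frame`.
#' @export
ideal_helix <- function(n_res, resnames = "ALA", chain = "A", group = "pore") {
  stopifnot(n_res >= 4)
  i <- seq_len(n_res)
  ang <- (i - 1) * 100 * pi / 180
  xyz <- cbind(2.3 * cos(ang), 2.3 * sin(ang), (i - 1) * 1.5)
  p <- particles(name = "CA", resid = i, resname = rep_len(resnames, n_res),
                 chain = chain, group = group, quiet = TRUE)
  list(topology = topology(p), frame = frame(xyz, box = c(100, 100, 100)))
}
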