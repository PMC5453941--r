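#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-counting SASA with a deterministic golden-spiral point set on
#' each expanded atom sphere.  Radii default to a heavy-atom element
#' table for all-atom structures (`resolution = "aa"`, probe 1.4 A) or a
#' uniform 2.3 A bead radius for coarse-grained systems
#' (`resolution = "cg"`, probe 2.6 A — half a CG water bead).
#'
#' @param top A [topology()].
#' @param fr The matching [frame()].
#' @param sel Optional selection restricting the computation (other
#'   particles are ignored entirely, as if absent).
#' @param resolution "aa" or "cg" (sets default radii and probe).
#' @param radii Named vector overriding per-element radii ("aa") or a
#'   single bead radius ("cg"); an unnamed length-1 value is used for all
#'   particles.
#' @param probe Probe radius, A.
#' @param n_points Sphere points per atom (accuracy ~ 1/sqrt(n)).
#' @return Tibble with one row per residue: `chain`, `resid`, `resname`,
#'   `polarity`, `area` (A^2).  Per-atom areas are attached as the
#'   `"atom_area"` attribute.
#' @export
sasa <- function(top, fr, sel = NULL, resolution = c("aa", "cg"),
                 radii = NULL, probe = NULL, n_points = 960) {
  resolution <- match.arg(resolution)
  rows <- if (is.null(sel)) seq_len(n_particles(top)) else select_particles(top, sel)
  p <- top$particles[rows, ]
  if (is.null(probe)) probe <- if (resolution == "aa") 1.4 else 2.6
  r <- atom_radii(p, resolution, radii)
  pts <- golden_sphere(n_points)
  area <- sasa_cpp(fr$xyz[rows, , drop = FALSE], r, probe, pts)
  per_res <- dplyr::summarise(
    dplyr::group_by(
      tibble(chain = p$chain, resid = p$resid, resname = p$resname,
             polarity = p$polarity, area = area),
      .data$chain, .data$resid, .data$resname, .data$polarity
    ),
    area = sum(.data$area), .groups = "drop"
  )
  attr(per_res, "atom_area") <- area
  attr(per_res, "probe") <- probe
  per_res
}

.aa_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
               F = 1.47, FE = 1.8, ZN = 1.39, MG = 1.73, CA = 1.97,
               NA. = 2.27, CL = 1.75, K = 2.75)

atom_radii <- function(p, resolution, radii) {
  if (!is.null(radii) && is.null(names(radii)) && length(radii) == 1) {
    return(rep(as.numeric(radii), nrow(p)))
  }
  if (resolution == "cg") {
    return(rep(if (is.null(radii)) 2.3 else as.numeric(radii[1]), nrow(p)))
  }
  tab <- .aa_radii
  names(tab)[names(tab) == "NA."] <- "NA"
  if (!is.null(radii)) tab[names(radii)] <- radii
  r <- unname(tab[p$element])
  if (anyNA(r)) {
    abort(sprintf("No radius for element(s): %s",
                  paste(sort(unique(p$element[is.na(r)])), collapse = ", ")))
  }
  r
}

# Deterministic, near-uniform unit-sphere point set (golden spiral).
golden_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Four-class surface decomposition
#'
#' Sums per-residue SASA by polarity class (positive, negative, polar
#' uncharged, hydrophobic) and reports areas and fractions; the
#' hydrophilic fraction is positive + negative + polar uncharged.
#'
#' @param per_residue_sasa A [sasa()] result (or any tibble with
#'   `polarity` and `area` columns).
#' @return Object of class `surface_decomposition`: tibble with one row
#'   per class (`class`, `area`, `fraction`), with `total` and
#'   `hydrophilic_fraction` attributes.
#' @export
surface_decomposition <- function(per_residue_sasa) {
  classes <- c("positive", "negative", "polar_uncharged", "hydrophobic")
  a <- vapply(classes, function(cl) {
    sum(per_residue_sasa$area[per_residue_sasa$polarity == cl])
  }, numeric(1))
  total <- sum(a)
  out <- tibble(class = classes, area = unname(a),
                fraction = if (total > 0) unname(a) / total else rep(NA_real_, 4))
  structure(out, class = c("surface_decomposition", class(out)),
            total = total,
            hydrophilic_fraction = sum(out$fraction[out$class %in% .hydrophilic_classes]))
}

#' @export
glance.surface_decomposition <- function(x, ...) {
  tibble(total_area = attr(x, "total"),
         hydrophilic_fraction = attr(x, "hydrophilic_fraction"),
         positive_fraction = x$fraction[x$class == "positive"],
         negative_fraction = x$fraction[x$class == "negative"],
         polar_fraction = x$fraction[x$class == "polar_uncharged"],
         hydrophobic_fraction = x$fraction[x$class == "hydrophobic"])
}

#' Buried surface fraction of a component in a complex
#'
#' Percentage of the component's isolated SASA occluded in the complex:
#' `(SASA_isolated - SASA_in_complex) / SASA_isolated * 100`.
#'
#' @param top Complex topology.
#' @param fr Complex frame.
#' @param component_sel Selection of the component (subset of the
#'   complex).
#' @inheritParams sasa
#' @return Percentage in `[0, 100]`.
#' @export
buried_fraction <- function(top, fr, component_sel, resolution = c("aa", "cg"),
                            radii = NULL, probe = NULL, n_points = 960) {
  resolution <- match.arg(resolution)
  rows <- select_particles(top, component_sel)
  s_iso <- sum(sasa(top, fr, sel = rows, resolution = resolution,
                    radii = radii, probe = probe, n_points = n_points)$area)
  if (s_iso <= 0) abort("Component has zero isolated surface area.")
  full <- sasa(top, fr, resolution = resolution, radii = radii, probe = probe,
               n_points = n_points)
  atom_area <- attr(full, "atom_area")
  s_cplx <- sum(atom_area[rows])
  (s_iso - s_cplx) / s_iso * 100
}
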