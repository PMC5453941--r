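#' Potential specifications for the synthetic samplers
#'
#' Analytic stand-ins for the free-energy surface a cargo particle samples.
#' Three functional forms are supported: multidimensional harmonic wells,
#' a quartic double well along one axis (harmonic in the others), and
#' tabulated 1D/2D grids with linear interpolation (infinite outside the
#' stated domain).  Energies are kcal/mol, lengths Angstrom.
#'
#' @param k Stiffness (kcal/mol/A^2), recycled over dimensions.
#' @param center Well center(s), recycled over dimensions.
#' @param dim Dimensionality (1-3).
#' @return Object of class `potential_spec`.
#' @export
#' @examples
#' pot <- potential_harmonic(k = 1, dim = 1)
#' potential_energy(pot, 2)  # 0.5 * 1 * 2^2
potential_harmonic <- function(k = 1, center = 0, dim = 1) {
  k <- rep_len(k, dim); center <- rep_len(center, dim)
  if (any(k <= 0)) abort("Harmonic stiffness must be positive.")
  new_potential("harmonic", dim, params = c(k, center),
                label = sprintf("harmonic k=%s", paste(k, collapse = ",")))
}

#' @rdname potential_harmonic
#' @param barrier Barrier height between the two wells (kcal/mol).
#' @param well Half-separation of the wells (wells at `center +- well` on
#'   `axis`), Angstrom.
#' @param axis Which dimension carries the double well (1-based).
#' @param k_other Harmonic stiffness on the remaining dimensions.
#' @export
potential_double_well <- function(barrier = 3, well = 8, axis = 1, dim = 1,
                                  k_other = 1, center = 0) {
  if (barrier <= 0 || well <= 0) abort("`barrier` and `well` must be positive.")
  if (axis < 1 || axis > dim) abort("`axis` must be within `dim`.")
  k <- rep_len(k_other, dim); center <- rep_len(center, dim)
  new_potential("double_well", dim,
                params = c(axis - 1, barrier, well, k, center),
                label = sprintf("double well %g kcal/mol at +-%g A", barrier, well))
}

#' @rdname potential_harmonic
#' @param edges_x,edges_y Ascending grid node positions (A); `edges_y`
#'   `NULL` for 1D.
#' @param values Energy at the nodes: vector (1D) or
#'   `length(edges_x) x length(edges_y)` matrix (2D).
#' @export
potential_tabulated <- function(edges_x, values, edges_y = NULL) {
  edges_x <- as.numeric(edges_x)
  if (is.unsorted(edges_x, strictly = TRUE)) abort("`edges_x` must be strictly ascending.")
  if (is.null(edges_y)) {
    values <- matrix(as.numeric(values), ncol = 1)
    if (nrow(values) != length(edges_x)) abort("`values` length must match `edges_x`.")
    dim_ <- 1L
    edges_y <- numeric(0)
  } else {
    edges_y <- as.numeric(edges_y)
    if (is.unsorted(edges_y, strictly = TRUE)) abort("`edges_y` must be strictly ascending.")
    values <- as.matrix(values)
    if (!all(dim(values) == c(length(edges_x), length(edges_y)))) {
      abort("`values` must be length(edges_x) x length(edges_y).")
    }
    dim_ <- 2L
  }
  if (any(!is.finite(values))) abort("Tabulated potential must be finite on its domain.")
  p <- new_potential("tabulated", dim_, params = numeric(0), label = "tabulated grid")
  p$grid <- list(x = edges_x, y = edges_y, v = values)
  p
}

new_potential <- function(form, dim, params, label) {
  structure(list(form = form, dim = as.integer(dim), params = as.numeric(params),
                 grid = list(x = numeric(0), y = numeric(0), v = matrix(0, 1, 1)),
                 label = label),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("<potential_spec> %s (%dD)\n", x$label, x$dim))
  invisible(x)
}

form_code <- function(pot) {
  match(pot$form, c("harmonic", "double_well", "tabulated")) - 1L
}

#' Evaluate a potential
#'
#' @param pot A `potential_spec`.
#' @param x Point (length `dim`) or matrix of points (rows).
#' @return Energy (kcal/mol), vectorized over rows.
#' @export
potential_energy <- function(pot, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = pot$dim)
  if (ncol(x) != pot$dim) abort("Point dimensionality does not match the potential.")
  vapply(seq_len(nrow(x)), function(i) {
    potential_energy_cpp(form_code(pot), pot$dim, pot$params,
                         pot$grid$x, pot$grid$y, pot$grid$v, x[i, ])
  }, numeric(1))
}
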