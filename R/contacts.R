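#' Residue-residue contact matrix
#'
#' Two residues are in contact in a frame iff the minimum inter-particle
#' (bead-bead) distance between them is below `cutoff` (6.5 A default),
#' under the minimum-image convention.  The matrix entry is the fraction
#' of analyzed frames in contact.
#'
#' @param traj A [trajectory()] (a single [frame()] plus `top=` also
#'   works).
#' @param sel_a,sel_b Disjoint selections (rows = `sel_a` residues,
#'   cols = `sel_b`).
#' @param cutoff Contact distance, A (> 0).
#' @param frames Optional integer vector of frames to analyze.
#' @param top Topology when `traj` is a single frame.
#' @param pbc Apply the minimum-image convention (default `TRUE`).
#' @return Object of class `contact_matrix`: `matrix` (fractions in
#'   `[0, 1]`), residue tables `rows`/`cols` (with polarity), `cutoff`,
#'   `n_frames`.
#' @export
contact_matrix <- function(traj, sel_a = "pore", sel_b = "cargo", cutoff = 6.5,
                           frames = NULL, top = NULL, pbc = TRUE) {
  if (inherits(traj, "frame")) {
    if (is.null(top)) abort("Pass `top=` when analyzing a single frame.")
    traj <- trajectory(top, list(traj))
  }
  if (cutoff <= 0) abort("`cutoff` must be positive.")
  ra <- select_particles(traj$topology, sel_a)
  rb <- select_particles(traj$topology, sel_b)
  if (length(intersect(ra, rb))) abort("Selections overlap; contact groups must be disjoint.")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  p <- traj$topology$particles
  res_tab <- function(rows) {
    d <- p[rows, c("chain", "resid", "resname", "polarity")]
    key <- paste(d$chain, d$resid, sep = ":")
    first <- !duplicated(key)
    list(idx0 = match(key, key[first]) - 1L,
         residues = dplyr::mutate(d[first, ], label = paste(.data$chain, .data$resid, .data$resname, sep = ":")))
  }
  ta <- res_tab(ra); tb <- res_tab(rb)
  na <- nrow(ta$residues); nb <- nrow(tb$residues)
  acc <- matrix(0, na, nb)
  for (fi in frames) {
    f <- traj$frames[[fi]]
    d <- min_res_dist_cpp(f$xyz[ra, , drop = FALSE], ta$idx0, na,
                          f$xyz[rb, , drop = FALSE], tb$idx0, nb,
                          if (pbc) f$box else numeric(0))
    acc <- acc + (d < cutoff)
  }
  m <- acc / length(frames)
  dimnames(m) <- list(ta$residues$label, tb$residues$label)
  structure(list(matrix = m, rows = ta$residues, cols = tb$residues,
                 cutoff = cutoff, n_frames = length(frames)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d x %d residues, cutoff %.1f A over %d frame(s); %d pairs ever in contact\n",
              nrow(x$matrix), ncol(x$matrix), x$cutoff, x$n_frames,
              sum(x$matrix > 0)))
  invisible(x)
}

#' @export
tidy.contact_matrix <- function(x, ...) {
  g <- tidyr::expand_grid(row = x$rows$label, col = x$cols$label)
  g <- g[order(match(g$row, x$rows$label)), ]
  tibble(
    row = rep(x$rows$label, times = ncol(x$matrix)),
    col = rep(x$cols$label, each = nrow(x$matrix)),
    fraction = as.numeric(x$matrix)
  )
}

#' Transpose a contact matrix
#' @param x A `contact_matrix`.
#' @export
t.contact_matrix <- function(x) {
  structure(list(matrix = t(x$matrix), rows = x$cols, cols = x$rows,
                 cutoff = x$cutoff, n_frames = x$n_frames),
            class = "contact_matrix")
}

#' Per-residue contact-number profiles
#'
#' For each residue on either side, the number of partner residues whose
#' contact frame-fraction exceeds `threshold` (default 0: any contact).
#'
#' @param cm A [contact_matrix()].
#' @param threshold Frame-fraction threshold.
#' @return List of tibbles `rows` and `cols` with columns `label`,
#'   `resid`, `resname`, `n_contacts`.
#' @export
contact_number_profiles <- function(cm, threshold = 0) {
  stopifnot(inherits(cm, "contact_matrix"))
  inc <- cm$matrix > threshold
  list(
    rows = dplyr::mutate(cm$rows[, c("label", "resid", "resname")],
                         n_contacts = as.integer(rowSums(inc))),
    cols = dplyr::mutate(cm$cols[, c("label", "resid", "resname")],
                         n_contacts = as.integer(colSums(inc)))
  )
}

#' Polarity-classified contact fractions
#'
#' Classifies every contacting residue pair (frame-fraction above
#' `threshold`) by the polarity of its two residues — hydrophilic =
#' positive, negative or polar uncharged — and reports the percentage of
#' hydrophilic-hydrophilic, hydrophobic-hydrophobic and mixed pairs
#' (summing to 100).
#'
#' @param cm A [contact_matrix()] (residue polarity classes are carried
#'   from the topology).
#' @param threshold Frame-fraction threshold.
#' @return Tibble with columns `category`, `n_pairs`, `percent`.
#' @export
polarity_contact_fractions <- function(cm, threshold = 0) {
  stopifnot(inherits(cm, "contact_matrix"))
  inc <- which(cm$matrix > threshold, arr.ind = TRUE)
  phil_a <- cm$rows$polarity %in% .hydrophilic_classes
  phil_b <- cm$cols$polarity %in% .hydrophilic_classes
  cat_of <- function(i, j) {
    a <- phil_a[i]; b <- phil_b[j]
    dplyr::case_when(a & b ~ "hydrophilic_hydrophilic",
                     !a & !b ~ "hydrophobic_hydrophobic",
                     TRUE ~ "mixed")
  }
  cats <- factor(if (nrow(inc)) cat_of(inc[, 1], inc[, 2]) else character(),
                 levels = c("hydrophilic_hydrophilic", "hydrophobic_hydrophobic", "mixed"))
  n <- table(cats)
  tot <- sum(n)
  tibble(category = names(n), n_pairs = as.integer(n),
         percent = if (tot > 0) 100 * as.integer(n) / tot else rep(NA_real_, 3))
}
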