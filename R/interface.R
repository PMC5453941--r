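#' All-atom interface counts and pairwise energy split
#'
#' Counts hydrogen bonds, salt bridges and hydrophobic contacts across a
#' two-group interface of an all-atom structure, and (when a parameter
#' table is supplied) evaluates a fixed-charge Coulomb / 12-6
#' Lennard-Jones pairwise energy split.  This is a diagnostic with
#' standard-literature geometric criteria, not a force-field
#' reimplementation.
#'
#' Criteria (all configurable): hydrogen bond = donor-acceptor heavy-atom
#' distance < 3.5 A with donor-H...acceptor angle > 120 degrees (when the
#' structure has no hydrogens, a distance-only fallback of < 3.0 A is
#' used with a warning); salt bridge = any Arg/Lys/His side-chain N
#' within 4.0 A of an Asp/Glu side-chain O, counted once per residue
#' pair; hydrophobic contact = side-chain carbon pair of two
#' hydrophobic-class residues within 5.0 A, counted once per residue
#' pair; energies sum over cross-group atom pairs within 12 A with
#' epsilon_r = 1 (Coulomb constant 332.06 kcal mol^-1 A e^-2).
#'
#' @param top A [topology()] with element information.
#' @param fr The matching [frame()].
#' @param sel_a,sel_b Disjoint selections defining the interface.
#' @param params Optional parameter table (data frame with columns
#'   `name`, `charge`, `sigma`, `epsilon`); atoms missing from the table
#'   get charge 0 and no LJ well.  `NULL` skips the energy split (NA).
#' @param hbond_dist,hbond_angle,hbond_fallback_dist,salt_dist,phob_dist,energy_cutoff
#'   Criterion parameters (A / degrees).
#' @return One-row tibble: `h_bonds`, `salt_bridges`,
#'   `hydrophobic_contacts`, `elec_energy`, `vdw_energy`,
#'   `elec_fraction` (share of the total interaction energy magnitude).
#' @export
interface_counts <- function(top, fr, sel_a, sel_b, params = NULL,
                             hbond_dist = 3.5, hbond_angle = 120,
                             hbond_fallback_dist = 3.0, salt_dist = 4.0,
                             phob_dist = 5.0, energy_cutoff = 12) {
  ra <- select_particles(top, sel_a)
  rb <- select_particles(top, sel_b)
  if (length(intersect(ra, rb))) abort("Interface selections must be disjoint.")
  p <- top$particles
  xyz <- fr$xyz

  dist_ab <- function(ia, ib) {
    # ia x ib cross-distance matrix
    a <- xyz[ia, , drop = FALSE]; b <- xyz[ib, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  }

  has_h <- any(p$element[c(ra, rb)] == "H")
  hb <- count_hbonds(p, xyz, ra, rb, has_h, hbond_dist, hbond_angle, hbond_fallback_dist)

  # salt bridges: basic side-chain N vs acidic side-chain O, per residue pair
  basic_n <- function(rows) rows[p$resname[rows] %in% c("ARG", "LYS", "HIS") &
                                 p$element[rows] == "N" & p$name[rows] != "N"]
  acidic_o <- function(rows) rows[p$resname[rows] %in% c("ASP", "GLU") &
                                  grepl("^O[DE]", p$name[rows])]
  sb <- count_respair(p, xyz, basic_n(ra), acidic_o(rb), salt_dist) +
        count_respair(p, xyz, basic_n(rb), acidic_o(ra), salt_dist)

  # hydrophobic contacts: side-chain carbons of hydrophobic residues
  phob_c <- function(rows) rows[p$polarity[rows] == "hydrophobic" &
                                p$element[rows] == "C" &
                                !p$name[rows] %in% c("C", "CA")]
  ph <- count_respair(p, xyz, phob_c(ra), phob_c(rb), phob_dist)

  elec <- vdw <- NA_real_
  if (!is.null(params)) {
    q <- setNames(params$charge, params$name)
    sg <- setNames(params$sigma, params$name)
    ep <- setNames(params$epsilon, params$name)
    getp <- function(v, nm, default) ifelse(is.na(v[nm]), default, v[nm])
    d <- dist_ab(ra, rb)
    within <- which(d < energy_cutoff & d > 0, arr.ind = TRUE)
    if (nrow(within)) {
      qa <- getp(q, p$name[ra[within[, 1]]], 0)
      qb <- getp(q, p$name[rb[within[, 2]]], 0)
      r <- d[within]
      elec <- sum(332.06 * qa * qb / r)
      sa <- getp(sg, p$name[ra[within[, 1]]], 0)
      sb2 <- getp(sg, p$name[rb[within[, 2]]], 0)
      ea <- getp(ep, p$name[ra[within[, 1]]], 0)
      eb <- getp(ep, p$name[rb[within[, 2]]], 0)
      sij <- (sa + sb2) / 2
      eij <- sqrt(ea * eb)
      sr6 <- ifelse(sij > 0, (sij / r)^6, 0)
      vdw <- sum(4 * eij * (sr6^2 - sr6))
    } else {
      elec <- vdw <- 0
    }
  }
  tibble(
    h_bonds = hb, salt_bridges = sb, hydrophobic_contacts = ph,
    elec_energy = unname(elec), vdw_energy = unname(vdw),
    elec_fraction = if (is.na(elec)) NA_real_ else
      abs(elec) / (abs(elec) + abs(vdw))
  )
}

# number of residue pairs with any qualifying atom pair below `cutoff`
count_respair <- function(p, xyz, ia, ib, cutoff) {
  if (!length(ia) || !length(ib)) return(0L)
  a <- xyz[ia, , drop = FALSE]; b <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(0L)
  keys <- paste(p$chain[ia[hit[, 1]]], p$resid[ia[hit[, 1]]],
                p$chain[ib[hit[, 2]]], p$resid[ib[hit[, 2]]])
  length(unique(keys))
}

count_hbonds <- function(p, xyz, ra, rb, has_h, dmax, amin, fallback) {
  polar <- function(rows) rows[p$element[rows] %in% c("N", "O")]
  if (!has_h) {
    warn("No hydrogens in structure: counting hydrogen bonds by the distance-only fallback.")
    da <- polar(ra); ab <- polar(rb)
    return(count_respair_atoms(xyz, da, ab, fallback))
  }
  n_hb <- 0L
  count_dir <- function(don_rows, acc_rows) {
    donors <- polar(don_rows)
    hyd <- don_rows[p$element[don_rows] == "H"]
    accs <- polar(acc_rows)
    cnt <- 0L
    for (dn in donors) {
      # hydrogens covalently attached to this donor (same residue, < 1.3 A)
      hs <- hyd[p$resid[hyd] == p$resid[dn] & p$chain[hyd] == p$chain[dn]]
      if (length(hs)) {
        dh <- sqrt(colSums((t(xyz[hs, , drop = FALSE]) - xyz[dn, ])^2))
        hs <- hs[dh < 1.3]
      }
      if (!length(hs)) next
      for (ac in accs) {
        r_da <- sqrt(sum((xyz[dn, ] - xyz[ac, ])^2))
        if (r_da >= dmax || r_da < 0.5) next
        for (h in hs) {
          v1 <- xyz[dn, ] - xyz[h, ]
          v2 <- xyz[ac, ] - xyz[h, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                      (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
          if (ang > amin) {
            cnt <- cnt + 1L
            break
          }
        }
      }
    }
    cnt
  }
  n_hb + count_dir(ra, rb) + count_dir(rb, ra)
}

count_respair_atoms <- function(xyz, ia, ib, cutoff) {
  if (!length(ia) || !length(ib)) return(0L)
  a <- xyz[ia, , drop = FALSE]; b <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sum(d2 < cutoff^2)
}
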