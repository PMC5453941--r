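#' Define helix segments for back-mapping
#'
#' @param resid_range Inclusive 1-based residue range `c(lo, hi)` (length
#'   >= 4: axis estimation needs at least 4 points).
#' @param chain Chain id in the coarse-grained topology.
#' @param fragment Fragment id in the [fragment_library()].
#' @param name Optional segment label.
#' @return Object of class `helix_segment`.
#' @export
helix_segment <- function(resid_range, chain = "A", fragment = NULL,
                          name = NULL) {
  if (length(resid_range) != 2 || diff(resid_range) < 3) {
    abort("`resid_range` must span at least 4 residues.")
  }
  structure(list(resid_range = as.integer(resid_range), chain = chain,
                 fragment = fragment,
                 name = name %||% sprintf("%s:%d-%d", chain, resid_range[1], resid_range[2])),
            class = "helix_segment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure position and orientation of coarse-grained helix segments
#'
#' For each segment, the centroid is the mean backbone-bead position and
#' the axis is the dominant principal component of the backbone beads,
#' with its sign fixed to point N-terminus to C-terminus.
#'
#' @param top Coarse-grained [topology()].
#' @param fr The matching [frame()].
#' @param segments List of [helix_segment()]s.
#' @param backbone_names Bead names treated as backbone (default BB/CA).
#' @return Tibble with columns `segment`, `fragment`, `n_beads`,
#'   `centroid` and `axis` (list columns of length-3 vectors).
#' @export
extract_helix_frames <- function(top, fr, segments,
                                 backbone_names = c("BB", "CA")) {
  purrr::map_dfr(segments, function(sg) {
    rows <- segment_rows(top, sg, backbone_names)
    if (length(rows) < 4) {
      abort(sprintf("Segment %s has %d backbone beads; need >= 4.",
                    sg$name, length(rows)))
    }
    xyz <- fr$xyz[rows, , drop = FALSE]
    ctr <- colMeans(xyz)
    pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
    ax <- pc$rotation[, 1]
    nc <- xyz[nrow(xyz), ] - xyz[1, ]          # N -> C direction
    if (sum(ax * nc) < 0) ax <- -ax
    tibble(segment = sg$name, fragment = sg$fragment %||% NA_character_,
           n_beads = length(rows), centroid = list(unname(ctr)),
           axis = list(unname(ax / sqrt(sum(ax^2)))))
  })
}

segment_rows <- function(top, sg, backbone_names) {
  p <- top$particles
  which(p$chain == sg$chain & p$resid >= sg$resid_range[1] &
        p$resid <= sg$resid_range[2] & p$name %in% backbone_names)
}

#' Build a fragment library
#'
#' A named list of all-atom reference fragments (each a
#' `list(topology, frame)` as returned by [read_structure()] or
#' [ideal_helix()]).  Alternatively pass a directory containing PDB files
#' and a `manifest.json` mapping fragment id to file name.
#'
#' @param fragments Named list of structures, or a directory path.
#' @return Object of class `fragment_library`.
#' @export
fragment_library <- function(fragments) {
  if (is.character(fragments) && length(fragments) == 1) {
    man_path <- file.path(fragments, "manifest.json")
    if (!file.exists(man_path)) abort(sprintf("No manifest.json in %s", fragments))
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    fragments <- lapply(man, function(f) read_structure(file.path(dirname(man_path), f)))
    names(fragments) <- names(man)
  }
  if (is.null(names(fragments)) || any(names(fragments) == "")) {
    abort("Fragments must be named.")
  }
  structure(fragments, class = "fragment_library")
}

#' Rigid-fit an all-atom fragment onto coarse-grained target beads
#'
#' One anchor point per residue of the fragment (its CA atom, or the mean
#' of its backbone atoms when no CA exists) is matched, in residue order,
#' to the target bead positions, and the optimal proper rotation +
#' translation ([kabsch_fit()]; reflections excluded) is applied to the
#' whole fragment.
#'
#' @param fragment `list(topology, frame)` all-atom fragment.
#' @param target_xyz M x 3 matrix of CG backbone bead positions (M must
#'   equal the fragment residue count, >= 3).
#' @return List with `rotation`, `translation`, `rmsd` (anchor RMSD, A)
#'   and `frame` (the fitted all-atom coordinates as a [frame()]).
#' @export
fit_fragment <- function(fragment, target_xyz) {
  target_xyz <- as.matrix(target_xyz)
  anchors <- fragment_anchors(fragment)
  if (nrow(target_xyz) < 3) abort("Underdetermined fit: need >= 3 correspondence points.")
  if (nrow(anchors) != nrow(target_xyz)) {
    abort(sprintf("Correspondence mismatch: fragment has %d residues, target %d beads.",
                  nrow(anchors), nrow(target_xyz)))
  }
  fit <- kabsch_fit(anchors, target_xyz)
  fitted <- apply_rigid(fragment$frame$xyz, fit$rotation, fit$translation)
  list(rotation = fit$rotation, translation = fit$translation, rmsd = fit$rmsd,
       frame = frame(fitted, box = fragment$frame$box, time = 0))
}

fragment_anchors <- function(fragment) {
  p <- fragment$topology$particles
  xyz <- fragment$frame$xyz
  key <- paste(p$chain, p$resid)
  uk <- unique(key)
  t(vapply(uk, function(k) {
    rows <- which(key == k)
    ca <- rows[p$name[rows] == "CA"]
    if (length(ca)) xyz[ca[1], ] else colMeans(xyz[rows, , drop = FALSE])
  }, numeric(3)))
}

#' Back-map a coarse-grained assembly to all-atom coordinates
#'
#' Each listed helix segment is reconstructed by rigid-fitting its
#' library fragment onto the segment's CG backbone beads
#' ([fit_fragment()]).  Residues between consecutive segments of the same
#' chain are emitted as straight-line CA placeholders flagged
#' `placeholder = TRUE` (loop relaxation/minimization is out of scope and
#' must be done downstream).  A steric clash report (heavy-atom pairs
#' closer than `clash_dist` between different fitted segments;
#' placeholder loop beads are excluded) is attached.
#' Only the listed segments are back-mapped, so omitting a domain is
#' expressed by omitting its segments.
#'
#' @param top Coarse-grained [topology()].
#' @param fr The matching [frame()].
#' @param segments List of [helix_segment()]s, each naming a fragment.
#' @param library A [fragment_library()]; fragment residue names must
#'   match the CG segment residue names.
#' @param backbone_names CG backbone bead names.
#' @param clash_dist Clash threshold, A.
#' @return List with `topology` and `frame` of the all-atom model (the
#'   particle table carries a `placeholder` column; write to PDB with
#'   [write_structure()]), `report` (tibble `segment`, `fragment`,
#'   `rmsd`) and `clashes` (tibble `segment_a`, `segment_b`, `distance`).
#' @export
backmap_assembly <- function(top, fr, segments, library,
                             backbone_names = c("BB", "CA"), clash_dist = 2) {
  stopifnot(inherits(library, "fragment_library"))
  placed <- list()
  report <- list()
  for (sg in segments) {
    if (is.null(sg$fragment) || !sg$fragment %in% names(library)) {
      abort(sprintf("No library fragment for segment %s (fragment id '%s').",
                    sg$name, sg$fragment %||% "<none>"))
    }
    fragment <- library[[sg$fragment]]
    rows <- segment_rows(top, sg, backbone_names)
    if (length(rows) < 3) abort(sprintf("Segment %s has too few CG beads.", sg$name))
    cg_res <- top$particles$resname[rows]
    fg <- fragment$topology$particles
    fg_res <- fg$resname[!duplicated(paste(fg$chain, fg$resid))]
    if (length(fg_res) == length(cg_res) && !all(toupper(fg_res) == toupper(cg_res))) {
      abort(sprintf("Fragment '%s' residue names do not match segment %s.",
                    sg$fragment, sg$name))
    }
    fit <- fit_fragment(fragment, fr$xyz[rows, , drop = FALSE])
    pp <- fragment$topology$particles
    placed[[sg$name]] <- list(
      particles = dplyr::mutate(pp, chain = sg$chain,
                                resid = pp$resid - min(pp$resid) + sg$resid_range[1],
                                group = "pore", placeholder = FALSE,
                                segment = sg$name),
      xyz = fit$frame$xyz
    )
    report[[sg$name]] <- tibble(segment = sg$name, fragment = sg$fragment,
                                rmsd = fit$rmsd)
  }
  # straight-line CA placeholders across inter-segment loops (same chain)
  ord <- order(vapply(segments, function(s) s$resid_range[1], numeric(1)))
  segments <- segments[ord]
  placed <- placed[vapply(segments, `[[`, character(1), "name")]
  loops <- list()
  for (k in seq_len(length(segments) - 1)) {
    a <- segments[[k]]; b <- segments[[k + 1]]
    if (a$chain != b$chain) next
    gap <- seq(a$resid_range[2] + 1L, length.out = max(0, b$resid_range[1] - a$resid_range[2] - 1L))
    if (!length(gap)) next
    pa <- placed[[a$name]]; pb <- placed[[b$name]]
    from <- pa$xyz[nrow(pa$xyz), ]
    to <- pb$xyz[1, ]
    tfrac <- seq_len(length(gap)) / (length(gap) + 1)
    xyz <- t(vapply(tfrac, function(s) from + s * (to - from), numeric(3)))
    cg_sub <- top$particles[top$particles$chain == a$chain &
                            top$particles$resid %in% gap, ]
    rn <- cg_sub$resname[match(gap, cg_sub$resid)]
    rn[is.na(rn)] <- "GLY"
    loops[[k]] <- list(
      particles = tibble(index = 0L, name = "CA", resid = gap,
                         resname = rn,
                         chain = a$chain, group = "pore",
                         polarity = "hydrophobic", element = "C",
                         placeholder = TRUE, segment = sprintf("loop_%d", k)),
      xyz = xyz
    )
  }
  all_parts <- c(placed, loops[!vapply(loops, is.null, logical(1))])
  ptab <- dplyr::bind_rows(lapply(all_parts, `[[`, "particles"))
  ptab$index <- seq_len(nrow(ptab)) - 1L
  ptab$polarity <- classify_polarity(ptab$resname, quiet = TRUE)
  xyz <- do.call(rbind, lapply(all_parts, `[[`, "xyz"))
  clashes <- clash_report(ptab, xyz, clash_dist)
  list(topology = topology(ptab), frame = frame(xyz, box = fr$box),
       report = dplyr::bind_rows(report), clashes = clashes)
}

clash_report <- function(ptab, xyz, clash_dist) {
  # placeholder loop beads are unrefined by construction and excluded
  heavy <- which(ptab$element != "H" & !ptab$placeholder)
  seg <- ptab$segment[heavy]
  h <- xyz[heavy, , drop = FALSE]
  d2 <- outer(rowSums(h^2), rowSums(h^2), `+`) - 2 * tcrossprod(h)
  hit <- which(d2 < clash_dist^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2] & seg[hit[, 1]] != seg[hit[, 2]], , drop = FALSE]
  tibble(segment_a = seg[hit[, 1]], segment_b = seg[hit[, 2]],
         distance = sqrt(pmax(0, d2[hit])))
}
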