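#' Read a molecular structure file
#'
#' Reads PDB (via bio3d) or GROMACS GRO files into the package's
#' topology/frame pair.  GRO coordinates (nm) are converted to Angstrom on
#' read.  The group tag of each particle is inferred from its residue
#' name: common water and ion names map to "water"/"ion", common lipid
#' names to "lipid", everything else to `default_group`.
#'
#' @param path File path.
#' @param format "auto" (from extension), "pdb" or "gro".
#' @param default_group Group tag for residues that are not water, ion or
#'   lipid (default "pore").
#' @param quiet Suppress unknown-residue polarity warnings.
#' @return List with elements `topology` and `frame`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           default_group = "pore", quiet = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") format <- guess_format(path, c(pdb = "pdb", gro = "gro"))
  switch(format,
    pdb = read_pdb_structure(path, default_group, quiet),
    gro = read_gro_structure(path, default_group, quiet)
  )
}

guess_format <- function(path, map) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% names(map)) {
    abort(sprintf("Cannot guess format from extension '.%s'; pass `format`.", ext))
  }
  map[[ext]]
}

.water_names <- c("W", "HOH", "SOL", "TIP3", "TIP", "WAT")
.ion_names <- c("NA", "CL", "CA", "NA+", "CL-", "CA2+", "ION", "K", "MG", "SOD", "CLA", "CAL")
.lipid_names <- c("DSPC", "DPPC", "POPC", "DOPC", "POPE", "DOPE", "LIP")

infer_group <- function(resname, default_group) {
  up <- toupper(resname)
  dplyr::case_when(
    up %in% .water_names ~ "water",
    up %in% .ion_names ~ "ion",
    up %in% .lipid_names ~ "lipid",
    TRUE ~ default_group
  )
}

read_pdb_structure <- function(path, default_group, quiet) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(sprintf("Malformed PDB file %s: %s", path, conditionMessage(e)))
  )
  a <- pdb$atom
  box <- parse_cryst1(path)
  grp <- infer_group(a$resid, default_group)
  p <- particles(
    name = a$elety, resid = a$resno, resname = a$resid,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    group = grp, quiet = quiet
  )
  xyz <- cbind(a$x, a$y, a$z)
  if (any(!is.finite(xyz))) abort(sprintf("Non-finite coordinates in %s", path))
  list(topology = topology(p), frame = frame(xyz, box = box))
}

parse_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(c(100, 100, 100))
  v <- suppressWarnings(as.numeric(c(
    substr(ln[1], 7, 15), substr(ln[1], 16, 24), substr(ln[1], 25, 33)
  )))
  if (any(is.na(v)) || any(v <= 0)) c(100, 100, 100) else v
}

read_gro_structure <- function(path, default_group, quiet) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort(sprintf("Malformed GRO file %s: fewer than 3 lines", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort(sprintf("Malformed GRO file %s: line 2 is not an atom count", path))
  if (length(lines) < 2L + n + 1L) {
    abort(sprintf("Malformed GRO file %s: expected %d atom lines, found %d",
                  path, n, length(lines) - 3L))
  }
  at <- lines[3:(2 + n)]
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    abort(sprintf("Malformed GRO file %s: cannot parse atom line %d", path, 2L + bad[1]))
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))[1:3]
  if (any(is.na(box))) abort(sprintf("Malformed GRO file %s: bad box line", path))
  p <- particles(name = name, resid = resid, resname = resname,
                 group = infer_group(resname, default_group), quiet = quiet)
  # GRO is in nm; internal unit is Angstrom
  list(topology = topology(p), frame = frame(cbind(x, y, z) * 10, box = box * 10))
}

#' Write a molecular structure file
#'
#' Writes PDB (bio3d, with a CRYST1 record for the box) or GRO
#' (Angstrom converted to nm).  Round-trips with [read_structure()] to
#' within format precision (10^-3 Angstrom).  PDB residue names are
#' truncated to the standard 3-character field; use GRO for systems with
#' 4-character coarse-grained residue names (e.g. DSPC).
#'
#' @param top A [topology()].
#' @param fr A [frame()].
#' @param path Output path.
#' @param format "auto", "pdb" or "gro".
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, fr, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path, c(pdb = "pdb", gro = "gro"))
  if (any(!is.finite(fr$xyz))) abort("Refusing to write non-finite coordinates.")
  if (nrow(fr$xyz) != n_particles(top)) abort("Topology/frame size mismatch.")
  ok <- tryCatch({
    if (format == "pdb") write_pdb_structure(top, fr, path) else write_gro_structure(top, fr, path)
    TRUE
  }, error = function(e) abort(sprintf("Cannot write %s: %s", path, conditionMessage(e))))
  invisible(path)
}

write_pdb_structure <- function(top, fr, path) {
  p <- top$particles
  # the PDB resName field is 3 characters; 4-character CG residue names
  # (e.g. DSPC) are truncated here — use GRO for such systems
  bio3d::write.pdb(
    file = path, xyz = as.numeric(t(fr$xyz)), type = "ATOM",
    resno = p$resid, resid = substr(p$resname, 1, 3), eleno = seq_len(nrow(p)),
    elety = p$name, chain = substr(p$chain, 1, 1)
  )
  lines <- readLines(path, warn = FALSE)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   fr$box[1], fr$box[2], fr$box[3], 90, 90, 90)
  writeLines(c(cryst, lines), path)
}

write_gro_structure <- function(top, fr, path) {
  p <- top$particles
  nm <- fr$xyz / 10
  at <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                p$resid %% 100000L, substr(p$resname, 1, 5), substr(p$name, 1, 5),
                seq_len(nrow(p)) %% 100000L, nm[, 1], nm[, 2], nm[, 3])
  writeLines(c("written by porescape", sprintf("%5d", nrow(p)), at,
               sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10)),
             path)
}
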