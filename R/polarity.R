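#' Default residue polarity classification table
#'
#' Maps three-letter residue names to one of four surface/contact classes:
#' `positive`, `negative`, `polar_uncharged`, `hydrophobic`.  This is the
#' table used to decompose solvent-accessible surface into charged /
#' non-charged hydrophilic / hydrophobic patches and to classify
#' residue-residue contacts as hydrophilic or hydrophobic.  Histidine is
#' grouped with the positively charged residues; glycine, cysteine and
#' tryptophan are grouped with the polar uncharged class; the heme group
#' (HEC/HEM) is classified hydrophobic at residue level (no atom-level
#' override for the propionate oxygens is attempted).
#'
#' @return Named character vector mapping residue name to class.
#' @export
#' @examples
#' polarity_table()[["LYS"]]
polarity_table <- function() {
  c(
    ARG = "positive", LYS = "positive", HIS = "positive",
    ASP = "negative", GLU = "negative",
    SER = "polar_uncharged", THR = "polar_uncharged", ASN = "polar_uncharged",
    GLN = "polar_uncharged", TYR = "polar_uncharged", CYS = "polar_uncharged",
    TRP = "polar_uncharged", GLY = "polar_uncharged",
    ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
    ILE = "hydrophobic", PRO = "hydrophobic", PHE = "hydrophobic",
    MET = "hydrophobic",
    HEC = "hydrophobic", HEM = "hydrophobic"
  )
}

#' Classes considered hydrophilic
#' @keywords internal
.hydrophilic_classes <- c("positive", "negative", "polar_uncharged")

#' Classify residue names into polarity classes
#'
#' Unknown residue names (lipids, ions, water beads, modified residues not
#' in the table) are classified `hydrophobic` and reported once in a
#' warning, so that mixed protein/membrane systems pass through without
#' failing.
#'
#' @param resname Character vector of residue names.
#' @param table Named character vector mapping residue name to class;
#'   defaults to [polarity_table()].
#' @param quiet If `TRUE`, suppress the unknown-residue warning.
#' @return Character vector of classes, same length as `resname`.
#' @export
classify_polarity <- function(resname, table = polarity_table(), quiet = FALSE) {
  cls <- unname(table[toupper(resname)])
  unknown <- is.na(cls)
  if (any(unknown)) {
    if (!quiet) {
      warn(paste0(
        "Unknown residue name(s) classified hydrophobic: ",
        paste(sort(unique(resname[unknown])), collapse = ", ")
      ))
    }
    cls[unknown] <- "hydrophobic"
  }
  cls
}
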