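#' Amino-acid hydrophobicity scales
#'
#' The observed hydrophobicity density assigns every residue an intrinsic
#' hydrophobicity \eqn{H^r}. The scale is a free choice of the analysis; any
#' table mapping the twenty standard three-letter codes to finite numbers can
#' be used. The package ships a Kyte-Doolittle scale rescaled linearly to
#' \eqn{[0, 1]} as a documented default.
#'
#' @param path Path to a two-column whitespace-separated text file
#'   (three-letter code, value). Lines starting with `#` are comments.
#' @param name Label attached to the scale (recorded in run manifests).
#' @return Named numeric vector over the 20 standard residues, with a
#'   `scale_name` attribute.
#' @examples
#' sc <- default_scale()
#' sc[["ILE"]]
#' @export
read_hydrophobicity_scale <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("scale file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("aa", "h"),
                           colClasses = c("character", "numeric"))
  aa <- toupper(tab$aa)
  if (anyDuplicated(aa)) stop("duplicate residue codes in scale file")
  bad <- setdiff(aa, STANDARD_AA)
  if (length(bad)) stop("unknown residue codes in scale: ",
                        paste(bad, collapse = ", "))
  missing <- setdiff(STANDARD_AA, aa)
  if (length(missing)) stop("scale does not cover: ",
                            paste(missing, collapse = ", "))
  h <- stats::setNames(tab$h, aa)[STANDARD_AA]
  if (any(!is.finite(h))) stop("non-finite hydrophobicity values in scale")
  attr(h, "scale_name") <- name
  h
}

#' @rdname read_hydrophobicity_scale
#' @export
default_scale <- function() {
  read_hydrophobicity_scale(
    system.file("extdata", "scale_kd_normalized.txt", package = "oildrop"),
    name = "kyte-doolittle-normalized")
}

#' Standard amino acids
#'
#' Three-letter codes of the 20 standard amino acids, the residue alphabet
#' the package operates on.
#' @export
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
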