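#' Effective-atom structure model
#'
#' A `fod_structure` is the package's working representation of one structural
#' unit (protein, domain or fragment): an ordered table of residues, each
#' located at its *effective atom* (the unweighted mean position of its heavy
#' atoms), plus, when available, the heavy-atom table the model was built from
#' (needed for backbone torsions).
#'
#' @param residues data.frame with columns `chain`, `seq_id`, `ins`, `aa`,
#'   `x`, `y`, `z` (effective-atom coordinates, Angstrom).
#' @param atoms Optional data.frame of heavy atoms with columns `chain`,
#'   `seq_id`, `ins`, `aa`, `elety`, `x`, `y`, `z`.
#' @param unit_label Free-text label of the unit.
#' @return Object of class `fod_structure`.
#' @export
fod_structure <- function(residues, atoms = NULL, unit_label = "unit") {
  need <- c("chain", "seq_id", "ins", "aa", "x", "y", "z")
  if (!all(need %in% names(residues)))
    stop("residues must have columns: ", paste(need, collapse = ", "))
  if (nrow(residues) < 1L) stop("empty residue set")
  xyz <- as.matrix(residues[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite effective-atom coordinates")
  key <- paste(residues$chain, residues$seq_id, residues$ins)
  if (anyDuplicated(key))
    stop("duplicate (chain, seq_id, insertion) residue identifiers")
  rownames(residues) <- NULL
  structure(list(residues = residues, atoms = atoms,
                 unit_label = unit_label),
            class = "fod_structure")
}

#' @export
print.fod_structure <- function(x, ...) {
  cat(sprintf("<fod_structure> %s: %d residues (%s...)\n", x$unit_label,
              nrow(x$residues),
              paste(utils::head(x$residues$aa, 5), collapse = "-")))
  invisible(x)
}

#' Number of residues in a structure
#' @param model A `fod_structure`.
#' @export
n_residues <- function(model) nrow(model$residues)

#' Effective atom of one residue
#'
#' The unweighted arithmetic mean of the residue's heavy-atom positions.
#' Hydrogens (and deuteriums) are excluded so that X-ray models, which
#' usually lack them, and NMR models, which carry them, are treated alike.
#'
#' @param atoms data.frame with columns `element` (or `elety`), `x`, `y`, `z`.
#' @return Numeric 3-vector (Angstrom).
#' @examples
#' compute_effective_atom(data.frame(element = c("C", "N"),
#'                                   x = c(0, 2), y = 0, z = 0))
#' @export
compute_effective_atom <- function(atoms) {
  el <- if ("element" %in% names(atoms)) atoms$element else atoms$elety
  keep <- !is_hydrogen(el)
  if (!any(keep)) stop("residue has no heavy atoms")
  p <- colMeans(as.matrix(atoms[keep, c("x", "y", "z")]))
  if (!all(is.finite(p))) stop("non-finite atom coordinates")
  unname(p)
}

# element symbol or PDB atom name -> hydrogen? Only ever applied to atoms of
# standard amino acids, where every name starting with (digit+)H/D is a proton.
is_hydrogen <- function(el) {
  el <- toupper(trimws(as.character(el)))
  grepl("^[0-9]*[HD]", el)
}

#' Load a protein structure as an effective-atom model
#'
#' Reads a PDB or mmCIF file, keeps the standard amino-acid residues of the
#' selected model and chains, resolves alternate locations to the highest
#' occupancy conformer (ties broken by file order), drops heteroatoms and
#' waters, and computes per-residue effective atoms. Residues that have lost
#' all backbone atoms (none of N, CA, C present) are dropped with a warning;
#' residues merely missing side-chain atoms are kept.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param model_index Model to use for multi-model (NMR) entries; default 1.
#' @param chain_filter Optional character vector of chain identifiers.
#' @param nonstandard `"skip"` (default) logs and skips non-standard
#'   residues, `"error"` raises.
#' @param unit_label Label for the unit; defaults to the file base name.
#' @return A [fod_structure].
#' @export
load_structure <- function(path, model_index = 1L, chain_filter = NULL,
                           nonstandard = c("skip", "error"),
                           unit_label = NULL) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse structure file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  n_models <- nrow(as.matrix(pdb$xyz))
  if (model_index < 1L || model_index > n_models)
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  if (n_models > 1L) {
    xyz <- matrix(as.matrix(pdb$xyz)[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  at <- at[at$type == "ATOM", , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  if (!"o" %in% names(at) || all(is.na(at$o))) at$o <- 1
  at$o[is.na(at$o)] <- 1

  if (!is.null(chain_filter)) at <- at[at$chain %in% chain_filter, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty selection: no ATOM records match")

  ns <- unique(at$resid[!(at$resid %in% STANDARD_AA)])
  if (length(ns)) {
    if (nonstandard == "error")
      stop("non-standard residue(s): ", paste(ns, collapse = ", "))
    message("skipping non-standard residue type(s): ",
            paste(ns, collapse = ", "))
    at <- at[at$resid %in% STANDARD_AA, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("empty selection: no standard amino-acid residues")

  # alternate locations: per (chain, resno, insert, atom name) keep the
  # highest-occupancy record, ties -> first in file
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(akey, levels = unique(akey)), -at$o,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  at <- at[!is_hydrogen(ifelse(is.na(at$elesy) | at$elesy == "",
                               at$elety, at$elesy)), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty selection: no heavy atoms")

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  rkey <- factor(rkey, levels = unique(rkey))   # file order
  split_idx <- split(seq_len(nrow(at)), rkey)

  res_list <- lapply(split_idx, function(ii) {
    a <- at[ii, , drop = FALSE]
    if (!any(a$elety %in% c("N", "CA", "C"))) return(NULL)
    p <- compute_effective_atom(data.frame(element = a$elesy, x = a$x,
                                           y = a$y, z = a$z))
    data.frame(chain = a$chain[1], seq_id = a$resno[1], ins = a$insert[1],
               aa = a$resid[1], x = p[1], y = p[2], z = p[3],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res_list, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " residue(s) with no backbone atoms dropped")
  residues <- do.call(rbind, res_list[!vapply(res_list, is.null, logical(1))])
  if (is.null(residues) || nrow(residues) == 0L)
    stop("empty selection: no residues with backbone atoms")

  atoms <- data.frame(chain = at$chain, seq_id = at$resno, ins = at$insert,
                      aa = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  atoms <- atoms[paste(atoms$chain, atoms$seq_id, atoms$ins) %in%
                   paste(residues$chain, residues$seq_id, residues$ins), ,
                 drop = FALSE]

  if (is.null(unit_label))
    unit_label <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "", basename(path),
                      ignore.case = TRUE)
  fod_structure(residues, atoms = atoms, unit_label = unit_label)
}
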