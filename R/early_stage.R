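#' Early-stage (partially unfolded) intermediate of a structure
#'
#' Runs the full early-stage pipeline on a single-chain structure: measures
#' backbone torsions, projects each complete (phi, psi) pair onto the
#' elliptical conformational path (shortest-distance criterion, periodic),
#' assigns structural codes A-G, and rebuilds an ideal-geometry backbone from
#' the projected dihedrals. The rebuilt model can be scored by the same
#' hydrophobicity-profile machinery as the native structure.
#'
#' Terminal residues lack one dihedral of the pair; their surviving angle is
#' kept as measured and their code is undefined. Chain breaks are not
#' supported here: the intermediate is a single continuous backbone.
#'
#' @param model A [fod_structure] with backbone atoms (single chain, no
#'   breaks).
#' @param path An [ellipse_path()].
#' @param geometry A [peptide_geometry()].
#' @return List with `assignment` (data.frame: `seq_id`, `aa`, `phi`, `psi`,
#'   `phi_e`, `psi_e`, `t`, `code`) and `es_model` (a [fod_structure] of the
#'   rebuilt backbone, label suffixed `-es`).
#' @export
make_early_stage <- function(model, path = default_ellipse_path(),
                             geometry = peptide_geometry()) {
  if (length(unique(model$residues$chain)) != 1L)
    stop("early-stage rebuilding expects a single chain")
  tor <- compute_torsions(model)
  n <- nrow(tor)
  if (n < 3L) stop("early-stage model needs at least 3 residues")
  if (any(is.na(tor$phi[-1])) || any(is.na(tor$psi[-n])))
    stop("undefined internal torsions (missing atoms or chain break); ",
         "the early-stage backbone must be continuous")

  proj <- project_to_ellipse(tor$phi, tor$psi, path)
  phi_e <- ifelse(is.na(proj$phi_e), tor$phi, proj$phi_e)
  psi_e <- ifelse(is.na(proj$psi_e), tor$psi, proj$psi_e)
  code <- assign_code(proj$t, path)

  es <- build_backbone(phi_e, psi_e, aa = tor$aa, geometry = geometry,
                       chain = model$residues$chain[1],
                       unit_label = paste0(model$unit_label, "-es"))
  es$residues$seq_id <- model$residues$seq_id
  es$atoms$seq_id <- model$residues$seq_id[es$atoms$seq_id]

  list(assignment = data.frame(seq_id = tor$seq_id, aa = tor$aa,
                               phi = tor$phi, psi = tor$psi,
                               phi_e = phi_e, psi_e = psi_e, t = proj$t,
                               code = code, stringsAsFactors = FALSE),
       es_model = es)
}
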