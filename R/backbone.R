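#' Ideal peptide geometry
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used when building
#' backbones from dihedrals. Values are standard ideal-geometry constants;
#' the peptide bond is kept planar trans (omega 180 degrees).
#'
#' @param n_ca,ca_c,c_n,c_o Bond lengths.
#' @param n_ca_c,ca_c_n,c_n_ca,ca_c_o Bond angles.
#' @export
peptide_geometry <- function(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                             c_o = 1.231, n_ca_c = 111.2, ca_c_n = 116.2,
                             c_n_ca = 121.7, ca_c_o = 120.8) {
  list(n_ca = n_ca, ca_c = ca_c, c_n = c_n, c_o = c_o,
       n_ca_c = n_ca_c, ca_c_n = ca_c_n, c_n_ca = c_n_ca, ca_c_o = ca_c_o)
}

# place atom D from A-B-C with bond |CD|, angle BCD, torsion ABCD (degrees)
nerf_place <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  ta <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  nv <- cross3(B - A, bc)
  nv <- nv / sqrt(sum(nv^2))
  m <- cross3(nv, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  C + d2[1] * bc + d2[2] * m + d2[3] * nv
}

#' Build a backbone from dihedral angles
#'
#' Sequential internal-coordinate (NeRF) construction of an N, CA, C, O
#' backbone with ideal geometry and planar trans peptide bonds
#' (omega fixed at 180 degrees). `phi[1]` and, for atom placement beyond the
#' carbonyl oxygen, `psi[n]` do not influence the chain; `NA` there is
#' accepted (a trailing `NA` psi places the last oxygen as if psi were 180).
#' Recomputing torsions from the built chain returns the inputs to well below
#' 1e-4 degrees.
#'
#' @param phi,psi Dihedrals in degrees, one per residue (same length, n >= 2).
#' @param aa Residue types (three-letter codes); defaults to `"GLY"`.
#' @param geometry A [peptide_geometry()].
#' @param chain Chain identifier for the generated model.
#' @param unit_label Label of the generated model.
#' @return A [fod_structure] with atoms N, CA, C, O per residue and
#'   backbone-derived effective atoms.
#' @export
build_backbone <- function(phi, psi, aa = NULL, geometry = peptide_geometry(),
                           chain = "A", unit_label = "built-backbone") {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  if (is.null(aa)) aa <- rep("GLY", n)
  stopifnot(length(aa) == n)
  if (any(!is.finite(phi[-1])) || any(!is.finite(psi[-n])))
    stop("non-finite dihedral in the chain-determining positions")

  g <- geometry
  N <- CA <- C <- O <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  a1 <- g$n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$ca_c * c(-cos(a1), sin(a1), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], C[[i]],
                               g$c_n, g$ca_c_n, psi[i])
      CA[[i + 1]] <- nerf_place(CA[[i]], C[[i]], N[[i + 1]],
                                g$n_ca, g$c_n_ca, 180)       # omega trans
      C[[i + 1]] <- nerf_place(C[[i]], N[[i + 1]], CA[[i + 1]],
                               g$ca_c, g$n_ca_c, phi[i + 1])
    }
    psi_i <- if (is.na(psi[i])) 180 else psi[i]
    O[[i]] <- nerf_place(N[[i]], CA[[i]], C[[i]],
                         g$c_o, g$ca_c_o, psi_i - 180)
  }

  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- rbind(N[[i]], CA[[i]], C[[i]], O[[i]])
    data.frame(chain = chain, seq_id = i, ins = "", aa = aa[i],
               elety = c("N", "CA", "C", "O"),
               x = p[, 1], y = p[, 2], z = p[, 3], stringsAsFactors = FALSE)
  }))
  residues <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- atoms[atoms$seq_id == i, ]
    p <- compute_effective_atom(data.frame(element = c("N", "C", "C", "O"),
                                           x = a$x, y = a$y, z = a$z))
    data.frame(chain = chain, seq_id = i, ins = "", aa = aa[i],
               x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }))
  fod_structure(residues, atoms = atoms, unit_label = unit_label)
}
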