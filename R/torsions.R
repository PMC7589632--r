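#' Dihedral angle of four points
#'
#' IUPAC-signed dihedral in degrees in (-180, 180]. The sign convention is
#' such that an ideal right-handed alpha helix gives phi of about -57 and psi
#' of about -47 degrees.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone torsion angles of a structure
#'
#' Computes phi and psi for every residue from the stored backbone atoms
#' (N, CA, C). Phi is undefined for the first residue of a chain and psi for
#' the last. A chain break (peptide C-N distance above `break_cutoff`) makes
#' the torsions spanning the break undefined, as does a missing backbone atom.
#'
#' @param model A [fod_structure] that retains its atom table.
#' @param break_cutoff Maximum C(i)-N(i+1) distance (Angstrom) for an intact
#'   peptide bond; default 2.5.
#' @return data.frame with columns `chain`, `seq_id`, `ins`, `aa`, `phi`,
#'   `psi` (`NA` where undefined).
#' @export
compute_torsions <- function(model, break_cutoff = 2.5) {
  if (is.null(model$atoms))
    stop("structure has no atom table; torsions need backbone atoms")
  res <- model$residues
  n <- nrow(res)
  bb <- function(i, name) {
    a <- model$atoms
    j <- which(a$chain == res$chain[i] & a$seq_id == res$seq_id[i] &
                 a$ins == res$ins[i] & a$elety == name)
    if (length(j) == 0L) return(NULL)
    c(a$x[j[1]], a$y[j[1]], a$z[j[1]])
  }
  N <- lapply(seq_len(n), bb, "N")
  CA <- lapply(seq_len(n), bb, "CA")
  C <- lapply(seq_len(n), bb, "C")

  linked <- rep(FALSE, n)  # peptide bond i-1 -> i intact
  for (i in seq_len(n)[-1]) {
    if (res$chain[i] != res$chain[i - 1]) next
    if (is.null(C[[i - 1]]) || is.null(N[[i]])) next
    linked[i] <- sqrt(sum((C[[i - 1]] - N[[i]])^2)) <= break_cutoff
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok_i <- !is.null(N[[i]]) && !is.null(CA[[i]]) && !is.null(C[[i]])
    if (!ok_i) next
    if (i > 1 && linked[i] && !is.null(C[[i - 1]]))
      phi[i] <- dihedral_angle(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    if (i < n && linked[i + 1] && !is.null(N[[i + 1]]))
      psi[i] <- dihedral_angle(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
  }
  data.frame(chain = res$chain, seq_id = res$seq_id, ins = res$ins,
             aa = res$aa, phi = phi, psi = psi, stringsAsFactors = FALSE)
}

#' Write a backbone model to a PDB file
#'
#' Writes the heavy backbone atoms (or all stored heavy atoms) of a structure
#' as standard ATOM records, re-loadable with [load_structure()].
#'
#' @param model A [fod_structure] with an atom table.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(model, path) {
  if (is.null(model$atoms) || nrow(model$atoms) == 0L)
    stop("model has no atoms to write")
  a <- model$atoms
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$seq_id, resid = a$aa, chain = a$chain,
                   insert = ifelse(a$ins == "", NA, a$ins),
                   elety = a$elety, eleno = seq_len(nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}
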