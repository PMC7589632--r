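#' Canonical orientation of a structure
#'
#' Centers the effective atoms at their geometric mean, rotates the molecule
#' so that the line through the two most distant effective atoms lies on the
#' X axis, then rotates about X so that the two most distant YZ-plane
#' projections lie on the Y axis. The per-axis standard deviations of the
#' enclosing Gaussian are then set by the 3-sigma rule:
#' \eqn{\sigma = \max_i |coordinate_i| / 3} on each axis.
#'
#' Ties for the most distant pair are broken by residue order (first pair in
#' lexicographic order wins); axis signs are fixed so that the first residue
#' of the pair has a positive coordinate. The theoretical density is even in
#' every coordinate, so the sign choice cannot affect it.
#'
#' @param model A [fod_structure].
#' @return Object of class `fod_oriented`: list with the transformed `model`
#'   and `sigma` (3-vector, Angstrom).
#' @export
orient_structure <- function(model) {
  xyz0 <- as.matrix(model$residues[, c("x", "y", "z")])
  n <- nrow(xyz0)
  if (n < 3L) stop("orientation needs at least 3 residues")
  ctr <- colMeans(xyz0)
  xyz <- sweep(xyz0, 2, ctr)
  if (max(abs(xyz)) < 1e-9) stop("degenerate geometry: all points coincide")

  # rotation 1: longest effective-atom pair onto the X axis
  pr <- farthest_pair(xyz)
  v <- xyz[pr[1], ] - xyz[pr[2], ]
  M <- rotation_to_x(v / sqrt(sum(v^2)))
  xyz1 <- xyz %*% t(M)
  if (xyz1[pr[1], 1] < 0) M <- diag(c(-1, 1, 1)) %*% M

  xyz1 <- xyz %*% t(M)
  # rotation 2 (about X): longest YZ-projection pair onto the Y axis
  yz <- xyz1[, 2:3, drop = FALSE]
  pr2 <- farthest_pair(yz)
  w <- yz[pr2[1], ] - yz[pr2[2], ]
  if (sqrt(sum(w^2)) > 1e-12) {
    ang <- -atan2(w[2], w[1])   # rotate w onto +Y (first axis of the YZ plane)
    R2 <- diag(3)
    R2[2:3, 2:3] <- matrix(c(cos(ang), -sin(ang),
                             sin(ang),  cos(ang)), 2, 2, byrow = TRUE)
    M <- R2 %*% M
    xyz1 <- xyz %*% t(M)
    if (xyz1[pr2[1], 2] < 0) {
      M <- diag(c(1, -1, 1)) %*% M
      xyz1 <- xyz %*% t(M)
    }
  }

  sigma <- apply(abs(xyz1), 2, max) / 3
  out <- model
  out$residues$x <- xyz1[, 1]; out$residues$y <- xyz1[, 2]
  out$residues$z <- xyz1[, 3]
  if (!is.null(out$atoms)) {
    axyz <- sweep(as.matrix(model$atoms[, c("x", "y", "z")]), 2, ctr) %*% t(M)
    out$atoms$x <- axyz[, 1]; out$atoms$y <- axyz[, 2]; out$atoms$z <- axyz[, 3]
  }
  structure(list(model = out, sigma = unname(sigma)), class = "fod_oriented")
}

# index pair (i, j), i < j, with maximal distance; ties -> lexicographic first
farthest_pair <- function(x) {
  d <- as.matrix(stats::dist(x))
  d[lower.tri(d, diag = TRUE)] <- -Inf
  best <- which(d >= max(d) - 1e-12, arr.ind = TRUE)   # row < col entries
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  c(best[1, 1], best[1, 2])
}

# rotation matrix sending unit vector u to +e1 (Rodrigues)
rotation_to_x <- function(u) {
  e1 <- c(1, 0, 0)
  cth <- sum(u * e1)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  v <- cross3(u, e1)
  s2 <- sum(v^2)
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s2)
}

#' @export
print.fod_oriented <- function(x, ...) {
  cat(sprintf("<fod_oriented> %s: %d residues, sigma = (%.2f, %.2f, %.2f) A\n",
              x$model$unit_label, nrow(x$model$residues),
              x$sigma[1], x$sigma[2], x$sigma[3]))
  invisible(x)
}
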