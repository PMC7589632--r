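# Independent brute-force oracles and fixture builders used across tests.

# observed profile by naive double loop (independent of the package path)
brute_force_observed <- function(xyz, h, cutoff = 9) {
  n <- nrow(xyz)
  o <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r <= cutoff) {
        s <- r / cutoff
        w <- 1 - 0.5 * (7 * s^2 - 9 * s^4 + 5 * s^6 - s^8)
        acc <- acc + (h[i] + h[j]) * w
      }
    }
    o[i] <- acc
  }
  o / sum(o)
}

# KL divergence by naive loop, base 2
brute_force_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i], base = 2)
  }
  s
}

# random rigid motion (proper rotation + translation) applied to a structure
apply_rigid_motion <- function(model, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  shift <- stats::runif(3, -30, 30)
  out <- model
  xyz <- as.matrix(model$residues[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  out$residues$x <- xyz[, 1]; out$residues$y <- xyz[, 2]
  out$residues$z <- xyz[, 3]
  if (!is.null(model$atoms)) {
    axyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
    axyz <- sweep(axyz, 2, shift, "+")
    out$atoms$x <- axyz[, 1]; out$atoms$y <- axyz[, 2]; out$atoms$z <- axyz[, 3]
  }
  out
}

# random effective-atom structure in a box, standard residue types
random_cloud_structure <- function(n, seed, box = 18) {
  set.seed(seed)
  xyz <- matrix(stats::runif(3 * n, -box / 2, box / 2), n, 3)
  fod_structure(data.frame(chain = "A", seq_id = seq_len(n), ins = "",
                           aa = sample(STANDARD_AA, n, replace = TRUE),
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           stringsAsFactors = FALSE),
                unit_label = sprintf("random-%d-%d", n, seed))
}

# profiles data.frame straight from vectors (for divergence-level tests)
profiles_from <- function(T, O) {
  n <- length(T)
  out <- data.frame(chain = "A", seq_id = seq_len(n), ins = "",
                    aa = "ALA", T = T, O = O, R = 1 / n,
                    stringsAsFactors = FALSE)
  class(out) <- c("fod_profiles", "data.frame")
  out
}

pdb_atom_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                          occ = 1, elem = substr(trimws(name), 1, 1),
                          record = "ATOM") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, alt, resn, chain, resno, x, y, z,
          occ, 0, elem)
}

# hand-written 3-residue PDB exercising altloc, HETATM and hydrogen handling
write_mini_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N",  " ", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 1, 1.458, 0.0, 0.0),
    pdb_atom_line(3, "C",  " ", "ALA", "A", 1, 2.009, 1.422, 0.0),
    pdb_atom_line(4, "CB", "A", "ALA", "A", 1, 2.0, -1.0, 0.5, occ = 0.7),
    pdb_atom_line(5, "CB", "B", "ALA", "A", 1, 2.0, -1.0, -0.5, occ = 0.3),
    pdb_atom_line(6, "N",  " ", "GLY", "A", 2, 1.329, 2.422, 0.0),
    pdb_atom_line(7, "CA", " ", "GLY", "A", 2, 2.0, 3.7, 0.0),
    pdb_atom_line(8, "C",  " ", "GLY", "A", 2, 3.5, 3.6, 0.2),
    pdb_atom_line(9, "HA", " ", "GLY", "A", 2, 2.0, 4.0, 1.0, elem = "H"),
    pdb_atom_line(10, "N",  " ", "SER", "A", 3, 4.2, 4.7, 0.2),
    pdb_atom_line(11, "CA", " ", "SER", "A", 3, 5.6, 4.8, 0.4),
    pdb_atom_line(12, "C",  " ", "SER", "A", 3, 6.3, 6.1, 0.1),
    pdb_atom_line(13, "O",  " ", "HOH", "A", 9, 9.0, 9.0, 9.0,
                  record = "HETATM"),
    "END")
  writeLines(lines, path)
  path
}
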