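#' Theoretical (Gaussian) hydrophobicity profile
#'
#' Evaluates the 3D Gaussian density of the oriented molecule at every
#' effective atom and normalizes the values to sum to one. The profile is a
#' pure function of geometry; the hydrophobicity scale never enters.
#'
#' @param oriented A `fod_oriented` (see [orient_structure()]).
#' @return Numeric vector summing to 1, one entry per residue.
#' @export
theoretical_profile <- function(oriented) {
  sigma <- oriented$sigma
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("degenerate geometry: sigma must be strictly positive on all axes")
  r <- oriented$model$residues
  g <- exp(-r$x^2 / (2 * sigma[1]^2)) *
       exp(-r$y^2 / (2 * sigma[2]^2)) *
       exp(-r$z^2 / (2 * sigma[3]^2))
  g / sum(g)
}

#' Distance weight of the observed-hydrophobicity collector
#'
#' The polynomial contact function used to accumulate pairwise hydrophobic
#' interactions: `w(r) = 1 - 1/2 (7(r/c)^2 - 9(r/c)^4 + 5(r/c)^6 - (r/c)^8)`
#' for `r <= c` and 0 beyond the cutoff. `w(0) = 1` and `w(c) = 0`.
#'
#' @param r Distances (Angstrom), vectorized.
#' @param cutoff Interaction cutoff c, default 9 Angstrom.
#' @export
pair_weight <- function(r, cutoff = 9) {
  s <- r / cutoff
  w <- 1 - 0.5 * (7 * s^2 - 9 * s^4 + 5 * s^6 - s^8)
  w[r > cutoff] <- 0
  w
}

#' Observed hydrophobicity profile
#'
#' For every residue, sums `(H_i^r + H_j^r) * w(r_ij)` over all other
#' residues `j != i` within the cutoff, where `H^r` is the intrinsic
#' hydrophobicity of the residue type under the active scale, and normalizes
#' the result to sum to one. The self term is excluded: the collector
#' accumulates pairwise interactions, and a `j = i` term would add a constant
#' `2 H_i^r` that double-counts intrinsic hydrophobicity
#' (`include_self = TRUE` restores it for comparison).
#'
#' @param model A [fod_structure] or `fod_oriented` (distances are
#'   rigid-motion invariant, so orientation is irrelevant here).
#' @param scale Named hydrophobicity vector (see
#'   [read_hydrophobicity_scale()]).
#' @param cutoff Interaction cutoff (Angstrom), default 9.
#' @param include_self Include the `j = i` term; default `FALSE`.
#' @return Numeric vector summing to 1, one entry per residue.
#' @export
observed_profile <- function(model, scale = default_scale(), cutoff = 9,
                             include_self = FALSE) {
  if (inherits(model, "fod_oriented")) model <- model$model
  res <- model$residues
  h <- scale[res$aa]
  if (any(is.na(h))) stop("residue type(s) missing from the scale: ",
                          paste(unique(res$aa[is.na(h)]), collapse = ", "))
  xyz <- as.matrix(res[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  w <- pair_weight(d, cutoff)
  if (!include_self) diag(w) <- 0
  hs <- outer(h, h, "+")
  o <- rowSums(hs * w)
  tot <- sum(o)
  if (!is.finite(tot) || tot <= 0)
    stop("observed profile cannot be normalized: ",
         "all pairwise contributions are zero")
  unname(o / tot)
}

#' Per-residue T / O / R hydrophobicity profiles
#'
#' Convenience wrapper: orients the structure, computes the theoretical (T),
#' observed (O) and uniform (R = 1/N) distributions and returns them with the
#' residue identities.
#'
#' @inheritParams observed_profile
#' @return A data.frame of class `fod_profiles` with columns `chain`,
#'   `seq_id`, `ins`, `aa`, `T`, `O`, `R` and attributes `sigma`,
#'   `unit_label`, `cutoff`, `scale_name`.
#' @export
hydro_profiles <- function(model, scale = default_scale(), cutoff = 9,
                           include_self = FALSE) {
  oriented <- if (inherits(model, "fod_oriented")) model
              else orient_structure(model)
  Tv <- theoretical_profile(oriented)
  Ov <- observed_profile(oriented, scale = scale, cutoff = cutoff,
                         include_self = include_self)
  res <- oriented$model$residues
  out <- data.frame(chain = res$chain, seq_id = res$seq_id, ins = res$ins,
                    aa = res$aa, T = Tv, O = Ov, R = 1 / nrow(res),
                    stringsAsFactors = FALSE)
  class(out) <- c("fod_profiles", "data.frame")
  attr(out, "sigma") <- oriented$sigma
  attr(out, "unit_label") <- oriented$model$unit_label
  attr(out, "cutoff") <- cutoff
  attr(out, "scale_name") <- attr(scale, "scale_name")
  out
}
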