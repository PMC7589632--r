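#' Kullback-Leibler divergence in bits
#'
#' `sum(P * log2(P / Q))` with the convention `0 * log(0/q) = 0`. Entries of
#' `P` below 1e-15 are treated as exact zeros. An entry with `P > 0` where
#' `Q = 0` makes the divergence undefined and raises an error.
#'
#' @param p,q Probability vectors of equal length, each summing to 1
#'   (checked to 1e-6).
#' @return Non-negative divergence in bits.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))  # 1 bit
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("distributions differ in length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must each sum to 1")
  p <- ifelse(p < 1e-15, 0, p)
  live <- p > 0
  if (any(live & q <= 0))
    stop("undefined divergence: P > 0 where Q = 0")
  sum(p[live] * log2(p[live] / q[live]))
}

#' RD: relative distance of the observed profile between T and R
#'
#' `RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))`. Values below 0.5 indicate an
#' observed hydrophobicity distribution closer to the idealized centric
#' (micelle-like) Gaussian than to the featureless uniform reference.
#'
#' @param profiles A `fod_profiles` object (see [hydro_profiles()]), or any
#'   data.frame with columns `T`, `O`, `R`.
#' @return Object of class `fod_result`: list with `dkl_ot`, `dkl_or` (bits),
#'   `rd`, `micelle_like`, `n`, `unit_label`.
#' @export
relative_distance <- function(profiles) {
  Tv <- profiles$T / sum(profiles$T)
  Ov <- profiles$O / sum(profiles$O)
  Rv <- rep(1 / length(Tv), length(Tv))
  d_ot <- kl_divergence(Ov, Tv)
  d_or <- kl_divergence(Ov, Rv)
  denom <- d_ot + d_or
  rd <- if (denom > 0) d_ot / denom else NA_real_
  structure(list(dkl_ot = d_ot, dkl_or = d_or, rd = rd,
                 micelle_like = if (is.na(rd)) NA else rd < 0.5,
                 n = length(Tv),
                 unit_label = attr(profiles, "unit_label") %||% "unit"),
            class = "fod_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fod_result <- function(x, ...) {
  cat(sprintf(
    "<fod_result> %s (n = %d): D(O|T) = %.4f, D(O|R) = %.4f bits, RD = %s%s\n",
    x$unit_label, x$n, x$dkl_ot, x$dkl_or,
    if (is.na(x$rd)) "undefined" else sprintf("%.3f", x$rd),
    if (isTRUE(x$micelle_like)) " (micelle-like)" else ""))
  invisible(x)
}

#' Parse residue-range specifications
#'
#' Accepts strings such as `"35,53,55-58"` (author numbering, inclusive) or a
#' list of `c(lo, hi)` pairs, and returns a two-column matrix of ranges.
#'
#' @param ranges Character scalar or list of numeric ranges.
#' @export
parse_ranges <- function(ranges) {
  if (is.character(ranges)) {
    stopifnot(length(ranges) == 1L)
    parts <- strsplit(ranges, ",", fixed = TRUE)[[1]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    if (!length(parts)) stop("empty range specification")
    ranges <- lapply(parts, function(p) {
      m <- regmatches(p, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
      if (length(m) == 0L || !nzchar(m[2]))
        stop("cannot parse range element: '", p, "'")
      lo <- as.integer(m[2])
      hi <- if (nzchar(m[3])) as.integer(m[3]) else lo
      c(lo, hi)
    })
  }
  m <- do.call(rbind, lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2])
      stop("each range must be c(lo, hi) with lo <= hi")
    r
  }))
  colnames(m) <- c("lo", "hi")
  m
}

resolve_ranges <- function(profiles, ranges) {
  m <- parse_ranges(ranges)
  sel <- rep(FALSE, nrow(profiles))
  for (k in seq_len(nrow(m)))
    sel <- sel | (profiles$seq_id >= m[k, "lo"] & profiles$seq_id <= m[k, "hi"])
  sel
}

#' RD of a chain fragment within a fixed structural unit
#'
#' Restricts the parent unit's T and O profiles to the residues of the
#' fragment, renormalizes each to sum to one, sets R to `1/n_fragment` and
#' recomputes RD. The parent's orientation and Gaussian are kept as they are:
#' the fragment is scored inside the field of the unit it belongs to, never
#' re-derived.
#'
#' @param profiles `fod_profiles` of the parent unit.
#' @param ranges Fragment residue ranges (author numbering), see
#'   [parse_ranges()].
#' @param mode `"select"` keeps the listed residues, `"eliminate"` drops them
#'   and rescores the remainder.
#' @return A `fod_result` for the fragment (or remainder).
#' @export
fragment_rd <- function(profiles, ranges, mode = c("select", "eliminate")) {
  mode <- match.arg(mode)
  sel <- resolve_ranges(profiles, ranges)
  if (!any(sel) && mode == "select")
    stop("fragment resolves to no residues of the unit")
  keep <- if (mode == "select") sel else !sel
  if (!any(keep)) stop("elimination empties the unit")
  sub <- profiles[keep, , drop = FALSE]
  sub$T <- sub$T / sum(sub$T)
  sub$O <- sub$O / sum(sub$O)
  sub$R <- 1 / nrow(sub)
  attr(sub, "unit_label") <-
    sprintf("%s[%s %s]", attr(profiles, "unit_label") %||% "unit", mode,
            if (is.character(ranges)) ranges
            else paste(apply(parse_ranges(ranges), 1, function(r)
              if (r[1] == r[2]) r[1] else paste0(r[1], "-", r[2])),
              collapse = ","))
  relative_distance(sub)
}

#' @rdname fragment_rd
#' @export
eliminate_and_rescore <- function(profiles, ranges) {
  fragment_rd(profiles, ranges, mode = "eliminate")
}

#' Pearson correlation between the T and O profiles
#'
#' @param profiles A `fod_profiles` object.
#' @return Correlation coefficient; `NA` with a warning when either profile
#'   has zero variance.
#' @export
to_correlation <- function(profiles) {
  if (nrow(profiles) < 3L) stop("correlation needs at least 3 residues")
  if (stats::sd(profiles$T) == 0 || stats::sd(profiles$O) == 0) {
    warning("zero variance in T or O; correlation undefined")
    return(NA_real_)
  }
  stats::cor(profiles$T, profiles$O)
}

#' One-call RD for a structure file or model
#'
#' @param x Path to a PDB/mmCIF file or a [fod_structure].
#' @param ... Passed to [load_structure()] (for paths).
#' @inheritParams observed_profile
#' @export
rd_for_structure <- function(x, scale = default_scale(), cutoff = 9, ...) {
  model <- if (inherits(x, "fod_structure")) x else load_structure(x, ...)
  relative_distance(hydro_profiles(model, scale = scale, cutoff = cutoff))
}
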