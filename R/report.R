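#' Per-residue hydrophobicity status
#'
#' Classifies every residue by comparing its theoretical (T) and observed (O)
#' density. With thresholds expressed in units of the uniform level `1/N`
#' (so defaults are chain-length invariant):
#' core if `min(T, O) >= tau_high`; surface if `max(T, O) < tau_low`
#' (strictly below the uniform level, so a featureless profile is not read
#' as an all-surface protein);
#' deficit if `T - O >= delta` (expected but unrealized hydrophobicity, the
#' signature of catalytic pockets); excess if `O - T >= delta`; otherwise
#' insignificant. The rules are applied in that order, which makes the
#' categories mutually exclusive and exhaustive.
#'
#' @param profiles A `fod_profiles` object.
#' @param tau_high Core threshold; default `1.5/N`.
#' @param tau_low Surface threshold; default `1/N`.
#' @param delta Discordance threshold; default `1/N`.
#' @return Character vector of statuses with a `thresholds` attribute.
#' @export
classify_residues <- function(profiles,
                              tau_high = 1.5 / nrow(profiles),
                              tau_low = 1 / nrow(profiles),
                              delta = 1 / nrow(profiles)) {
  if (tau_low > tau_high) stop("inconsistent thresholds: tau_low > tau_high")
  if (delta <= 0) stop("delta must be positive")
  Tv <- profiles$T; Ov <- profiles$O
  status <- ifelse(pmin(Tv, Ov) >= tau_high, "core",
            ifelse(pmax(Tv, Ov) < tau_low, "surface",
            ifelse(Tv - Ov >= delta, "deficit",
            ifelse(Ov - Tv >= delta, "excess", "insignificant"))))
  attr(status, "thresholds") <- c(tau_high = tau_high, tau_low = tau_low,
                                  delta = delta)
  status
}

#' Tabular per-residue report
#'
#' Joins profiles, statuses and (optionally) torsions and early-stage
#' assignments into one table; [write_profile_table()] renders it as TSV with
#' six-decimal numeric columns, [read_profile_table()] reads it back.
#'
#' @param profiles A `fod_profiles` object.
#' @param statuses Optional output of [classify_residues()].
#' @param torsions Optional output of [compute_torsions()].
#' @param es Optional `assignment` data.frame from [make_early_stage()].
#' @return data.frame with columns `seq_id`, `aa`, `T`, `O`, `R`
#'   (then `status`, `phi`, `psi`, `phi_e`, `psi_e`, `code` when supplied).
#' @export
profile_table <- function(profiles, statuses = NULL, torsions = NULL,
                          es = NULL) {
  out <- data.frame(seq_id = profiles$seq_id, aa = profiles$aa,
                    T = profiles$T, O = profiles$O, R = profiles$R,
                    stringsAsFactors = FALSE)
  if (!is.null(statuses)) {
    if (length(statuses) != nrow(out)) stop("status length mismatch")
    out$status <- as.character(statuses)
  }
  if (!is.null(torsions)) {
    if (nrow(torsions) != nrow(out)) stop("torsion length mismatch")
    out$phi <- torsions$phi; out$psi <- torsions$psi
  }
  if (!is.null(es)) {
    if (nrow(es) != nrow(out)) stop("early-stage assignment length mismatch")
    out$phi_e <- es$phi_e; out$psi_e <- es$psi_e; out$code <- es$code
  }
  out
}

#' @rdname profile_table
#' @param table A [profile_table()] result.
#' @param path Output/input TSV path.
#' @export
write_profile_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1)) &
    !(names(table) %in% "seq_id")
  table[num] <- lapply(table[num], function(x) sprintf("%.6f", x))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname profile_table
#' @export
read_profile_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Run manifest
#'
#' A JSON-serializable record of one analysis run: inputs, parameter values,
#' content hashes and results, sufficient to rerun the computation exactly.
#'
#' @param structure_id Identifier of the structure (file base name, PDB id).
#' @param model_index,chain Structure selection used.
#' @param scale The hydrophobicity scale used.
#' @param cutoff Interaction cutoff (Angstrom).
#' @param ellipse Optional [ellipse_path()] used for early-stage analysis.
#' @param fragments Optional named list/character of fragment range strings.
#' @param results Named list of `fod_result` objects (e.g. native, es).
#' @param correlation Optional T-O Pearson correlation.
#' @return List of class `fod_manifest`.
#' @export
run_manifest <- function(structure_id, model_index = 1L, chain = NULL,
                         scale = default_scale(), cutoff = 9,
                         ellipse = NULL, fragments = NULL, results = list(),
                         correlation = NULL) {
  res <- lapply(results, function(r)
    list(dkl_ot = r$dkl_ot, dkl_or = r$dkl_or, rd = r$rd,
         micelle_like = r$micelle_like, n = r$n, unit_label = r$unit_label))
  m <- list(structure_id = structure_id,
            model_index = model_index,
            chain = chain,
            scale_name = attr(scale, "scale_name") %||% "unnamed",
            scale_hash = object_hash(round(unclass(scale), 12)),
            cutoff = cutoff,
            ellipse_hash = if (is.null(ellipse)) NULL else
              object_hash(ellipse[c("center", "semi_axes", "tilt",
                                    "anchors")]),
            fragments = fragments,
            results = res,
            correlation = correlation)
  class(m) <- "fod_manifest"
  m
}

# md5 of a canonical serialization (timestamp-free)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' @rdname run_manifest
#' @param manifest A `fod_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
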