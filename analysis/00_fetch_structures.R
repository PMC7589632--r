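#!/usr/bin/env Rscript
# Fetches the study set of PDB entries into inst/extdata/pdb/ so that the
# real-structure analyses (03_real_structures.R) and the reference-value
# acceptance checks can run. Requires network access to the RCSB; all other
# scripts work offline on generated structures.

ids <- c("2CYU", "2L6Q", "2L6R", "1W4E", "1W4F", "1W4G", "1W4H", "2BTH",
         "1W4J", "1W4K", "1BBL", "2WXC", "2A3D", "2F21", "2P6J",
         "1WFA", "1LZ1")

dest <- file.path("inst", "extdata", "pdb")
dir.create(dest, showWarnings = FALSE, recursive = TRUE)

ok <- character()
for (id in ids) {
  out <- file.path(dest, paste0(tolower(id), ".pdb"))
  if (file.exists(out)) { ok <- c(ok, id); next }
  got <- tryCatch({
    bio3d::get.pdb(id, path = dest, verbose = FALSE)
    src <- file.path(dest, paste0(id, ".pdb"))
    if (file.exists(src)) file.rename(src, out)
    file.exists(out)
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (got) ok <- c(ok, id) else message("could not fetch ", id)
}

if (length(ok) == length(ids)) {
  cat("fetched all", length(ids), "entries into", dest, "\n")
  cat("reinstall the package so system.file() finds them:\n",
      "  R CMD INSTALL .\n")
} else if (length(ok) == 0) {
  cat("no entries fetched (no network access?); offline analyses",
      "(01, 02) still run on generated structures\n")
} else {
  cat("fetched", length(ok), "of", length(ids), "entries\n")
}
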