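#!/usr/bin/env Rscript
# Synthetic benchmark of the RD statistic: clouds with a Gaussian-packed
# hydrophobic core (micelle), inverted clouds (anti-micelle), unstructured
# clouds (uniform), and the elongated-helix negative control. Writes
# results/synthetic_rd.tsv and prints a summary.

suppressPackageStartupMessages(library(oildrop))
dir.create("results", showWarnings = FALSE)

n_chain <- 60L
seeds <- 1:20

rows <- list()
for (mode in c("micelle", "anti_micelle", "uniform")) {
  for (s in seeds) {
    pr <- hydro_profiles(generate_cloud(synthetic_spec(n_chain, mode,
                                                       seed = s)))
    r <- relative_distance(pr)
    rows[[length(rows) + 1]] <-
      data.frame(mode = mode, seed = s, n = r$n, dkl_ot = r$dkl_ot,
                 dkl_or = r$dkl_or, rd = r$rd,
                 to_corr = to_correlation(pr))
  }
}
# the antifreeze-like control: a 37-residue helix spanning the whole chain
for (s in seeds[1:5]) {
  pr <- hydro_profiles(generate_backbone(synthetic_spec(37L, "ideal_helix",
                                                        seed = s)))
  r <- relative_distance(pr)
  rows[[length(rows) + 1]] <-
    data.frame(mode = "ideal_helix", seed = s, n = r$n, dkl_ot = r$dkl_ot,
               dkl_or = r$dkl_or, rd = r$rd, to_corr = to_correlation(pr))
}

tab <- do.call(rbind, rows)
write.table(tab, "results/synthetic_rd.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nRD by construction mode (", length(seeds), "seeds, n =", n_chain,
    "for clouds):\n")
print(aggregate(rd ~ mode, tab, function(x)
  c(mean = round(mean(x), 3), min = round(min(x), 3),
    max = round(max(x), 3))))
cat("\nmicelle clouds below RD 0.5:",
    sum(tab$rd[tab$mode == "micelle"] < 0.5), "/", length(seeds), "\n")
cat("anti-micelle clouds above RD 0.5:",
    sum(tab$rd[tab$mode == "anti_micelle"] > 0.5), "/", length(seeds), "\n")
cat("helix controls above RD 0.5:",
    sum(tab$rd[tab$mode == "ideal_helix"] > 0.5), "/ 5\n")
cat("\nwrote results/synthetic_rd.tsv\n")
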