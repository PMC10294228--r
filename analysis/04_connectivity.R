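#!/usr/bin/env Rscript
# Score every drug profile for reversal of each retained signature: KS
# tag-enrichment of the up and down sets in the drug's ranking, combined
# into the RGES, with a 10,000-draw permutation null shared across drugs,
# BH correction, and the hit rule q < 0.05 & RGES < 0.
source("analysis/00_config.R")

outdir <- "results/connectivity"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
config <- study_config()
n_perm <- 10000L

sig_files <- list.files("results/signatures", pattern = "^signature_.*\\.tsv$",
                        full.names = TRUE)
for (f in sig_files) {
  tag <- sub("^signature_(.*)\\.tsv$", "\\1", basename(f))
  sig_tab <- read.delim(f)
  sig <- signature_profile(tag,
                           up = sig_tab$gene_id[sig_tab$direction == "up"],
                           down = sig_tab$gene_id[sig_tab$direction == "down"],
                           log2fc = setNames(sig_tab$log2fc, sig_tab$gene_id))
  if (!sig$retained) {
    cat(sprintf("arm %s: signature not retained, skipped\n", tag))
    next
  }
  drugs <- read_drug_profiles(file.path("results/sim",
                                        sprintf("drugs_%s.tsv", tag)))
  rec <- score_compendium(sig, drugs, n_perm = n_perm, seed = config$seed)
  write.table(rec, file.path(outdir, sprintf("rges_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- rec[1L, ]
  cat(sprintf("arm %s: %d hit(s) of %d drugs; top: %s (RGES %.3f, q %.2g)\n",
              tag, sum(rec$hit), nrow(rec), top$drug_id, top$rges, top$q))
}
cat("written to", outdir, "\n")
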