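#!/usr/bin/env Rscript
# Cross-arm aggregation: the drugs x arms hit matrix (RGES defined only
# where a drug is a significant hit), drugs recurring as hits across arms,
# and genes recurring across the retained signatures.
source("analysis/00_config.R")

outdir <- "results/summary"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

rges_files <- list.files("results/connectivity", pattern = "^rges_.*\\.tsv$",
                         full.names = TRUE)
records <- do.call(rbind, lapply(rges_files, read.delim))

sig_files <- list.files("results/signatures", pattern = "^signature_.*\\.tsv$",
                        full.names = TRUE)
signatures <- lapply(sig_files, function(f) {
  tab <- read.delim(f)
  signature_profile(sub("^signature_(.*)\\.tsv$", "\\1", basename(f)),
                    up = tab$gene_id[tab$direction == "up"],
                    down = tab$gene_id[tab$direction == "down"])
})

hs <- hit_matrix(records, signatures)
write.table(data.frame(drug_id = names(hs$hit_counts),
                       n_arms_hit = unname(hs$hit_counts)),
            file.path(outdir, "hit_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
rh <- recurrent_hits(hs, min_arms = 2L)
write.table(rh, file.path(outdir, "recurrent_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
rg <- recurrent_genes(hs, min_profiles = 2L)
write.table(rg, file.path(outdir, "recurrent_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d arms, %d drugs; %d drug(s) hit in >= 2 arms\n",
            length(hs$arms), length(hs$drugs), nrow(rh)))
if (nrow(rh))
  cat(sprintf("top recurrent hit: %s (%d arms, mean RGES %.3f)\n",
              rh$drug_id[1], rh$n_arms_hit[1], rh$mean_rges[1]))
cat(sprintf("%d gene(s) appear in >= 2 retained signatures\n", nrow(rg)))
cat("written to", outdir, "\n")
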