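#!/usr/bin/env Rscript
# Derive per-arm resistance signatures: 75th-percentile normalization,
# RCB-based stratification (sensitive = RCB 0/I, resistant = III, II and
# missing excluded), moderated differential expression, MCC-optimized
# log2FC cutoff selection, and the strict >50-gene retention rule.
source("analysis/00_config.R")

indir <- "results/sim"
outdir <- "results/signatures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
config <- study_config()

expr <- normalize_array(read_expression(file.path(indir, "expression.tsv")))
ann <- read_annotations(file.path(indir, "annotations.tsv"))
arms <- stratify_arms(expr, ann)
dropped <- attr(arms, "dropped")
if (nrow(dropped))
  cat("dropped arms:", paste(dropped$arm_id, collapse = ", "), "\n")

for (a in names(arms)) {
  cohort <- arms[[a]]
  de <- moderated_de(cohort)
  sel <- select_lfc_cutoff(de, cohort, seed = config$seed)
  sig <- build_signature(de, sel$cutoff, a, mcc = sel$mcc)
  tag <- arm_tag(a)
  write.table(de, file.path(outdir, sprintf("de_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sel$trace, file.path(outdir, sprintf("cutoff_trace_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig_df <- sig$genes
  sig_df$direction <- ifelse(sig_df$log2fc > 0, "up", "down")
  write.table(sig_df, file.path(outdir, sprintf("signature_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "arm %s (%d sensitive / %d resistant): cutoff %.1f, MCC %.2f, %d genes (%d up, %d down), retained=%s\n",
    a, sum(cohort$labels == "sensitive"), sum(cohort$labels == "resistant"),
    sel$cutoff, sel$mcc, nrow(sig$genes),
    length(sig$up_genes), length(sig$down_genes), sig$retained))
}
cat("written to", outdir, "\n")
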