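#!/usr/bin/env Rscript
# Generate the synthetic study: a two-arm neoadjuvant cohort with planted
# resistance signatures (60 of 100 genes shared across arms so recurrence
# is observable), a per-arm drug compendium of 200 random profiles plus a
# planted reverser and mimicker, and a gene-set collection per arm.
source("analysis/00_config.R")

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
config <- study_config()

sim <- gen_cohort(config)
write_expression(sim$expression, file.path(outdir, "expression.tsv"))
write_annotations(sim$annotations, file.path(outdir, "annotations.tsv"))
jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

for (a in names(sim$truth$arms)) {
  dp <- gen_drug_profiles(config, sim$truth, a)
  write_drug_profiles(dp, file.path(outdir, sprintf("drugs_%s.tsv", arm_tag(a))))
  sets <- gen_gene_sets(config, sim$truth, arm = a, n_random = 10L)
  write_gmt(sets, file.path(outdir, sprintf("sets_%s.gmt", arm_tag(a))))
}

cat(sprintf("cohort: %d genes x %d samples across %d arms\n",
            nrow(sim$expression), ncol(sim$expression), length(config$arms)))
cat(sprintf("compendium per arm: %d drugs (incl. reverser + mimicker)\n",
            config$n_drugs + 2L))
cat(sprintf("planted signature: %d genes per arm, %d shared across arms\n",
            config$n_signature_genes, config$n_shared_signature_genes))
cat("written to", outdir, "\n")
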