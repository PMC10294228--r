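#' Run the full simulate -> signatures -> GSEA -> connectivity pipeline
#'
#' Self-contained end-to-end driver: generates a synthetic cohort, drug
#' compendium and gene-set collection from `config`, then runs
#' normalization, arm stratification, moderated differential expression,
#' MCC-optimized cutoff selection, signature assembly, preranked GSEA and
#' RGES connectivity scoring, and writes every intermediate table, a
#' machine-readable run manifest and a plain-text log under `outdir`.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config a [sim_config()], or path to a YAML file whose top-level
#'   `sim` section holds `sim_config` fields (with optional `arms` entries)
#'   and whose optional `thresholds` section overrides the analysis
#'   defaults (`p_threshold`, `min_genes`, `q_threshold`, `n_perm_gsea`,
#'   `n_perm_connectivity`, `n_random_sets`, `min_per_group`).
#' @param outdir output directory (created if needed).
#' @param p_threshold DE p-value filter.
#' @param min_genes strict signature retention threshold.
#' @param q_threshold hit FDR threshold.
#' @param n_perm_gsea GSEA permutation count.
#' @param n_perm_connectivity RGES permutation count.
#' @param n_random_sets random gene sets in the simulated collection.
#' @param min_per_group minimum samples per response group.
#' @return (invisibly) list with `arms`, `signatures`, `gsea`, `records`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         p_threshold = 0.01, min_genes = 50L,
                         q_threshold = 0.05,
                         n_perm_gsea = 2000L, n_perm_connectivity = 100000L,
                         n_random_sets = 10L, min_per_group = 3L) {
  if (is.character(config)) {
    loaded <- load_run_config(config)
    config <- loaded$config
    for (nm in names(loaded$thresholds)) assign(nm, loaded$thresholds[[nm]])
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  }

  note("pipeline start: %d genes, %d arm spec(s), %d drugs, master seed %d",
       config$n_genes, length(config$arms), config$n_drugs, config$seed)
  sim <- gen_cohort(config)
  write_expression(sim$expression, file.path(outdir, "expression.tsv"))
  write_annotations(sim$annotations, file.path(outdir, "annotations.tsv"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  expr <- normalize_array(sim$expression)
  arms <- stratify_arms(expr, sim$annotations, min_per_group = min_per_group)
  dropped <- attr(arms, "dropped")
  for (i in seq_len(nrow(dropped)))
    note("arm %s dropped: %s", dropped$arm_id[i], dropped$reason[i])
  note("%d arm(s) stratified", length(arms))

  grid <- seq(1, 0, by = -0.1)
  signatures <- list()
  gsea_results <- list()
  records <- list()
  manifest_arms <- list()
  for (a in names(arms)) {
    tag <- sanitize_id(a)
    cohort <- arms[[a]]
    de <- moderated_de(cohort)
    utils::write.table(de, file.path(outdir, sprintf("de_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel <- select_lfc_cutoff(de, cohort, p_threshold = p_threshold,
                             grid = grid, seed = config$seed)
    utils::write.table(sel$trace,
                       file.path(outdir, sprintf("cutoff_trace_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- build_signature(de, sel$cutoff, a, mcc = sel$mcc,
                           p_threshold = p_threshold, min_genes = min_genes)
    signatures[[a]] <- sig
    sig_df <- sig$genes
    sig_df$direction <- ifelse(sig_df$log2fc > 0, "up", "down")
    utils::write.table(sig_df,
                       file.path(outdir, sprintf("signature_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("arm %s: cutoff %.1f, MCC %.3f, %d signature genes, retained=%s",
         a, sel$cutoff, sel$mcc, nrow(sig$genes), sig$retained)

    sets <- gen_gene_sets(config, sim$truth, arm = a, n_random = n_random_sets)
    gsea <- gsea_preranked(de, sets, n_perm = n_perm_gsea, seed = config$seed)
    gsea_results[[a]] <- gsea
    utils::write.table(gsea, file.path(outdir, sprintf("gsea_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    manifest_arms[[a]] <- list(
      arm_id = a, n_samples = length(cohort$sample_ids),
      cutoff_grid = grid, chosen_cutoff = sel$cutoff, mcc = sel$mcc,
      n_signature_genes = nrow(sig$genes), retained = sig$retained)

    if (!sig$retained) {
      note("arm %s: signature not retained (<= %d genes), skipping connectivity",
           a, min_genes)
      next
    }
    drugs <- gen_drug_profiles(config, sim$truth, a)
    write_drug_profiles(drugs, file.path(outdir, sprintf("drugs_%s.tsv", tag)))
    rec <- score_compendium(sig, drugs, n_perm = n_perm_connectivity,
                            seed = config$seed, q_threshold = q_threshold)
    records[[a]] <- rec
    utils::write.table(rec, file.path(outdir, sprintf("rges_%s.tsv", tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("arm %s: %d drug hit(s) of %d profiles", a, sum(rec$hit), nrow(rec))
  }

  summary <- NULL
  if (length(records)) {
    summary <- hit_matrix(do.call(rbind, records), signatures)
    utils::write.table(
      data.frame(drug_id = names(summary$hit_counts),
                 n_arms_hit = unname(summary$hit_counts)),
      file.path(outdir, "hit_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rg <- recurrent_genes(summary, min_profiles = 1L)
    utils::write.table(rg, file.path(outdir, "recurrent_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "revsig",
    package_version = as.character(utils::packageVersion("revsig")),
    sim_config = unclass(config),
    thresholds = list(p_threshold = p_threshold, min_genes = min_genes,
                      q_threshold = q_threshold,
                      n_perm_gsea = n_perm_gsea,
                      n_perm_connectivity = n_perm_connectivity,
                      n_random_sets = n_random_sets,
                      min_per_group = min_per_group),
    arms = unname(manifest_arms),
    dropped_arms = dropped)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "log.txt"))
  invisible(list(arms = arms, signatures = signatures, gsea = gsea_results,
                 records = records, summary = summary, manifest = manifest))
}

# YAML run config: `sim` section maps onto sim_config(); its `arms` entries
# map onto arm_spec(); `thresholds` overrides the analysis defaults.
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$sim %||% list()
  if (!is.null(sim$arms))
    sim$arms <- lapply(sim$arms, function(a) do.call(arm_spec, a))
  config <- do.call(sim_config, sim)
  list(config = config, thresholds = y$thresholds %||% list())
}
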