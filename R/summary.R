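#' Cross-arm hit summary
#'
#' Assembles the drugs x arms RGES matrix (defined only where a drug is a
#' significant hit; non-hits are `NA`, never 0, since RGES 0 is a
#' meaningful score), per-drug hit counts, and per-gene signature-
#' membership counts over the retained signatures.
#'
#' @param records `rges_records` rows from one or more arms (rbind-able).
#' @param signatures optional list of `signature_profile`s for the gene
#'   membership counts (non-retained signatures are ignored).
#' @return object of class `hit_summary`.
#' @export
hit_matrix <- function(records, signatures = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  arms <- sort(unique(records$arm_id))
  drugs <- sort(unique(records$drug_id))
  rges_m <- matrix(NA_real_, length(drugs), length(arms),
                   dimnames = list(drugs, arms))
  all_rges <- rges_m
  for (i in seq_len(nrow(records))) {
    d <- records$drug_id[i]; a <- records$arm_id[i]
    all_rges[d, a] <- records$rges[i]
    if (isTRUE(records$hit[i])) rges_m[d, a] <- records$rges[i]
  }
  hit_counts <- rowSums(!is.na(rges_m))
  gene_counts <- integer()
  if (!is.null(signatures)) {
    kept <- Filter(function(s) isTRUE(s$retained), signatures)
    if (length(kept)) {
      tab <- table(unlist(lapply(kept, function(s) s$genes$gene_id)))
      gene_counts <- stats::setNames(as.integer(tab), names(tab))
    }
  }
  structure(list(arms = arms, drugs = drugs, rges_matrix = rges_m,
                 all_rges = all_rges, hit_counts = hit_counts,
                 gene_counts = gene_counts),
            class = "hit_summary")
}

#' Drugs recurring as hits across arms
#'
#' @param summary a `hit_summary`.
#' @param min_arms minimum number of arms where the drug is a hit.
#' @return data.frame (`drug_id`, `n_arms_hit`, `mean_rges`) sorted by hit
#'   count descending, then mean RGES ascending, then drug id.
#' @export
recurrent_hits <- function(summary, min_arms = 1L) {
  stopifnot(inherits(summary, "hit_summary"), min_arms >= 1)
  keep <- names(summary$hit_counts)[summary$hit_counts >= min_arms]
  mean_rges <- vapply(keep, function(d) {
    mean(summary$rges_matrix[d, ], na.rm = TRUE)
  }, 0)
  out <- data.frame(drug_id = keep,
                    n_arms_hit = unname(summary$hit_counts[keep]),
                    mean_rges = unname(mean_rges),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_arms_hit, out$mean_rges, out$drug_id,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Genes recurring across retained signatures
#'
#' @param summary a `hit_summary` built with `signatures`.
#' @param min_profiles minimum number of signatures containing the gene.
#' @return data.frame (`gene_id`, `n_profiles`) sorted by count descending
#'   then gene id.
#' @export
recurrent_genes <- function(summary, min_profiles = 1L) {
  stopifnot(inherits(summary, "hit_summary"), min_profiles >= 1)
  gc <- summary$gene_counts
  if (!length(gc))
    return(data.frame(gene_id = character(), n_profiles = integer(),
                      stringsAsFactors = FALSE))
  keep <- names(gc)[gc >= min_profiles]
  out <- data.frame(gene_id = keep, n_profiles = unname(gc[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_profiles, out$gene_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}
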