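#' Normalize a log2 expression matrix to its 75th percentile
#'
#' Per sample, subtract the sample's 75th percentile (linear interpolation
#' between order statistics) and add a fixed 9.5 so values stay positive;
#' afterwards every sample column has 75th percentile exactly 9.5. The
#' operation is idempotent.
#'
#' @param expr numeric genes x samples matrix, log2 scale.
#' @return matrix of the same shape.
#' @export
normalize_array <- function(expr) {
  if (!is.matrix(expr) || nrow(expr) == 0L || ncol(expr) == 0L)
    stop("empty expression matrix", call. = FALSE)
  q75 <- apply(expr, 2L, stats::quantile, probs = 0.75, names = FALSE)
  sweep(expr, 2L, q75 - 9.5)
}

#' Stratify a cohort into (treatment, subtype) arms with response labels
#'
#' Samples are labeled sensitive (RCB 0 or I) or resistant (RCB III); RCB
#' II and missing-RCB samples are excluded before counting. Arms with fewer
#' than `min_per_group` samples in either group are dropped, with the
#' reason recorded in the `dropped` attribute.
#'
#' @param expr normalized expression matrix.
#' @param ann annotation data.frame (see [read_annotations()]).
#' @param min_per_group minimum samples per response group (default 3).
#' @return named list of `arm_cohort` objects; attribute `dropped` is a
#'   data.frame of excluded arms and reasons.
#' @export
stratify_arms <- function(expr, ann, min_per_group = 3L) {
  validate_expression(expr)
  unknown <- setdiff(ann$sample_id, colnames(expr))
  if (length(unknown))
    warning(sprintf("%d annotated sample(s) absent from the expression matrix: %s",
                    length(unknown), paste(utils::head(unknown, 5L), collapse = ", ")))
  ann <- ann[ann$sample_id %in% colnames(expr), , drop = FALSE]
  label <- ifelse(ann$rcb_class %in% c("0", "I"), "sensitive",
                  ifelse(ann$rcb_class == "III", "resistant", NA))
  keep <- !is.na(label)
  ann <- ann[keep, , drop = FALSE]
  label <- label[keep]
  subtype <- paste0("HR", ifelse(ann$hr_status == "positive", "+", "-"),
                    "HER2", ifelse(ann$her2_status == "positive", "+", "-"))
  id <- arm_id(ann$treatment, subtype)

  arms <- list()
  dropped <- data.frame(arm_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (a in unique(id)) {
    sel <- id == a
    labs <- stats::setNames(label[sel], ann$sample_id[sel])
    n_s <- sum(labs == "sensitive"); n_r <- sum(labs == "resistant")
    if (n_s < min_per_group || n_r < min_per_group) {
      dropped <- rbind(dropped, data.frame(
        arm_id = a, reason = "min-samples", stringsAsFactors = FALSE))
      next
    }
    arms[[a]] <- structure(
      list(arm_id = a,
           treatment = ann$treatment[sel][1L],
           subtype = subtype[sel][1L],
           sample_ids = names(labs),
           labels = labs,
           expression = expr[, names(labs), drop = FALSE]),
      class = "arm_cohort")
  }
  if (!length(arms))
    stop(paste("no arm satisfies the minimum group sizes;",
               "check RCB labeling and sample counts"), call. = FALSE)
  attr(arms, "dropped") <- dropped
  arms
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; if any factor of
#' the denominator is zero the MCC is defined as 0.
#'
#' @param tp,fp,fn,tn non-negative confusion counts.
#' @return MCC in `[-1, 1]`.
#' @export
matthews_cc <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fp + fn + tn == 0) stop("all confusion counts are zero", call. = FALSE)
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

# MCC between cluster assignment (integer 1/2) and labels, maximized over
# the two cluster -> {sensitive, resistant} mappings (swapping the
# predicted classes flips the MCC sign, so this is |MCC| unless a zero
# denominator forces 0).
cluster_label_mcc <- function(cluster, labels) {
  act_res <- labels == "resistant"
  pred_res <- cluster == 1L
  m1 <- matthews_cc(tp = sum(pred_res & act_res),
                    fp = sum(pred_res & !act_res),
                    fn = sum(!pred_res & act_res),
                    tn = sum(!pred_res & !act_res))
  max(m1, -m1)
}

#' Select the log2 fold-change cutoff maximizing cluster/label agreement
#'
#' Iterates over cutoffs 1.0, 0.9, ..., 0.0. At each cutoff the genes with
#' `p < p_threshold` and `|log2fc| >= cutoff` define a feature space
#' (per-gene standardized); k-means (k = 2, 25 restarts, seeded) clusters
#' the arm's samples there, clusters are mapped to sensitive/resistant by
#' the assignment with the larger MCC, and the cutoff with the highest MCC
#' wins (ties go to the larger cutoff, i.e. the smaller signature).
#'
#' @param de a `de_result` for the cohort.
#' @param cohort the `arm_cohort` the DE was computed on.
#' @param p_threshold DE p-value filter (default 0.01).
#' @param grid cutoff grid, iterated in the given order.
#' @param nstart k-means restarts.
#' @param seed RNG seed for k-means.
#' @return list with `cutoff`, `mcc`, and a `trace` data.frame
#'   (`cutoff`, `n_genes`, `mcc`; MCC is `NA` where fewer than 2 genes pass).
#' @export
select_lfc_cutoff <- function(de, cohort, p_threshold = 0.01,
                              grid = seq(1, 0, by = -0.1),
                              nstart = 25L, seed = 1L) {
  stopifnot(inherits(de, "de_result"), inherits(cohort, "arm_cohort"))
  X <- cohort$expression
  labels <- cohort$labels[colnames(X)]
  trace <- data.frame(cutoff = grid, n_genes = NA_integer_, mcc = NA_real_)
  for (i in seq_along(grid)) {
    pass <- de$p < p_threshold & abs(de$log2fc) >= grid[i]
    trace$n_genes[i] <- sum(pass)
    if (sum(pass) < 2L) next
    feat <- X[de$gene_id[pass], , drop = FALSE]
    sds <- apply(feat, 1L, stats::sd)
    feat <- (feat - rowMeans(feat)) / ifelse(sds == 0, 1, sds)
    km <- with_seed_offset(seed, 0,
      stats::kmeans(t(feat), centers = 2L, nstart = nstart))
    trace$mcc[i] <- cluster_label_mcc(km$cluster, labels)
  }
  if (all(is.na(trace$mcc)))
    stop("no usable signature: no cutoff retains at least 2 genes", call. = FALSE)
  best <- which.max(trace$mcc)  # first max in grid order = larger cutoff on ties
  list(cutoff = grid[best], mcc = trace$mcc[best], trace = trace)
}

#' Assemble a resistance signature at a chosen cutoff
#'
#' Members are genes with `p < p_threshold` and `|log2fc| >= cutoff`; genes
#' with log2fc exactly 0 are excluded (a signature gene needs a direction).
#' Up-genes are up-regulated in resistant tumors. The signature is retained
#' for downstream scoring only when it holds more than `min_genes` members.
#'
#' @inheritParams select_lfc_cutoff
#' @param cutoff chosen log2FC cutoff.
#' @param arm_id arm identifier carried through the pipeline.
#' @param mcc MCC achieved at `cutoff` (optional, stored).
#' @param min_genes retention threshold (strict: default keeps > 50).
#' @return object of class `signature_profile`.
#' @export
build_signature <- function(de, cutoff, arm_id, mcc = NA_real_,
                            p_threshold = 0.01, min_genes = 50L) {
  stopifnot(inherits(de, "de_result"))
  pass <- de$p < p_threshold & abs(de$log2fc) >= cutoff & de$log2fc != 0
  genes <- de[pass, c("gene_id", "log2fc", "p")]
  structure(list(
    arm_id = arm_id,
    genes = genes,
    chosen_cutoff = cutoff,
    mcc_at_cutoff = mcc,
    up_genes = genes$gene_id[genes$log2fc > 0],
    down_genes = genes$gene_id[genes$log2fc < 0],
    retained = nrow(genes) > min_genes
  ), class = "signature_profile")
}

#' Construct a signature profile from explicit up/down gene sets
#'
#' Direct constructor for signatures defined outside the DE path (e.g.
#' externally curated or randomly drawn gene sets). Directions are encoded
#' as log2fc +1/-1 unless explicit values are supplied.
#'
#' @param arm_id identifier carried into downstream records.
#' @param up,down disjoint character vectors of up-/down-genes.
#' @param log2fc optional named numeric log2 fold changes for the members.
#' @param min_genes retention threshold (strict).
#' @return `signature_profile`.
#' @export
signature_profile <- function(arm_id, up, down, log2fc = NULL,
                              min_genes = 50L) {
  stopifnot(length(up) >= 1, length(down) >= 1,
            !anyDuplicated(c(up, down)))
  lfc <- if (is.null(log2fc))
    stats::setNames(rep(c(1, -1), c(length(up), length(down))), c(up, down))
  else log2fc[c(up, down)]
  genes <- data.frame(gene_id = c(up, down), log2fc = unname(lfc),
                      p = NA_real_, stringsAsFactors = FALSE)
  structure(list(arm_id = arm_id, genes = genes,
                 chosen_cutoff = NA_real_, mcc_at_cutoff = NA_real_,
                 up_genes = up, down_genes = down,
                 retained = nrow(genes) > min_genes),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("<signature_profile> arm %s: %d genes (%d up / %d down), cutoff %.1f, MCC %.3f, retained: %s\n",
              x$arm_id, nrow(x$genes), length(x$up_genes),
              length(x$down_genes), x$chosen_cutoff, x$mcc_at_cutoff,
              x$retained))
  invisible(x)
}
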