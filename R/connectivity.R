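#' Signed KS tag-enrichment of a gene set in a ranked profile
#'
#' Bidirectional Kolmogorov-Smirnov statistic in the classic connectivity-
#' mapping form: for ascending tag positions `V(1..t)` in a universe of
#' `n` ranks, `a = max_j [j/t - V(j)/n]`, `b = max_j [V(j)/n - (j-1)/t]`,
#' and `es = a` if `a > b`, else `-b`. Positive scores mean the tags
#' concentrate at the top of the ranking (most up-regulated), negative at
#' the bottom.
#'
#' @param positions ascending integer ranks of the tag genes.
#' @param n universe size (number of ranked genes).
#' @return list with `es`, `t` (tag count), `n`.
#' @export
ks_enrichment <- function(positions, n) {
  t <- length(positions)
  if (t == 0L) stop("no tags in universe", call. = FALSE)
  if (is.unsorted(positions, strictly = TRUE) ||
      positions[1L] < 1L || positions[t] > n)
    stop("positions must be strictly ascending ranks within 1..n", call. = FALSE)
  j <- seq_len(t)
  a <- max(j / t - positions / n)
  b <- max(positions / n - (j - 1) / t)
  list(es = if (a > b) a else -b, t = t, n = n)
}

# Bare combination rule: a coherent reversal (or mimicry) needs the two
# sets displaced in opposite directions; same-sign displacement scores 0.
combine_rges <- function(ks_up, ks_down) {
  if (ks_up * ks_down <= 0) ks_up - ks_down else 0
}

#' Reverse gene expression score of one drug against a signature
#'
#' KS tag-enrichment of the signature's up- and down-genes in the drug's
#' ranking, combined as `rges = ks_up - ks_down` when the two scores have
#' opposite signs (or either is zero), else 0. Negative RGES means the drug
#' pushes resistance-up genes to the bottom of its ranking and
#' resistance-down genes to the top: reversal.
#'
#' @param up,down character vectors of signature genes (disjoint).
#' @param ranks named integer rank vector for one drug (rank 1 = most
#'   up-regulated by the drug).
#' @return list with `ks_up`, `ks_down`, `rges`, and the tag counts used.
#' @export
rges_score <- function(up, down, ranks) {
  stopifnot(!is.null(names(ranks)))
  if (length(intersect(up, down)))
    stop("up and down sets must be disjoint", call. = FALSE)
  pos_up <- sort.int(unname(ranks[names(ranks) %in% up]))
  pos_dn <- sort.int(unname(ranks[names(ranks) %in% down]))
  if (!length(pos_up) || !length(pos_dn))
    stop("up or down set empty after intersection with profile universe",
         call. = FALSE)
  n <- length(ranks)
  ku <- ks_enrichment(pos_up, n)$es
  kd <- ks_enrichment(pos_dn, n)$es
  list(ks_up = ku, ks_down = kd, rges = combine_rges(ku, kd),
       n_up = length(pos_up), n_down = length(pos_dn))
}

# Shared permutation null: RGES of random disjoint up/down sets of fixed
# sizes against a fixed reference ranking. Random sets on a fixed ranking
# are distributionally identical to fixed sets on a random ranking, so one
# null serves every drug scored against the same signature.
rges_null <- function(up_size, down_size, n, n_perm, seed) {
  stopifnot(up_size >= 1, down_size >= 1)
  if (up_size + down_size > n)
    stop("up_size + down_size exceeds the universe", call. = FALSE)
  if (n_perm < 1000L) stop("n_perm < 1000 gives an unstable null", call. = FALSE)
  iu <- seq_len(up_size)
  with_seed_offset(seed, 0, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n, up_size + down_size)
      ku <- ks_enrichment(sort.int(idx[iu]), n)$es
      kd <- ks_enrichment(sort.int(idx[-iu]), n)$es
      combine_rges(ku, kd)
    }, 0)
  })
}

#' Permutation p-values for observed RGES scores
#'
#' One-sided (left-tail, reversal) permutation test:
#' `p = (1 + #\{null <= observed\}) / (1 + n_perm)`, with the null built
#' once from `n_perm` random disjoint up/down sets of the signature's sizes
#' over the profile universe. `alternative = "two.sided"` doubles the
#' smaller tail, capped at 1.
#'
#' @param up_size,down_size signature set sizes after universe intersection.
#' @param universe character vector (or size) of the profile gene universe.
#' @param observed numeric vector of observed RGES values.
#' @param n_perm number of null draws (>= 1000).
#' @param seed RNG seed.
#' @param alternative `"less"` (reversal, default) or `"two.sided"`.
#' @return numeric p-values with floor `1/(n_perm + 1)`.
#' @export
permutation_pvalues <- function(up_size, down_size, universe, observed,
                                n_perm = 10000L, seed = 1L,
                                alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- if (is.numeric(universe) && length(universe) == 1L) universe else
    length(universe)
  null <- rges_null(up_size, down_size, n, n_perm, seed)
  sn <- sort.int(null)
  lo <- (1 + findInterval(observed, sn)) / (1 + n_perm)
  if (alternative == "less") return(lo)
  hi <- (1 + (n_perm - findInterval(observed, sn, left.open = TRUE))) /
    (1 + n_perm)
  pmin(1, 2 * pmin(lo, hi))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment (via [stats::p.adjust()]), order-preserving with
#' the input.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Score a drug compendium for reversal of one signature
#'
#' Every drug gets a KS up/down enrichment and RGES; the shared permutation
#' null gives one-sided p-values, BH-corrected across drugs; hits are drugs
#' with `q < q_threshold` and `rges < 0`. Signature genes absent from the
#' profile universe are dropped (counts reported via message).
#'
#' @param sig retained `signature_profile`.
#' @param drugs `drug_profiles` compendium.
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @param q_threshold hit FDR threshold (default 0.05).
#' @return data.frame of class `rges_records`, sorted by RGES ascending:
#'   `arm_id`, `drug_id`, `ks_up`, `ks_down`, `rges`, `p`, `q`, `hit`.
#' @export
score_compendium <- function(sig, drugs, n_perm = 10000L, seed = 1L,
                             q_threshold = 0.05) {
  stopifnot(inherits(sig, "signature_profile"), inherits(drugs, "drug_profiles"))
  if (!isTRUE(sig$retained))
    stop(sprintf("signature %s is not retained (<= min_genes members)",
                 sig$arm_id), call. = FALSE)
  universe <- rownames(drugs$ranks)
  up <- intersect(sig$up_genes, universe)
  down <- intersect(sig$down_genes, universe)
  lost <- (length(sig$up_genes) - length(up)) +
    (length(sig$down_genes) - length(down))
  if (!length(up) || !length(down))
    stop(sprintf("signature %s: up or down set entirely absent from the profile universe",
                 sig$arm_id), call. = FALSE)
  if (lost > 0)
    message(sprintf("signature %s: %d gene(s) absent from the profile universe dropped",
                    sig$arm_id, lost))
  n <- length(universe)
  drug_ids <- colnames(drugs$ranks)
  scores <- lapply(drug_ids, function(d) {
    rges_score(up, down, drugs$ranks[, d])
  })
  rges <- vapply(scores, `[[`, 0, "rges")
  p <- permutation_pvalues(length(up), length(down), n, rges,
                           n_perm = n_perm, seed = seed)
  q <- bh_fdr(p)
  out <- data.frame(
    arm_id = sig$arm_id, drug_id = drug_ids,
    ks_up = vapply(scores, `[[`, 0, "ks_up"),
    ks_down = vapply(scores, `[[`, 0, "ks_down"),
    rges = rges, p = p, q = q,
    hit = q < q_threshold & rges < 0,
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rges, out$drug_id, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("rges_records", "data.frame")
  out
}
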