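#' Weighted KS enrichment score with running sum
#'
#' Classic weighted GSEA running statistic over a ranked list: at member
#' positions the sum increments by `|stat|^weight_p / N_R` (`N_R` = sum of
#' `|stat|^weight_p` over members present) and elsewhere decrements by
#' `1/(N - n_members)`. The enrichment score is the running-sum value of
#' maximal absolute deviation from zero.
#'
#' @param ranked named numeric vector of stats, sorted descending.
#' @param members character vector of member gene ids.
#' @param weight_p stat weighting exponent (1 = classic weighted GSEA).
#' @return list with `es` and the full `running` curve (length N).
#' @export
gsea_es <- function(ranked, members, weight_p = 1) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  if (is.unsorted(rev(ranked))) stop("ranked stats must be sorted descending",
                                     call. = FALSE)
  hit <- names(ranked) %in% members
  if (!any(hit)) stop("empty intersection: no member in ranked universe",
                      call. = FALSE)
  N <- length(ranked)
  t <- sum(hit)
  w <- abs(ranked)^weight_p
  nr <- sum(w[hit])
  inc <- numeric(N)
  if (nr == 0) inc[hit] <- 1 / t else inc[hit] <- w[hit] / nr
  if (t < N) inc[!hit] <- -1 / (N - t)
  running <- cumsum(inc)
  # degenerate composition (every gene a member): the sum never decrements
  # and the score is taken at the first position
  es <- if (t == N) running[1L] else running[which.max(abs(running))]
  list(es = es, running = running)
}

# Enrichment score from member positions only, O(t): deviation extrema can
# only occur at a member position (maximum) or just before one (minimum).
# Mirrors gsea_es() exactly; used for the permutation null.
es_from_positions <- function(pos, w_at_pos, N, miss_dec) {
  t <- length(pos)
  w_at_pos <- unname(w_at_pos)
  nr <- sum(w_at_pos)
  cumw <- if (nr == 0) seq_len(t) / t else cumsum(w_at_pos) / nr
  if (t == N) return(cumw[1L])
  gaps <- (pos - seq_len(t)) * miss_dec
  after <- cumw - gaps          # running value at each member position
  before <- c(0, cumw[-t]) - gaps  # value just before each member
  cand <- c(after, before, after[t] - (N - pos[t]) * miss_dec)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment with a random-set permutation null
#'
#' Genes are ranked by log2 fold change (descending; ties broken by gene
#' id). Per set, the enrichment score is normalized by the mean of the
#' same-sign null scores from `n_perm` random gene sets of the same size,
#' giving the NES; the permutation p-value is sign-stratified and BH-
#' corrected across sets.
#'
#' @param de a `de_result` (ranking source), or a named numeric vector of
#'   per-gene stats.
#' @param sets a `gene_set_collection` (named list of gene id vectors).
#' @param n_perm permutation count (>= 100).
#' @param seed RNG seed for the null draws.
#' @param weight_p stat weighting exponent.
#' @return data.frame of class `enrichment_result` with columns `set`,
#'   `size_used`, `es`, `nes`, `p`, `q`.
#' @export
gsea_preranked <- function(de, sets, n_perm = 2000L, seed = 1L, weight_p = 1) {
  if (n_perm < 100L) stop("n_perm < 100 gives an unstable null", call. = FALSE)
  if (inherits(de, "de_result")) {
    stats_vec <- stats::setNames(de$log2fc, de$gene_id)
  } else {
    stopifnot(is.numeric(de), !is.null(names(de)))
    stats_vec <- de
  }
  ord <- order_desc_stat(stats_vec, names(stats_vec))
  ranked <- stats_vec[ord]
  N <- length(ranked)
  w_all <- abs(ranked)^weight_p

  size_used <- vapply(sets, function(s) sum(names(ranked) %in% s), 0L)
  es <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    if (size_used[i] > 0L) es[i] <- gsea_es(ranked, sets[[i]], weight_p)$es
  }

  # Null ES per distinct set size, shared across sets of that size.
  null_by_size <- list()
  with_seed_offset(seed, 0, {
    for (s in sort(unique(size_used[size_used > 0L]))) {
      miss_dec <- if (s < N) 1 / (N - s) else 0
      null_by_size[[as.character(s)]] <- vapply(seq_len(n_perm), function(b) {
        pos <- sort.int(sample.int(N, s))
        es_from_positions(pos, w_all[pos], N, miss_dec)
      }, 0)
    }
  })

  nes <- rep(NA_real_, length(sets))
  p <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    if (is.na(es[i])) next
    null <- null_by_size[[as.character(size_used[i])]]
    same <- if (es[i] >= 0) null[null >= 0] else null[null < 0]
    nes[i] <- if (length(same)) es[i] / abs(mean(same)) else NA_real_
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }
  q <- rep(NA_real_, length(sets))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])

  out <- data.frame(set = names(sets), size_used = size_used, es = es,
                    nes = nes, p = p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
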