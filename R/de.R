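#' Moderated two-group differential expression
#'
#' Empirical-Bayes moderated t-test of resistant versus sensitive samples
#' within one arm. Per gene, the log2 fold change is
#' `mean(resistant) - mean(sensitive)` and the pooled residual variance
#' `s2` has `df = n - 2` degrees of freedom. The prior degrees of freedom
#' `d0` and prior variance `s0sq` are estimated by method of moments on
#' `log(s2)` (digamma/trigamma matching); the posterior variance is
#' `(d0*s0sq + df*s2) / (d0 + df)` (limit `s0sq` when `d0` is infinite),
#' and the moderated t is referenced to a t distribution on `d0 + df`
#' degrees of freedom. `method = "pooled"` gives the ordinary pooled-
#' variance t-test instead.
#'
#' @param cohort an `arm_cohort` from [stratify_arms()].
#' @param method `"moderated"` (default) or `"pooled"`.
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `log2fc`, `s2`, `df`, `t_mod`, `p`, and attributes `d0`, `s0sq`,
#'   `n_sens`, `n_res`.
#' @export
moderated_de <- function(cohort, method = c("moderated", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "arm_cohort"))
  X <- cohort$expression
  is_res <- cohort$labels[colnames(X)] == "resistant"
  ns <- sum(!is_res); nr <- sum(is_res)
  stopifnot(ns >= 2, nr >= 2)
  Xs <- X[, !is_res, drop = FALSE]
  Xr <- X[, is_res, drop = FALSE]
  ms <- rowMeans(Xs); mr <- rowMeans(Xr)
  lfc <- mr - ms
  df <- ns + nr - 2
  s2 <- (rowSums((Xs - ms)^2) + rowSums((Xr - mr)^2)) / df
  se_factor <- sqrt(1 / ns + 1 / nr)

  if (method == "pooled") {
    d0 <- 0; s0sq <- NA_real_
    s2post <- s2
    df_total <- df
  } else {
    hp <- fit_f_dist(s2, df)
    d0 <- hp$d0; s0sq <- hp$s0sq
    s2post <- if (is.finite(d0)) (d0 * s0sq + df * s2) / (d0 + df) else
      rep(s0sq, length(s2))
    df_total <- if (is.finite(d0)) d0 + df else Inf
  }

  denom <- sqrt(s2post) * se_factor
  t_mod <- ifelse(denom == 0 & lfc == 0, 0, lfc / denom)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[denom == 0 & lfc == 0] <- 1

  out <- data.frame(gene_id = rownames(X), log2fc = lfc, s2 = s2,
                    df = df, t_mod = t_mod, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  attr(out, "n_sens") <- ns
  attr(out, "n_res") <- nr
  attr(out, "method") <- method
  class(out) <- c("de_result", "data.frame")
  out
}

# Method-of-moments fit of the scaled-F prior for gene variances:
# log(s2) ~ log(s0sq) + log F(df, d0) up to constants, so matching the mean
# and variance of e = log(s2) - digamma(df/2) + log(df/2) against
# digamma/trigamma identities yields (d0, s0sq). Genes with s2 == 0 are
# excluded from moment estimation but still shrunk.
fit_f_dist <- function(s2, df) {
  z <- log(s2[is.finite(s2) & s2 > 0])
  if (length(z) < 2) return(list(d0 = Inf, s0sq = mean(s2)))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

# Newton inversion of trigamma on (0, Inf); monotone decreasing, so the
# iteration from 0.5 + 1/x converges in a handful of steps.
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}
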