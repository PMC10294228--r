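# Shared fixtures and independent oracles for the test suite.

# Brute-force signed KS tag-enrichment oracle: scans the two one-sided
# sup-differences between the tag empirical CDF and the uniform reference
# CDF over every position of the ranked universe. Independent of the
# closed-form maxima used by ks_enrichment().
ks_bruteforce <- function(positions, n) {
  t <- length(positions)
  Ft <- vapply(0:n, function(i) sum(positions <= i) / t, 0)  # Ft[i+1] = F(i)
  i <- seq_len(n)
  a <- max(Ft[i + 1L] - i / n)
  b <- max(i / n - Ft[i])
  if (a > b) a else -b
}

# Hand-built arm cohort from an expression matrix and a label vector.
make_arm <- function(expr, labels, arm = "test|HR+HER2-") {
  stopifnot(ncol(expr) == length(labels))
  labels <- stats::setNames(labels, colnames(expr))
  structure(list(arm_id = arm, treatment = "test", subtype = "HR+HER2-",
                 sample_ids = colnames(expr), labels = labels,
                 expression = expr),
            class = "arm_cohort")
}

# Two-group Gaussian expression fixture: n_genes background genes plus a
# planted block shifted by +/- effect in the second group.
make_two_group <- function(n_genes, n1, n2, effect = 0, n_planted = 0,
                           noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_genes * (n1 + n2), 9.5, noise_sd), n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n1 + n2))))
    if (n_planted > 0) {
      up <- seq_len(ceiling(n_planted / 2))
      dn <- seq(ceiling(n_planted / 2) + 1, n_planted)
      grp2 <- (n1 + 1):(n1 + n2)
      X[up, grp2] <- X[up, grp2] + effect
      X[dn, grp2] <- X[dn, grp2] - effect
    }
    X
  })
}

# Random up/down signature over a gene universe.
random_signature <- function(genes, n_up = 50, n_down = 50, seed = 1) {
  withr::with_seed(seed, {
    idx <- sample(genes, n_up + n_down)
    signature_profile("random", up = idx[seq_len(n_up)],
                      down = idx[-seq_len(n_up)])
  })
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
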