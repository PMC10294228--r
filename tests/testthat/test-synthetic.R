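test_that("generation is a pure function of the seed", {
  cfg <- sim_config(n_genes = 400L, n_signature_genes = 40L,
                    n_drugs = 10L, seed = 33L)
  s1 <- gen_cohort(cfg)
  s2 <- gen_cohort(cfg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth, s2$truth)
  a <- names(s1$truth$arms)[1]
  expect_identical(gen_drug_profiles(cfg, s1$truth, a)$ranks,
                   gen_drug_profiles(cfg, s2$truth, a)$ranks)
  expect_identical(unclass(gen_gene_sets(cfg, s1$truth)),
                   unclass(gen_gene_sets(cfg, s2$truth)))
})

test_that("planted sets are disjoint, in-universe, and the compendium draw does not perturb the cohort", {
  cfg <- sim_config(n_genes = 400L, n_signature_genes = 50L,
                    n_drugs = 5L, seed = 2L)
  sim <- gen_cohort(cfg)
  tr <- sim$truth$arms[[1]]
  expect_length(intersect(tr$up, tr$down), 0)
  expect_true(all(c(tr$up, tr$down) %in% rownames(sim$expression)))
  expect_identical(sum(sim$truth$drug_roles == "reverser"), 1L)
  expect_identical(sum(sim$truth$drug_roles == "mimicker"), 1L)

  cfg_more_drugs <- sim_config(n_genes = 400L, n_signature_genes = 50L,
                               n_drugs = 50L, seed = 2L)
  expect_identical(gen_cohort(cfg_more_drugs)$expression, sim$expression)

  expect_error(gen_cohort(sim_config(n_genes = 10L, n_signature_genes = 20L)),
               "n_signature_genes")
  expect_error(gen_drug_profiles(cfg, sim$truth, "nope|arm"), "unknown arm")
})

test_that("planted effect sizes are recovered empirically at stated accuracy", {
  cfg <- sim_config(n_genes = 2000L, effect_size = 3, noise_sd = 0.5, seed = 5L)
  sim <- gen_cohort(cfg)
  ann <- sim$annotations
  res <- ann$sample_id[ann$rcb_class == "III"]
  sens <- ann$sample_id[ann$rcb_class %in% c("0", "I")]
  lfc <- rowMeans(sim$expression[, res]) - rowMeans(sim$expression[, sens])
  tr <- sim$truth$arms[[1]]
  hits <- c(abs(lfc[tr$up] - 3) <= 0.5, abs(lfc[tr$down] + 3) <= 0.5)
  expect_gte(mean(hits), 0.95)
})

test_that("fidelity-1 reverser owns the extreme ranks; fidelity-0 reverser is a random drug", {
  cfg <- sim_config(n_genes = 500L, n_signature_genes = 40L, n_drugs = 5L,
                    reverser_fidelity = 1, seed = 8L)
  sim <- gen_cohort(cfg)
  a <- names(sim$truth$arms)[1]
  dp <- gen_drug_profiles(cfg, sim$truth, a)
  up <- sim$truth$arms[[a]]$up
  dn <- sim$truth$arms[[a]]$down
  n <- nrow(dp$ranks)
  expect_setequal(dp$ranks[up, "reverser"], (n - length(up) + 1):n)
  expect_setequal(dp$ranks[dn, "reverser"], seq_along(dn))
  expect_setequal(dp$ranks[up, "mimicker"], seq_along(up))

  # With fidelity 0 the reverser's stats are indistinguishable from a
  # random drug's (two-sample KS p > 0.01 in >= 95% of replicates).
  ps <- vapply(1:100, function(s) {
    cfg0 <- sim_config(n_genes = 500L, n_signature_genes = 40L, n_drugs = 5L,
                       reverser_fidelity = 0, seed = s)
    tr <- gen_cohort(cfg0)$truth
    d <- gen_drug_profiles(cfg0, tr, names(tr$arms)[1])
    suppressWarnings(stats::ks.test(d$stat[, "reverser"],
                                    d$stat[, "rnd001"])$p.value)
  }, 0)
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("generated gene-set collections contain planted and size-matched random sets", {
  cfg <- sim_config(n_genes = 400L, n_signature_genes = 40L, seed = 6L)
  sim <- gen_cohort(cfg)
  sets <- gen_gene_sets(cfg, sim$truth, n_random = 7L)
  expect_identical(names(sets)[1:2], c("planted_up", "planted_down"))
  expect_length(sets, 9L)
  expect_identical(sets$planted_up, sim$truth$arms[[1]]$up)
  rnd <- sets[grepl("^random", names(sets))]
  expect_true(all(lengths(rnd) == length(sets$planted_up)))
  expect_true(all(vapply(rnd, anyDuplicated, 0L) == 0L))
})
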