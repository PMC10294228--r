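test_that("KS tag-enrichment matches hand-evaluated maxima", {
  expect_equal(ks_enrichment(c(1L, 2L), 10)$es, 0.8)
  expect_equal(ks_enrichment(c(9L, 10L), 10)$es, -0.9)
  expect_equal(ks_enrichment(1:10, 10)$es, -1 / 10)  # every gene tagged
  expect_error(ks_enrichment(integer(), 10), "no tags")
  expect_error(ks_enrichment(c(3L, 2L), 10), "ascending")
  expect_error(ks_enrichment(c(0L, 2L), 10), "ascending")
})

test_that("KS tag-enrichment equals the brute-force sup-difference oracle", {
  withr::with_seed(41, {
    for (rep in 1:200) {
      n <- sample(5:50, 1)
      t <- sample.int(n, 1)
      pos <- sort(sample.int(n, t))
      expect_equal(ks_enrichment(pos, n)$es, ks_bruteforce(pos, n))
    }
  })
})

test_that("RGES combines opposite-signed displacements and zeroes same-signed ones", {
  expect_equal(revsig:::combine_rges(-0.8, 0.9), -1.7)   # reversal
  expect_equal(revsig:::combine_rges(0.8, -0.9), 1.7)    # mimicry
  expect_equal(revsig:::combine_rges(0.5, 0.3), 0)       # same sign
  expect_equal(revsig:::combine_rges(0, 0.4), -0.4)      # zero counts as either

  # constructed drug: up-genes at the bottom, down-genes at the top
  genes <- sprintf("g%02d", 1:20)
  ranks <- stats::setNames(1:20, genes)
  sc <- rges_score(up = genes[17:20], down = genes[1:4], ranks)
  expect_lt(sc$ks_up, 0); expect_gt(sc$ks_down, 0)
  expect_equal(sc$rges, sc$ks_up - sc$ks_down)
  expect_lte(sc$rges, -2 + 2 * (4 + 4) / 20)
  expect_error(rges_score(genes[1:2], genes[2:3], ranks), "disjoint")
  expect_error(rges_score(c("zz1", "zz2"), genes[1:4], ranks), "empty")
})

test_that("rank reversal turns a reverser into a mimicker within discreteness slack", {
  genes <- sprintf("g%03d", 1:200)
  up <- genes[191:200]; down <- genes[1:10]
  fwd <- stats::setNames(1:200, genes)
  rev_ranks <- stats::setNames(201L - fwd, genes)
  r_fwd <- rges_score(up, down, fwd)$rges
  r_rev <- rges_score(up, down, rev_ranks)$rges
  expect_lt(r_fwd, 0); expect_gt(r_rev, 0)
  expect_lte(abs(r_rev + r_fwd), 2 * (10 / 200 + 1 / 200))
})

test_that("Benjamini-Hochberg adjustment matches hand-applied step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_fdr(numeric()), numeric())
  p <- c(0.04, 0.001, 0.9)
  expect_identical(order(bh_fdr(p)), order(p))  # order-preserving
})

test_that("permutation p-values respect the floor and the null mass at zero", {
  p <- permutation_pvalues(10, 10, 500, observed = c(-2, 0, 2),
                           n_perm = 2000L, seed = 43L)
  expect_equal(p[1], 1 / 2001)             # more negative than any null draw
  expect_gte(p[2], 0.5)                    # null mass at <= 0 dominates
  expect_true(all(p > 0 & p <= 1))
  p2 <- permutation_pvalues(10, 10, 500, observed = -2, n_perm = 2000L,
                            seed = 43L, alternative = "two.sided")
  expect_equal(p2, 2 / 2001)
  expect_error(permutation_pvalues(300, 300, 500, 0, n_perm = 2000L),
               "exceeds")
  expect_error(permutation_pvalues(10, 10, 500, 0, n_perm = 500L), "unstable")
})

test_that("compendium scoring ranks the planted reverser first and flags it", {
  cfg <- sim_config(n_genes = 1000L, n_signature_genes = 60L, n_drugs = 50L,
                    seed = 47L)
  sim <- gen_cohort(cfg)
  a <- names(sim$truth$arms)[1]
  sig <- signature_profile(a, up = sim$truth$arms[[a]]$up,
                           down = sim$truth$arms[[a]]$down)
  drugs <- gen_drug_profiles(cfg, sim$truth, a)
  rec <- score_compendium(sig, drugs, n_perm = 2000L, seed = 47L)
  expect_identical(rec$drug_id[1], "reverser")
  expect_true(rec$hit[1])
  expect_gte(rec$rges[rec$drug_id == "mimicker"], 0)
  expect_false(rec$hit[rec$drug_id == "mimicker"])
  expect_true(all(rec$rges >= -2 & rec$rges <= 2))
  expect_true(all(rec$hit == (rec$q < 0.05 & rec$rges < 0)))
  expect_lte(rec$rges[1], -2 + 2 * (30 + 30) / 1000)

  sig_small <- signature_profile(a, up = sim$truth$arms[[a]]$up[1:5],
                                 down = sim$truth$arms[[a]]$down[1:5])
  expect_error(score_compendium(sig_small, drugs), "not retained")
  sig_alien <- signature_profile(a, up = sprintf("zz%02d", 1:60),
                                 down = sim$truth$arms[[a]]$down)
  expect_error(score_compendium(sig_alien, drugs), "absent from the profile")
})
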