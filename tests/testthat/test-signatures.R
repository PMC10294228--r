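test_that("75th-percentile normalization has its defining property and is idempotent", {
  one <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(letters[1:4], "s1"))
  n1 <- normalize_array(one)
  expect_equal(unname(quantile(n1[, 1], 0.75)), 9.5)
  expect_equal(n1[, 1], c(a = 1, b = 2, c = 3, d = 4) - 3.25 + 9.5)

  const <- matrix(5, 4, 1, dimnames = list(letters[1:4], "s1"))
  expect_true(all(normalize_array(const) == 9.5))

  two <- cbind(one, s2 = 10 * one[, 1])
  n2 <- normalize_array(two)
  expect_equal(unname(apply(n2, 2, quantile, 0.75)), c(9.5, 9.5))
  expect_equal(normalize_array(n2), n2)  # idempotent

  expect_error(normalize_array(matrix(numeric(), 0, 0)), "empty")
})

test_that("stratification applies the RCB labeling and minimum-size rules", {
  X <- make_two_group(20, 8, 0, seed = 2)
  ann <- data.frame(
    sample_id = colnames(X),
    hr_status = "positive", her2_status = "negative",
    treatment = "pac",
    rcb_class = c("0", "I", "0", "III", "III", "III", "II", "II"),
    stringsAsFactors = FALSE)
  arms <- stratify_arms(X, ann)
  expect_length(arms, 1L)
  expect_identical(sort(unname(arms[[1]]$labels)),
                   rep(c("resistant", "sensitive"), each = 3))
  expect_false(any(c("s007", "s008") %in% arms[[1]]$sample_ids))  # RCB II out

  # 4 sensitive + 2 resistant in a second treatment -> dropped; missing RCB
  # is excluded before counting
  ann2 <- ann
  ann2$treatment <- "other"
  ann2$rcb_class <- c("0", "0", "I", "I", "III", "III", "missing", "III")
  X2 <- X; colnames(X2) <- paste0("o", colnames(X))
  ann2$sample_id <- colnames(X2)
  ann2$rcb_class[8] <- "missing"  # only 2 resistant remain
  both <- stratify_arms(cbind(X, X2), rbind(ann, ann2))
  expect_length(both, 1L)
  expect_identical(attr(both, "dropped")$arm_id, "other|HR+HER2-")
  expect_identical(attr(both, "dropped")$reason, "min-samples")

  expect_error(stratify_arms(X2, ann2), "no arm")
  expect_warning(stratify_arms(X, rbind(ann, data.frame(
    sample_id = "ghost", hr_status = "positive", her2_status = "negative",
    treatment = "pac", rcb_class = "0"))), "absent")
})

test_that("Matthews correlation matches hand-computed values and conventions", {
  expect_equal(matthews_cc(tp = 5, fp = 0, fn = 0, tn = 5), 1)
  expect_equal(matthews_cc(tp = 0, fp = 5, fn = 5, tn = 0), -1)
  expect_equal(matthews_cc(tp = 3, fp = 1, fn = 2, tn = 4), 10 / sqrt(600))
  expect_equal(matthews_cc(tp = 4, fp = 2, fn = 0, tn = 0), 0)  # zero factor
  expect_error(matthews_cc(0, 0, 0, 0), "zero")
})

test_that("cutoff selection walks an 11-point grid and nails a separable cohort", {
  X <- make_two_group(800, 8, 8, effect = 5, n_planted = 60, noise_sd = 0.3,
                      seed = 13)
  arm <- make_arm(X, rep(c("sensitive", "resistant"), each = 8))
  de <- moderated_de(arm)
  sel <- select_lfc_cutoff(de, arm, seed = 13)
  expect_identical(nrow(sel$trace), 11L)
  expect_equal(sel$trace$cutoff, seq(1, 0, by = -0.1))
  expect_equal(sel$mcc, 1.0)
  expect_equal(sel$cutoff, 1.0)  # MCC ties resolve to the larger cutoff

  # MCC is invariant to swapping k-means cluster indices
  labels <- arm$labels
  cl <- ifelse(labels == "resistant", 1L, 2L)
  expect_equal(revsig:::cluster_label_mcc(cl, labels),
               revsig:::cluster_label_mcc(3L - cl, labels))

  de_null <- de
  de_null$p <- rep(0.5, nrow(de))
  class(de_null) <- class(de)
  expect_error(select_lfc_cutoff(de_null, arm, seed = 1), "no usable signature")
})

test_that("signature membership follows the p, cutoff, sign and >50 rules", {
  de <- data.frame(gene_id = sprintf("g%03d", 1:120),
                   log2fc = c(rep(c(1.5, -1.5), 30), rep(0.05, 59), 0),
                   p = c(rep(0.001, 60), rep(0.001, 60)),
                   stringsAsFactors = FALSE)
  class(de) <- c("de_result", "data.frame")
  sig <- build_signature(de, cutoff = 1, arm_id = "a")
  expect_true(sig$retained)
  expect_equal(length(sig$up_genes) + length(sig$down_genes), 60L)
  expect_equal(length(sig$up_genes), 30L)

  # exactly 50 members is not retained (threshold is strict)
  de50 <- de[c(1:50, 61:120), ]
  class(de50) <- c("de_result", "data.frame")
  sig50 <- build_signature(de50, cutoff = 1, arm_id = "a")
  expect_equal(nrow(sig50$genes), 50L)
  expect_false(sig50$retained)

  # log2fc exactly 0 is dropped even at cutoff 0
  sig0 <- build_signature(de, cutoff = 0, arm_id = "a")
  expect_false("g120" %in% sig0$genes$gene_id)
  expect_equal(nrow(sig0$genes), 119L)
})

test_that("planted signatures are recovered with low contamination", {
  cfg <- sim_config(n_genes = 2000L,
                    arms = list(arm_spec("pac", "HR+HER2-", 8L, 8L)),
                    effect_size = 1.5, noise_sd = 0.5, seed = 19L)
  sim <- gen_cohort(cfg)
  arms <- stratify_arms(normalize_array(sim$expression), sim$annotations)
  de <- moderated_de(arms[[1]])
  sel <- select_lfc_cutoff(de, arms[[1]], seed = 19)
  sig <- build_signature(de, sel$cutoff, names(arms)[1], mcc = sel$mcc)
  planted <- unlist(sim$truth$arms[[1]][c("up", "down")])
  expect_gte(mean(planted %in% sig$genes$gene_id), 0.80)
  expect_lte(mean(!(sig$genes$gene_id %in% planted)), 0.05)
  expect_setequal(sig$genes$gene_id, c(sig$up_genes, sig$down_genes))
})

test_that("labeling RCB II samples resistant blurs the cluster separation", {
  # asymmetric groups: the half-shifted RCB II cloud clusters with the
  # (smaller) sensitive group, so labeling it resistant costs agreement
  cfg <- sim_config(n_genes = 1500L,
                    arms = list(arm_spec("pac", "HR+HER2-", 6L, 16L,
                                         n_rcb2 = 8L)),
                    effect_size = 1.5, noise_sd = 0.5, seed = 23L)
  sim <- gen_cohort(cfg)
  expr <- normalize_array(sim$expression)
  arms <- stratify_arms(expr, sim$annotations)
  de_excl <- moderated_de(arms[[1]])
  mcc_excl <- select_lfc_cutoff(de_excl, arms[[1]], seed = 23)$mcc

  ann <- sim$annotations
  keep <- ann$rcb_class %in% c("0", "I", "II", "III")
  labels <- ifelse(ann$rcb_class[keep] %in% c("0", "I"),
                   "sensitive", "resistant")
  arm_incl <- make_arm(expr[, ann$sample_id[keep]], labels)
  de_incl <- moderated_de(arm_incl)
  mcc_incl <- select_lfc_cutoff(de_incl, arm_incl, seed = 23)$mcc
  expect_lt(mcc_incl, mcc_excl)
})
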