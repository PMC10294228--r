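#' Specify one (treatment, subtype) arm of a simulated cohort
#'
#' @param treatment treatment label.
#' @param subtype receptor subtype, e.g. `"HR+HER2-"` or `"HR-HER2-"`.
#' @param n_sensitive,n_resistant samples per response group (RCB 0/I vs III).
#' @param n_rcb2 extra RCB II samples carrying a half-effect shift; these are
#'   excluded by the stratifier under the default labeling rule.
#' @return list describing the arm.
#' @export
arm_spec <- function(treatment, subtype, n_sensitive, n_resistant, n_rcb2 = 0L) {
  stopifnot(n_sensitive >= 1, n_resistant >= 1, n_rcb2 >= 0)
  list(treatment = treatment, subtype = subtype,
       n_sensitive = as.integer(n_sensitive),
       n_resistant = as.integer(n_resistant),
       n_rcb2 = as.integer(n_rcb2))
}

#' Simulation configuration
#'
#' Defines the synthetic study: a cohort with receptor-subtype/treatment
#' arms, planted resistance-signature genes of a stated log2 effect size,
#' and a drug compendium of random profiles plus one planted reverser and
#' one planted mimicker.
#'
#' @param n_genes gene universe size.
#' @param arms list of [arm_spec()] entries.
#' @param n_signature_genes planted signature genes per arm (half shifted
#'   up, half down in resistant samples).
#' @param n_shared_signature_genes how many planted genes are common to all
#'   arms (the rest are drawn per arm); lets multi-arm benchmarks have a
#'   recurrent signature.
#' @param effect_size mean log2 shift of planted genes in resistant samples.
#' @param noise_sd per-gene Gaussian noise, log2 units.
#' @param baseline_mean background mean, log2 units.
#' @param n_drugs number of random drugs (the compendium additionally holds
#'   the reverser and the mimicker).
#' @param reverser_fidelity fraction in `[0, 1]` of signature genes the
#'   planted reverser flips (the mimicker matches them instead).
#' @param seed integer master seed; every generator draws from a stream
#'   derived from it plus a role-specific offset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L,
                       arms = list(arm_spec("paclitaxel", "HR+HER2-", 10L, 10L)),
                       n_signature_genes = 100L,
                       n_shared_signature_genes = 0L,
                       effect_size = 3,
                       noise_sd = 0.5,
                       baseline_mean = 9.5,
                       n_drugs = 200L,
                       reverser_fidelity = 1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), arms = arms,
              n_signature_genes = as.integer(n_signature_genes),
              n_shared_signature_genes = as.integer(n_shared_signature_genes),
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_mean = baseline_mean, n_drugs = as.integer(n_drugs),
              reverser_fidelity = reverser_fidelity, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, length(cfg$arms) >= 1,
            cfg$n_signature_genes > 0, cfg$n_drugs > 0,
            cfg$noise_sd > 0,
            cfg$reverser_fidelity >= 0, cfg$reverser_fidelity <= 1,
            cfg$n_shared_signature_genes >= 0,
            cfg$n_shared_signature_genes <= cfg$n_signature_genes)
  if (cfg$n_signature_genes > cfg$n_genes)
    stop("n_signature_genes exceeds n_genes", call. = FALSE)
  invisible(cfg)
}

#' @rdname sim_config
#' @param treatment,subtype arm coordinates.
#' @export
arm_id <- function(treatment, subtype) paste(treatment, subtype, sep = "|")

parse_subtype <- function(subtype) {
  hr <- if (grepl("HR+", subtype, fixed = TRUE)) "positive" else "negative"
  her2 <- if (grepl("HER2+", subtype, fixed = TRUE)) "positive" else "negative"
  list(hr = hr, her2 = her2)
}

# Stream offsets per generator role; gene-set and drug draws never perturb
# the cohort draw.
.SIM_OFFSETS <- c(cohort = 101, drugs = 100000, sets = 303)

#' Generate a synthetic expression cohort with planted resistance signatures
#'
#' Background expression is `Normal(baseline_mean, noise_sd)` i.i.d. over
#' genes and samples. Per arm, `n_signature_genes` planted genes are shifted
#' by `+effect_size` (half) or `-effect_size` (half) in resistant (RCB III)
#' samples only; RCB II samples carry a half-effect shift, emulating their
#' intermediate phenotype. Sensitive samples get RCB 0 or I uniformly.
#'
#' @param config a [sim_config()].
#' @return list with `expression` (matrix), `annotations` (data.frame) and
#'   `truth` (planted up/down sets per arm and the role of every drug).
#' @export
gen_cohort <- function(config) {
  validate_sim_config(config)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  with_seed_offset(config$seed, .SIM_OFFSETS[["cohort"]], {
    ann_rows <- list()
    planted <- list()
    n_shared <- config$n_shared_signature_genes
    shared <- if (n_shared > 0L) sample(genes, n_shared) else character()
    cols <- list()
    for (k in seq_along(config$arms)) {
      arm <- config$arms[[k]]
      id <- arm_id(arm$treatment, arm$subtype)
      own <- sample(setdiff(genes, shared),
                    config$n_signature_genes - n_shared)
      sig <- c(shared, own)
      half <- ceiling(length(sig) / 2)
      up <- sig[seq_len(half)]
      down <- sig[-seq_len(half)]
      planted[[id]] <- list(up = up, down = down)

      st <- parse_subtype(arm$subtype)
      n_tot <- arm$n_sensitive + arm$n_resistant + arm$n_rcb2
      ids <- sprintf("arm%02d_%s%03d", k,
                     rep(c("sens", "res", "rcb2"),
                         c(arm$n_sensitive, arm$n_resistant, arm$n_rcb2)),
                     c(seq_len(arm$n_sensitive), seq_len(arm$n_resistant),
                       seq_len(arm$n_rcb2)))
      rcb <- c(sample(c("0", "I"), arm$n_sensitive, replace = TRUE),
               rep("III", arm$n_resistant), rep("II", arm$n_rcb2))
      ann_rows[[k]] <- data.frame(
        sample_id = ids, hr_status = st$hr, her2_status = st$her2,
        treatment = arm$treatment, rcb_class = rcb,
        stringsAsFactors = FALSE)

      block <- matrix(stats::rnorm(config$n_genes * n_tot,
                                   config$baseline_mean, config$noise_sd),
                      config$n_genes, n_tot, dimnames = list(genes, ids))
      res_cols <- which(rcb == "III")
      rcb2_cols <- which(rcb == "II")
      block[up, res_cols] <- block[up, res_cols] + config$effect_size
      block[down, res_cols] <- block[down, res_cols] - config$effect_size
      if (length(rcb2_cols)) {
        block[up, rcb2_cols] <- block[up, rcb2_cols] + config$effect_size / 2
        block[down, rcb2_cols] <- block[down, rcb2_cols] - config$effect_size / 2
      }
      cols[[k]] <- block
    }
    expr <- do.call(cbind, cols)
    ann <- do.call(rbind, ann_rows)
  })
  drug_ids <- c("reverser", "mimicker", sprintf("rnd%03d", seq_len(config$n_drugs)))
  roles <- stats::setNames(c("reverser", "mimicker",
                             rep("random", config$n_drugs)), drug_ids)
  truth <- list(arms = planted, drug_roles = roles)
  list(expression = expr, annotations = ann, truth = truth)
}

#' Generate a synthetic drug-perturbation compendium for one arm
#'
#' Random drugs have i.i.d. `Normal(0, 1)` stats per gene. The planted
#' reverser assigns strongly negative stats to a `reverser_fidelity`
#' fraction of the arm's planted up-genes and strongly positive stats to
#' the matching fraction of down-genes; the mimicker does the opposite.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [gen_cohort()].
#' @param arm arm id (see [arm_id()]).
#' @return `drug_profiles` object over the cohort gene universe.
#' @export
gen_drug_profiles <- function(config, truth, arm) {
  validate_sim_config(config)
  if (!arm %in% names(truth$arms))
    stop(sprintf("unknown arm '%s'; known: %s", arm,
                 paste(names(truth$arms), collapse = ", ")), call. = FALSE)
  k <- match(arm, names(truth$arms))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  drug_ids <- names(truth$drug_roles)
  with_seed_offset(config$seed, .SIM_OFFSETS[["drugs"]] + k, {
    stat <- matrix(stats::rnorm(config$n_genes * length(drug_ids)),
                   config$n_genes, length(drug_ids),
                   dimnames = list(genes, drug_ids))
    up <- truth$arms[[arm]]$up
    down <- truth$arms[[arm]]$down
    n_up <- round(config$reverser_fidelity * length(up))
    n_dn <- round(config$reverser_fidelity * length(down))
    plant <- function(col, dn_set, up_set) {
      # pushed far outside the N(0,1) bulk so planted genes own the tails
      stat[dn_set, col] <<- -(8 + stats::runif(length(dn_set)))
      stat[up_set, col] <<- 8 + stats::runif(length(up_set))
    }
    rev_up <- if (n_up > 0L) sample(up, n_up) else character()
    rev_dn <- if (n_dn > 0L) sample(down, n_dn) else character()
    plant("reverser", dn_set = rev_up, up_set = rev_dn)
    mim_up <- if (n_up > 0L) sample(up, n_up) else character()
    mim_dn <- if (n_dn > 0L) sample(down, n_dn) else character()
    plant("mimicker", dn_set = mim_dn, up_set = mim_up)
  })
  drug_profiles(stat)
}

#' Generate a gene-set collection with planted and random sets
#'
#' Emits `planted_up` and `planted_down` (the arm's planted signature
#' halves) plus `n_random` random sets of matched size drawn without
#' replacement from the gene universe.
#'
#' @inheritParams gen_drug_profiles
#' @param arm arm id; defaults to the first arm in `truth`.
#' @param n_random number of random sets.
#' @return `gene_set_collection`.
#' @export
gen_gene_sets <- function(config, truth, arm = names(truth$arms)[1L],
                          n_random = 10L) {
  validate_sim_config(config)
  if (!arm %in% names(truth$arms))
    stop(sprintf("unknown arm '%s'", arm), call. = FALSE)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  up <- truth$arms[[arm]]$up
  down <- truth$arms[[arm]]$down
  sets <- with_seed_offset(config$seed, .SIM_OFFSETS[["sets"]], {
    rnd <- lapply(seq_len(n_random), function(i) sample(genes, length(up)))
    names(rnd) <- sprintf("random_%02d", seq_len(n_random))
    c(list(planted_up = up, planted_down = down), rnd)
  })
  attr(sets, "descriptions") <- stats::setNames(
    c("planted up-genes", "planted down-genes",
      rep("random set", n_random)), names(sets))
  gene_set_collection(sets)
}
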