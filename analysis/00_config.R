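# Shared study configuration for the analysis drivers. Sourced by the
# numbered scripts so every stage regenerates from the same definition.
library(revsig)

study_config <- function(seed = 1L) {
  sim_config(
    n_genes = 5000L,
    arms = list(arm_spec("paclitaxel", "HR+HER2-", 10L, 10L, n_rcb2 = 4L),
                arm_spec("paclitaxel", "HR-HER2-", 8L, 8L)),
    n_signature_genes = 100L,
    n_shared_signature_genes = 60L,
    effect_size = 3, noise_sd = 0.5, baseline_mean = 9.5,
    n_drugs = 200L, reverser_fidelity = 1, seed = seed)
}

arm_tag <- function(a) {
  a <- gsub("+", "pos", a, fixed = TRUE)
  a <- gsub("-", "neg", a, fixed = TRUE)
  gsub("[^A-Za-z0-9]+", "_", a)
}
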