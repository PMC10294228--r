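# Internal helpers shared across modules.

# Run `code` under a deterministic RNG stream derived from a base seed and a
# role-specific offset, restoring the caller's RNG state afterwards. Offsets
# keep the streams of independent generator roles separate, so e.g. adding
# drugs to a config never changes the cohort draw.
with_seed_offset <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  derived <- as.integer((as.numeric(seed) + offset) %% 2147483647)
  withr::with_seed(derived, code)
}

# Deterministic, locale-independent ordering by descending stat with
# gene-id tie-break (radix = C locale).
order_desc_stat <- function(stat, ids) {
  order(-stat, ids, method = "radix")
}

# File-system safe token for an arm id; receptor-status signs are spelled
# out so e.g. HR+HER2- and HR-HER2- stay distinct.
sanitize_id <- function(x) {
  x <- gsub("+", "pos", x, fixed = TRUE)
  x <- gsub("-", "neg", x, fixed = TRUE)
  gsub("[^A-Za-z0-9]+", "_", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_load <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
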