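#' Read a log2 expression matrix from TSV
#'
#' The file is tab-separated with gene ids in the first column and a header
#' row of sample ids. A GCT-style preamble (`#1.2` plus a dimensions line)
#' is detected and skipped. Values are log2-scale intensities.
#'
#' @param path path to a TSV (or GCT-headed) expression file.
#' @param policy how to treat genes with missing values: `"drop"` removes
#'   the gene row, `"impute"` replaces each missing cell with the gene mean.
#' @return numeric matrix (genes x samples) with unique row and column names.
#' @export
read_expression <- function(path, policy = c("drop", "impute")) {
  policy <- match.arg(policy)
  df <- read_tsv_table(path, what = "expression")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_load("duplicate gene id(s) in %s: %s", path,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- numeric_columns(df[-1L], path, row_ids = ids)
  rownames(mat) <- ids
  if (anyNA(mat)) {
    if (policy == "drop") {
      mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    } else {
      for (i in which(rowSums(is.na(mat)) > 0L)) {
        m <- mean(mat[i, ], na.rm = TRUE)
        mat[i, is.na(mat[i, ])] <- m
      }
    }
  }
  validate_expression(mat)
  mat
}

#' Write an expression matrix as TSV
#' @param mat numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) == 0L || ncol(mat) == 0L)
    stop_load("expression matrix is empty or not numeric")
  if (anyDuplicated(rownames(mat))) stop_load("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop_load("duplicate sample ids")
  if (anyNA(mat)) stop_load("expression matrix contains missing values")
  invisible(mat)
}

RCB_LEVELS <- c("0", "I", "II", "III", "missing")

#' Read a cohort annotation table
#'
#' Tab-separated with required columns `sample_id`, `hr_status`,
#' `her2_status`, `treatment`, `rcb_class`. Blank or NA `rcb_class` is
#' mapped to `"missing"`; any other value outside `0/I/II/III` is an error.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with validated columns.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_table(path, what = "annotations")
  req <- c("sample_id", "hr_status", "her2_status", "treatment", "rcb_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_load("annotation file %s lacks column(s): %s", path,
              paste(miss, collapse = ", "))
  df <- df[req]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id))
    stop_load("duplicate sample id(s) in %s", path)
  df$rcb_class[is.na(df$rcb_class) | df$rcb_class == ""] <- "missing"
  bad <- !(df$rcb_class %in% RCB_LEVELS)
  if (any(bad))
    stop_load("unknown rcb_class value(s) %s in row(s) %s of %s",
              paste(unique(df$rcb_class[bad]), collapse = ", "),
              paste(which(bad), collapse = ", "), path)
  for (col in c("hr_status", "her2_status")) {
    bad <- !(df[[col]] %in% c("positive", "negative"))
    if (any(bad))
      stop_load("invalid %s value(s) in row(s) %s of %s", col,
                paste(which(bad), collapse = ", "), path)
  }
  df
}

#' Write a cohort annotation table
#' @param ann annotation data.frame as returned by [read_annotations()].
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a set are deduplicated; duplicate set names and
#' lines with fewer than three fields are errors.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_load("GMT line(s) %s in %s have fewer than 3 fields",
              paste(short, collapse = ", "), path)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop_load("duplicate gene-set name(s) in %s: %s", path,
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  gene_set_collection(sets)
}

gene_set_collection <- function(sets) {
  if (any(lengths(sets) == 0L)) stop_load("empty gene set(s) in collection")
  class(sets) <- c("gene_set_collection", "list")
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors (optionally carrying a
#'   `descriptions` attribute).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Build a drug-profile object from a differential-expression stat matrix
#'
#' Per drug, genes are ranked by descending stat (rank 1 = most
#' up-regulated by the drug); ties are broken by gene-id lexicographic
#' order so rankings are reproducible across platforms.
#'
#' @param stat numeric genes x drugs matrix with dimnames.
#' @return object of class `drug_profiles`: list with `stat` and integer
#'   `ranks` matrices sharing dimnames.
#' @export
drug_profiles <- function(stat) {
  if (!is.matrix(stat) || !is.numeric(stat))
    stop_load("drug profile stats must be a numeric matrix")
  if (is.null(rownames(stat)) || anyDuplicated(rownames(stat)))
    stop_load("drug profile gene ids absent or duplicated")
  if (anyNA(stat)) stop_load("drug profile stats contain missing values")
  n <- nrow(stat)
  ranks <- matrix(0L, n, ncol(stat), dimnames = dimnames(stat))
  for (j in seq_len(ncol(stat))) {
    ord <- order_desc_stat(stat[, j], rownames(stat))
    ranks[ord, j] <- seq_len(n)
  }
  structure(list(stat = stat, ranks = ranks), class = "drug_profiles")
}

#' Read a drug-perturbation compendium from TSV
#'
#' Genes x drugs numeric matrix of differential-expression stats, gene ids
#' in the first column. Ranks are derived per drug (see [drug_profiles()]).
#'
#' @inheritParams read_expression
#' @return `drug_profiles` object.
#' @export
read_drug_profiles <- function(path) {
  df <- read_tsv_table(path, what = "drug profiles")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_load("duplicate gene id(s) in %s", path)
  mat <- numeric_columns(df[-1L], path, row_ids = ids)
  rownames(mat) <- ids
  if (anyNA(mat)) stop_load("missing value(s) in drug profile file %s", path)
  drug_profiles(mat)
}

#' Write a drug-profile stat matrix as TSV
#' @param dp `drug_profiles` object.
#' @param path output path.
#' @export
write_drug_profiles <- function(dp, path) {
  write_expression(dp$stat, path)
}

# -- shared low-level readers -------------------------------------------------

# Read a TSV with a header row, skipping a GCT preamble when present.
read_tsv_table <- function(path, what) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#1.2")) 2L else 0L
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, skip = skip,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = c("NA", "")),
    error = function(e) stop_load("malformed %s file %s: %s", what, path,
                                  conditionMessage(e)))
  if (ncol(df) < 2L)
    stop_load("malformed header in %s file %s (need id column + data)", what, path)
  if (anyDuplicated(names(df)[-1L]))
    stop_load("duplicate sample/column id(s) in %s", path)
  df
}

# Convert character data columns to a numeric matrix, reporting the first
# offending cell by gene id and column name.
numeric_columns <- function(df, path, row_ids) {
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop_load("non-numeric value '%s' at gene %s, column %s of %s",
                df[[j]][bad[1L]], row_ids[bad[1L]], names(df)[j], path)
    mat[, j] <- v
  }
  mat
}
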