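# Internal helpers shared across modules.

# Canonical symbol normalization: upper-case, trimmed, first token before ";".
# Matches how ChEA/Enrichr-style collections key their members.
normalize_ids <- function(x) {
  x <- toupper(trimws(as.character(x)))
  sub(";.*$", "", x)
}

sample_cols <- function(x) setdiff(names(x), "protein")

# Validate the wide intensity tibble: first column `protein` (unique ids),
# remaining columns numeric, finite, non-negative; >= 1 protein, >= 2 samples.
validate_intensity <- function(x, arg = "matrix") {
  if (!is.data.frame(x) || !"protein" %in% names(x)) {
    abort(sprintf("`%s` must be a data frame with a `protein` column.", arg))
  }
  smp <- sample_cols(x)
  if (nrow(x) < 1L || length(smp) < 2L) {
    abort(sprintf("`%s` needs at least 1 protein and 2 sample columns.", arg))
  }
  if (anyDuplicated(x$protein)) {
    dup <- unique(x$protein[duplicated(x$protein)])
    abort(sprintf("Duplicate protein ids in `%s`: %s", arg,
                  paste(head(dup, 5L), collapse = ", ")))
  }
  if (anyDuplicated(smp)) abort(sprintf("Duplicate sample ids in `%s`.", arg))
  vals <- as.matrix(x[smp])
  if (!is.numeric(vals)) abort(sprintf("Sample columns of `%s` must be numeric.", arg))
  if (any(!is.finite(vals))) abort(sprintf("`%s` contains non-finite values.", arg))
  if (any(vals < 0)) abort(sprintf("`%s` contains negative abundances.", arg))
  invisible(x)
}

# Wide tibble -> base matrix with protein rownames (fast path for math).
intensity_matrix <- function(x) {
  m <- as.matrix(x[sample_cols(x)])
  rownames(m) <- x$protein
  m
}

matrix_to_tbl <- function(m) {
  out <- as_tibble(m)
  dplyr::bind_cols(tibble(protein = rownames(m)), out)
}

# Validate a two-group sample annotation against the matrix's samples.
# Returns the annotation restricted/ordered to the matrix samples.
validate_annotation <- function(annotation, samples,
                                require_both = TRUE) {
  if (!is.data.frame(annotation) ||
      !all(c("sample", "group") %in% names(annotation))) {
    abort("`annotation` must have columns `sample` and `group`.")
  }
  if (anyDuplicated(annotation$sample)) {
    abort("`annotation` contains duplicated sample ids.")
  }
  bad <- setdiff(annotation$group, c("case", "control"))
  if (length(bad)) {
    abort(sprintf("Unknown group label(s): %s (expected \"case\"/\"control\").",
                  paste(unique(bad), collapse = ", ")))
  }
  missing <- setdiff(samples, annotation$sample)
  if (length(missing)) {
    abort(sprintf("Samples missing from annotation: %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  ann <- annotation[match(samples, annotation$sample), , drop = FALSE]
  if (require_both && (!any(ann$group == "case") || !any(ann$group == "control"))) {
    abort("Both `case` and `control` groups must be non-empty.")
  }
  ann
}

# Evaluate `code` under `seed` (restoring RNG state afterwards) when a seed
# is given; under the current RNG stream otherwise.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Validate a gene-set collection tibble (columns set, description, genes).
validate_collection <- function(collection) {
  if (!is.data.frame(collection) ||
      !all(c("set", "genes") %in% names(collection))) {
    abort("`collection` must be a tibble with columns `set` and `genes` (list).")
  }
  if (anyDuplicated(collection$set)) abort("Gene-set names must be unique.")
  if (any(lengths(collection$genes) == 0L)) {
    abort("Every gene set must have at least one member.")
  }
  invisible(collection)
}
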