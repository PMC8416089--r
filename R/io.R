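#' Read a MaxQuant proteinGroups table into an intensity tibble
#'
#' Extracts the per-sample iBAQ columns from a `proteinGroups.txt`-style
#' tab-separated file, drops decoy (`Reverse == "+"`) and contaminant
#' (`Potential contaminant == "+"`) rows as well as rows without an
#' identifier, and resolves duplicated identifiers by keeping the row with
#' the larger total iBAQ.
#'
#' Identifiers are normalized for downstream gene-set matching: upper-cased,
#' whitespace-trimmed, and truncated at the first `";"` for multi-id cells.
#'
#' @param path Path to a tab-separated proteinGroups file.
#' @param id_col Identifier column. Defaults to `"Gene names"`, falling back
#'   to `"Majority protein IDs"` when absent (set explicitly to match on
#'   UniProt accessions instead of gene symbols).
#' @return A tibble with a `protein` column of unique identifiers and one
#'   non-negative numeric column per sample (missing measurements are 0).
#' @export
read_protein_groups <- function(path, id_col = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  ibaq_cols <- grep("^iBAQ .+", names(raw), value = TRUE)
  ibaq_cols <- setdiff(ibaq_cols, "iBAQ peptides")
  if (!length(ibaq_cols)) {
    abort(sprintf(
      "No 'iBAQ <sample>' columns found; header was: %s",
      paste(names(raw), collapse = ", ")))
  }
  if (is.null(id_col)) {
    id_col <- if ("Gene names" %in% names(raw)) "Gene names" else "Majority protein IDs"
  }
  if (!id_col %in% names(raw)) {
    abort(sprintf("Identifier column '%s' not present in file.", id_col))
  }

  keep <- rep(TRUE, nrow(raw))
  for (flag in c("Reverse", "Potential contaminant")) {
    if (flag %in% names(raw)) {
      keep <- keep & (is.na(raw[[flag]]) | raw[[flag]] != "+")
    }
  }
  raw <- raw[keep, , drop = FALSE]

  ids <- normalize_ids(raw[[id_col]])
  ok <- !is.na(ids) & ids != "" & ids != "NA"
  raw <- raw[ok, , drop = FALSE]
  ids <- ids[ok]

  vals <- matrix(0, nrow(raw), length(ibaq_cols),
                 dimnames = list(NULL, sub("^iBAQ ", "", ibaq_cols)))
  for (j in seq_along(ibaq_cols)) {
    cell <- raw[[ibaq_cols[j]]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "" & cell != "NA" & cell != "NaN")
    if (length(bad)) {
      abort(sprintf("Non-numeric iBAQ value '%s' at data row %d, column '%s'.",
                    cell[bad[1L]], bad[1L], ibaq_cols[j]))
    }
    num[is.na(num)] <- 0
    vals[, j] <- num
  }

  # duplicate ids: keep the best-quantified row (largest total iBAQ)
  total <- rowSums(vals)
  ord <- order(total, decreasing = TRUE)
  first <- ord[!duplicated(ids[ord])]
  first <- sort(first)  # preserve file order among winners

  out <- dplyr::bind_cols(tibble(protein = ids[first]),
                          as_tibble(vals[first, , drop = FALSE]))
  validate_intensity(out, "proteinGroups matrix")
}

#' Read a plain protein-by-sample TSV matrix
#'
#' First column is the protein identifier; remaining columns are samples.
#' Blank and `NA` cells are coerced to 0 (the missing-as-zero convention)
#' and the number of coercions is reported.
#'
#' @param path Path to the TSV file.
#' @return An intensity tibble (`protein` + one numeric column per sample).
#' @export
read_intensity_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort("Empty data section: no protein rows found.")
  ids <- normalize_ids(raw[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Duplicate protein ids: %s", paste(dup, collapse = ", ")))
  }
  smp <- names(raw)[-1L]
  vals <- matrix(0, nrow(raw), length(smp), dimnames = list(NULL, smp))
  n_coerced <- 0L
  for (j in seq_along(smp)) {
    cell <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    blank <- is.na(cell) | cell == "" | cell == "NA"
    bad <- which(is.na(num) & !blank)
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' at data row %d, column '%s'.",
                    cell[bad[1L]], bad[1L], smp[j]))
    }
    n_coerced <- n_coerced + sum(blank)
    num[is.na(num)] <- 0
    vals[, j] <- num
  }
  if (n_coerced > 0L) {
    cli::cli_inform("Coerced {n_coerced} blank/NA cell{?s} to 0.")
  }
  out <- dplyr::bind_cols(tibble(protein = ids), as_tibble(vals))
  validate_intensity(out, "intensity matrix")
}

#' Write an intensity tibble to TSV
#'
#' Inverse of [read_intensity_tsv()]: a written matrix reads back with
#' identical ids and values.
#'
#' @param x Intensity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(x, path) {
  validate_intensity(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated
#' `name <TAB> description <TAB> member...`. Members are upper-cased on load
#' and de-duplicated within a set.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description`, and `genes`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", short[1L]))
  }
  sets <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(sets)) {
    abort(sprintf("Duplicate set names in GMT: %s",
                  paste(unique(sets[duplicated(sets)]), collapse = ", ")))
  }
  genes <- lapply(fields, function(f) {
    g <- normalize_ids(f[-(1:2)])
    unique(g[nzchar(g)])
  })
  if (any(lengths(genes) == 0L)) {
    abort("GMT contains a set with no non-empty members.")
  }
  tibble(set = sets,
         description = vapply(fields, `[[`, character(1), 2L),
         genes = genes)
}

#' Write a gene-set collection to GMT
#'
#' @param collection Collection tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  validate_collection(collection)
  desc <- if ("description" %in% names(collection)) collection$description else ""
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set[i], desc[i] %||% "", collection$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column sample annotation table
#'
#' Expects a header and two tab-separated columns: sample id and group
#' label. Labels are recoded to the internal `"case"`/`"control"` pair;
#' any label outside the configured pair is an error. Extra columns are
#' ignored with a warning.
#'
#' @param path Path to the TSV file.
#' @param case,control The file's label for each arm (e.g. `case = "PDR"`,
#'   `control = "iERM"`).
#' @return A tibble with columns `sample` and `group` (`"case"`/`"control"`).
#' @export
read_sample_annotation <- function(path, case = "case", control = "control") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("Annotation needs two columns: sample id and group.")
  if (ncol(raw) > 2L) {
    warn(sprintf("Ignoring extra annotation column(s): %s",
                 paste(names(raw)[-(1:2)], collapse = ", ")))
  }
  ann <- tibble(sample = raw[[1L]], group = raw[[2L]])
  if (anyDuplicated(ann$sample)) {
    abort(sprintf("Duplicated sample id(s): %s",
                  paste(unique(ann$sample[duplicated(ann$sample)]), collapse = ", ")))
  }
  bad <- setdiff(ann$group, c(case, control))
  if (length(bad)) {
    abort(sprintf("Unknown group label(s): %s (expected '%s' or '%s').",
                  paste(unique(bad), collapse = ", "), case, control))
  }
  ann$group <- ifelse(ann$group == case, "case", "control")
  ann
}
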