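#' Normalize raw abundances to iFOT fractions
#'
#' iFOT (intensity fraction of total) divides each protein's abundance by
#' its sample's total abundance, so every sample column sums to 1. Zeros
#' (absent measurements) stay zero, preserving detection semantics.
#'
#' @param x Intensity tibble (`protein` + numeric sample columns).
#' @return A tibble of the same shape whose sample columns each sum to 1.
#' @export
ifot_normalize <- function(x) {
  validate_intensity(x)
  m <- intensity_matrix(x)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(sprintf("Sample(s) with zero total intensity: %s",
                  paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  matrix_to_tbl(sweep(m, 2L, totals, "/"))
}

#' Log2-transform an iFOT matrix with a pseudocount
#'
#' Computes `log2(value + pseudocount)`. The pseudocount is applied only
#' here, never to the stored iFOT fractions, so `0` continues to mean
#' "not detected" upstream. The default `1e-8` sits below any plausible
#' single-protein iFOT fraction in a cohort of hundreds of proteins.
#'
#' @param x iFOT (or intensity) tibble.
#' @param pseudocount Positive offset added before taking log2.
#' @return Tibble of the same shape with log2-scale values.
#' @export
log_transform <- function(x, pseudocount = 1e-8) {
  validate_intensity(x)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number.")
  }
  m <- intensity_matrix(x)
  matrix_to_tbl(log2(m + pseudocount))
}
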