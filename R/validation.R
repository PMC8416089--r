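#' Per-protein Z-standardization across cohort samples
#'
#' Standardizes each protein's values to mean 0 and sample standard
#' deviation 1 (n - 1 denominator) across all cohort samples jointly.
#' Zero-variance proteins cannot be standardized and are dropped; their
#' ids are attached as attribute `"excluded_proteins"`.
#'
#' @param x Log-scale (or iFOT) tibble with at least 2 samples.
#' @return Tibble of Z-scores for the retained proteins.
#' @export
zscore_by_protein <- function(x) {
  m <- intensity_matrix_any(x)
  if (ncol(m) < 2L) abort("Z-standardization needs at least 2 samples.")
  mu <- rowMeans(m)
  sdev <- apply(m, 1L, sd)
  keep <- sdev > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  out <- matrix_to_tbl(z)
  attr(out, "excluded_proteins") <- rownames(m)[!keep]
  out
}

#' Mean signature Z-score per sample
#'
#' Scores each sample by the mean Z-score of the signature proteins
#' present in the cohort matrix. Coverage (fraction of signature proteins
#' found) is attached and enforced: low-coverage scoring is refused
#' because a sparse overlap no longer measures the signature.
#'
#' @param z Z-score tibble from [zscore_by_protein()].
#' @param signature Character vector of protein ids, or a
#'   `signature_definition` (its `up` set is used).
#' @param min_coverage Minimum tolerated coverage in \[0, 1\].
#' @return Tibble with columns `sample`, `score`; attribute `"coverage"`.
#' @export
mean_signature_score <- function(z, signature, min_coverage = 0.5) {
  if (inherits(signature, "signature_definition")) signature <- signature$up
  signature <- unique(normalize_ids(signature))
  if (!length(signature)) abort("`signature` is empty.")
  m <- intensity_matrix_any(z)
  hit <- intersect(signature, rownames(m))
  coverage <- length(hit) / length(signature)
  if (!length(hit)) abort("No signature protein is present in the matrix.")
  if (coverage < min_coverage) {
    abort(sprintf("Signature coverage %.2f below min_coverage %.2f.",
                  coverage, min_coverage))
  }
  out <- tibble(sample = colnames(m),
                score = unname(colMeans(m[hit, , drop = FALSE])))
  attr(out, "coverage") <- coverage
  out
}

#' Mann-Whitney U test (exact for small samples, else corrected normal)
#'
#' Computes the U statistic for `case` versus `control` (number of
#' case/control pairs with the case value larger, ties counted 1/2). The
#' p-value is exact (full null enumeration of the U distribution) when
#' `n1 + n2 <= 12` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used. With every
#' observation tied the null variance vanishes and p = 1 by convention.
#'
#' @param case,control Numeric score vectors (no NAs).
#' @param alternative `"greater"` (case > control, the default for an
#'   up-signature), `"less"`, or `"two.sided"`.
#' @return An object of class `mwu_test`: list with `u`, `p_value`,
#'   `n_case`, `n_control`, `method`, `alternative`.
#' @export
mann_whitney_u <- function(case, control,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (anyNA(case) || anyNA(control) || !length(case) || !length(control)) {
    abort("`case` and `control` must be non-empty and NA-free.")
  }
  n1 <- length(case); n2 <- length(control); n <- n1 + n2
  pooled <- c(case, control)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && n <= 12L) {
    method <- "exact"
    p <- switch(alternative,
      greater = 1 - pwilcox(u - 1, n1, n2),
      less = pwilcox(u, n1, n2),
      two.sided = min(1, 2 * min(pwilcox(u, n1, n2), 1 - pwilcox(u - 1, n1, n2))))
  } else {
    method <- "normal approximation"
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
        greater = pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
        less = pnorm((u - mu + 0.5) / sigma),
        two.sided = {
          z <- (u - mu - sign(u - mu) * 0.5) / sigma
          min(1, 2 * pnorm(-abs(z)))
        })
    }
  }
  structure(list(u = unname(u), p_value = unname(p), n_case = n1,
                 n_control = n2, method = method, alternative = alternative),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s)\n", x$method, x$alternative))
  cat(sprintf("  U = %g (n1 = %d, n2 = %d), p = %.4g\n",
              x$u, x$n_case, x$n_control, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mwu_test <- function(x, ...) {
  tibble(u = x$u, p_value = x$p_value, n_case = x$n_case,
         n_control = x$n_control, method = x$method,
         alternative = x$alternative)
}

#' ROC curve and AUC for a two-group score table
#'
#' Sweeps all score thresholds, recording the false and true positive
#' rates, and integrates the curve by the trapezoidal rule (tied scores
#' earn half credit, making the AUC identical to U / (n1 n2)). Higher
#' scores are taken to indicate the positive (`case`) class.
#'
#' @param data Tibble with one row per sample.
#' @param score Column holding the numeric score (default `score`).
#' @param group Column holding the class label (default `group`).
#' @param positive Label of the positive class (default `"case"`).
#' @return A `roc_result`: list with `points` (tibble of `threshold`,
#'   `fpr`, `tpr`), `auc`, `n_case`, `n_control`.
#' @export
roc_auc <- function(data, score = score, group = group, positive = "case") {
  sc <- dplyr::pull(data, {{ score }})
  lab <- dplyr::pull(data, {{ group }})
  if (anyNA(sc)) abort("Scores must not contain NA.")
  classes <- unique(lab)
  if (!positive %in% classes || length(classes) < 2L) {
    abort("Both classes must be present, including the positive label.")
  }
  response <- factor(ifelse(lab == positive, "pos", "neg"), levels = c("neg", "pos"))
  r <- pROC::roc(response, sc, levels = c("neg", "pos"), direction = "<",
                 quiet = TRUE)
  points <- tibble(threshold = rev(r$thresholds),
                   fpr = rev(1 - r$specificities),
                   tpr = rev(r$sensitivities))
  structure(list(points = points, auc = as.numeric(pROC::auc(r)),
                 n_case = sum(response == "pos"),
                 n_control = sum(response == "neg")),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d case vs %d control, %d points)\n",
              x$auc, x$n_case, x$n_control, nrow(x$points)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_case = x$n_case, n_control = x$n_control)
}
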