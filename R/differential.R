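#' Partition proteins by group-wise detection
#'
#' A protein is "detected in a group" when its abundance is greater than 0
#' in at least `min_detect` samples of that group. Proteins fall into four
#' disjoint classes: detected only in cases, only in controls, in both
#' (shared), or in neither (undetected).
#'
#' @param x Intensity or iFOT tibble.
#' @param annotation Tibble with columns `sample`, `group`
#'   (`"case"`/`"control"`).
#' @param min_detect Minimum number of positive samples per group (>= 1).
#' @return A `detection_partition` object: a list with character vectors
#'   `only_case`, `only_control`, `shared`, `undetected`.
#' @export
partition_by_detection <- function(x, annotation, min_detect = 1L) {
  validate_intensity(x)
  m <- intensity_matrix(x)
  ann <- validate_annotation(annotation, colnames(m))
  n_case <- sum(ann$group == "case")
  n_control <- sum(ann$group == "control")
  if (min_detect < 1L || min_detect > min(n_case, n_control)) {
    abort(sprintf("`min_detect` must be in [1, %d] for this design.",
                  min(n_case, n_control)))
  }
  det_case <- rowSums(m[, ann$group == "case", drop = FALSE] > 0) >= min_detect
  det_ctrl <- rowSums(m[, ann$group == "control", drop = FALSE] > 0) >= min_detect
  prot <- rownames(m)
  structure(
    list(only_case = prot[det_case & !det_ctrl],
         only_control = prot[!det_case & det_ctrl],
         shared = prot[det_case & det_ctrl],
         undetected = prot[!det_case & !det_ctrl],
         min_detect = as.integer(min_detect)),
    class = "detection_partition")
}

#' @export
print.detection_partition <- function(x, ...) {
  cat("Detection partition (min_detect =", x$min_detect, ")\n")
  cat("  only case:   ", length(x$only_case), "\n")
  cat("  only control:", length(x$only_control), "\n")
  cat("  shared:      ", length(x$shared), "\n")
  cat("  undetected:  ", length(x$undetected), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.detection_partition <- function(x, ...) {
  tibble(
    protein = c(x$only_case, x$only_control, x$shared, x$undetected),
    category = rep(c("only_case", "only_control", "shared", "undetected"),
                   c(length(x$only_case), length(x$only_control),
                     length(x$shared), length(x$undetected))))
}

#' @exportS3Method generics::glance
glance.detection_partition <- function(x, ...) {
  tibble(n_only_case = length(x$only_case),
         n_only_control = length(x$only_control),
         n_shared = length(x$shared),
         n_undetected = length(x$undetected),
         n_detected = length(x$only_case) + length(x$only_control) + length(x$shared))
}

#' Two-group tests on shared proteins
#'
#' Applies a two-sided two-sample test to every protein detected in both
#' groups. The default is Welch's unequal-variance t-test on log-scale
#' values; `"mann_whitney"` selects the rank-based alternative. When both
#' groups have zero variance and equal means the p-value is 1 by
#' convention (and 0 when the constant means differ).
#'
#' @param log_x Log-scale tibble, e.g. from [log_transform()].
#' @param annotation Sample annotation tibble.
#' @param partition A [partition_by_detection()] result; only its `shared`
#'   proteins are tested.
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @return Tibble with columns `protein`, `statistic`, `p_value`.
#' @export
test_shared_proteins <- function(log_x, annotation, partition,
                                 method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  m <- intensity_matrix_any(log_x)
  ann <- validate_annotation(annotation, colnames(m))
  shared <- intersect(rownames(m), partition$shared)
  mc <- m[shared, ann$group == "case", drop = FALSE]
  mk <- m[shared, ann$group == "control", drop = FALSE]
  n1 <- ncol(mc); n2 <- ncol(mk)

  if (method == "welch_t") {
    if (n1 < 2L || n2 < 2L) abort("Welch's t requires >= 2 samples per group.")
    m1 <- rowMeans(mc); m2 <- rowMeans(mk)
    v1 <- apply(mc, 1L, stats::var); v2 <- apply(mk, 1L, stats::var)
    se2 <- v1 / n1 + v2 / n2
    stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                   ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 1)
    p <- ifelse(is.finite(stat), 2 * stats::pt(-abs(stat), df),
                0)
    p[se2 == 0 & m1 == m2] <- 1
  } else {
    res <- lapply(seq_along(shared), function(i) {
      mw <- mann_whitney_u(mc[i, ], mk[i, ], alternative = "two.sided")
      c(mw$u, mw$p_value)
    })
    stat <- vapply(res, `[[`, numeric(1), 1L)
    p <- vapply(res, `[[`, numeric(1), 2L)
  }
  tibble(protein = shared, statistic = unname(stat), p_value = unname(p))
}

# log matrices may contain negative values; relax the non-negativity check
intensity_matrix_any <- function(x) {
  if (!is.data.frame(x) || !"protein" %in% names(x)) {
    abort("Expected a tibble with a `protein` column.")
  }
  m <- as.matrix(x[sample_cols(x)])
  rownames(m) <- x$protein
  if (!is.numeric(m) || any(!is.finite(m))) abort("Values must be finite numerics.")
  m
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (monotone step-up BH, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Per-protein log2 fold change of group mean iFOT
#'
#' `log2((mean case + eps) / (mean control + eps))`, with the pseudocount
#' guarding against zero group means for group-exclusive proteins.
#'
#' @param ifot iFOT tibble.
#' @param annotation Sample annotation tibble.
#' @param pseudocount Positive offset (default `1e-8`).
#' @return Tibble with columns `protein`, `log2fc`.
#' @export
compute_fold_change <- function(ifot, annotation, pseudocount = 1e-8) {
  validate_intensity(ifot)
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  m <- intensity_matrix(ifot)
  ann <- validate_annotation(annotation, colnames(m))
  mu_case <- rowMeans(m[, ann$group == "case", drop = FALSE])
  mu_ctrl <- rowMeans(m[, ann$group == "control", drop = FALSE])
  tibble(protein = rownames(m),
         log2fc = unname(log2((mu_case + pseudocount) / (mu_ctrl + pseudocount))))
}

#' Full differential-abundance table
#'
#' Orchestrates the detection partition, log-scale two-group tests on
#' shared proteins, BH adjustment (over the tested subset only), and fold
#' changes into one per-protein table. Undetected proteins are omitted;
#' group-exclusive proteins carry their fold change but no p/q (the test
#' is undefined without within-group observations on both sides).
#'
#' @param ifot iFOT tibble (use [ifot_normalize()] first).
#' @param annotation Sample annotation tibble.
#' @param alpha Significance level used to label `up`/`down` status.
#' @param min_detect Detection threshold per group (see
#'   [partition_by_detection()]).
#' @param pseudocount Offset for the log transform and fold changes.
#' @param method Two-group test, `"welch_t"` (default) or `"mann_whitney"`.
#' @return Tibble with columns `protein`, `log2fc`, `p_value`, `q_value`,
#'   `status` (one of `up`, `down`, `ns`, `case_only`, `control_only`),
#'   carrying the partition as attribute `"partition"`.
#' @export
differential_table <- function(ifot, annotation, alpha = 0.05,
                               min_detect = 1L, pseudocount = 1e-8,
                               method = c("welch_t", "mann_whitney")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  part <- partition_by_detection(ifot, annotation, min_detect)
  logm <- log_transform(ifot, pseudocount)
  tests <- test_shared_proteins(logm, annotation, part, method)
  tests$q_value <- bh_adjust(tests$p_value)
  fc <- compute_fold_change(ifot, annotation, pseudocount)

  out <- dplyr::left_join(fc, tests, by = "protein")
  out <- dplyr::filter(out, !(.data$protein %in% part$undetected))
  out$status <- dplyr::case_when(
    out$protein %in% part$only_case ~ "case_only",
    out$protein %in% part$only_control ~ "control_only",
    out$q_value < alpha & out$log2fc > 0 ~ "up",
    out$q_value < alpha & out$log2fc < 0 ~ "down",
    TRUE ~ "ns")
  out <- dplyr::select(out, "protein", "log2fc", "statistic", "p_value",
                       "q_value", "status")
  attr(out, "partition") <- part
  attr(out, "alpha") <- alpha
  out
}

#' Define up/down protein signatures from a differential table
#'
#' The up-signature (the "highly expressed proteome") collects shared
#' proteins with `q < alpha` and positive fold change; the down-signature
#' is the mirror image. `include_exclusive = TRUE` additionally folds the
#' group-exclusive proteins into the matching signature.
#'
#' @param diff_table Result of [differential_table()].
#' @param alpha FDR threshold in (0, 1).
#' @param include_exclusive Also include `case_only` proteins in the
#'   up-signature (and `control_only` in the down-signature)?
#' @return A `signature_definition` object with fields `up`, `down`, and
#'   the parameters used.
#' @export
define_signature <- function(diff_table, alpha = 0.05, include_exclusive = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  tested <- !is.na(diff_table$q_value)
  up <- diff_table$protein[tested & diff_table$q_value < alpha & diff_table$log2fc > 0]
  down <- diff_table$protein[tested & diff_table$q_value < alpha & diff_table$log2fc < 0]
  if (include_exclusive) {
    up <- c(up, diff_table$protein[diff_table$status == "case_only"])
    down <- c(down, diff_table$protein[diff_table$status == "control_only"])
  }
  structure(list(up = unique(up), down = unique(down),
                 alpha = alpha, include_exclusive = include_exclusive),
            class = "signature_definition")
}

#' @export
print.signature_definition <- function(x, ...) {
  cat(sprintf("Signature (alpha = %g, include_exclusive = %s)\n",
              x$alpha, x$include_exclusive))
  cat("  up:  ", length(x$up), "proteins\n")
  cat("  down:", length(x$down), "proteins\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.signature_definition <- function(x, ...) {
  tibble(protein = c(x$up, x$down),
         direction = rep(c("up", "down"), c(length(x$up), length(x$down))))
}
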