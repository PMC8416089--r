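#' Fisher exact over-representation analysis against a GMT collection
#'
#' For each gene set, builds the 2x2 table of query membership versus set
#' membership over the background universe and reports the one-sided
#' (enrichment) hypergeometric tail p-value
#' \eqn{P(X \ge k)}, \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}, the sample
#' odds ratio, and BH-adjusted q-values over the whole collection. Sets
#' are intersected with the background before testing, mirroring the
#' detected-proteome background convention of proteomics enrichment.
#'
#' @param query Character vector of protein/gene ids (must be a subset of
#'   `background` after case normalization).
#' @param collection Gene-set tibble (see [read_gmt()]).
#' @param background Character vector: the universe of testable ids,
#'   typically all proteins detected in the experiment.
#' @return Tibble sorted by (p, set name) with columns `set`, `overlap`,
#'   `set_size`, `query_size`, `background_size`, `odds_ratio`, `p_value`,
#'   `q_value`, `overlap_genes` (list-column).
#' @export
fisher_enrich <- function(query, collection, background) {
  validate_collection(collection)
  query <- unique(normalize_ids(query))
  background <- unique(normalize_ids(background))
  if (!length(background)) abort("`background` is empty.")
  extra <- setdiff(query, background)
  if (length(extra)) {
    abort(sprintf("Query ids outside the background: %s",
                  paste(head(extra, 5L), collapse = ", ")))
  }
  N <- length(background)
  n <- length(query)

  rows <- purrr::map(seq_len(nrow(collection)), function(i) {
    members <- intersect(collection$genes[[i]], background)
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    num <- k * (N - K - n + k)
    den <- (n - k) * (K - k)
    or <- if (k == 0) 0 else if (den == 0) Inf else num / den
    tibble(set = collection$set[i], overlap = k, set_size = K,
           query_size = n, background_size = N, odds_ratio = or,
           p_value = p, overlap_genes = list(sort(hit)))
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- dplyr::arrange(out, .data$p_value, .data$set)
  dplyr::relocate(out, "q_value", .after = "p_value")
}

#' Rank transcription factors from an ORA result
#'
#' Orders TF-keyed sets by ascending p-value, breaking ties by larger
#' overlap and then set name, and returns the first `top_k`.
#'
#' @param results Tibble from [fisher_enrich()] over a TF-target
#'   collection.
#' @param top_k Number of top TFs to return (>= 1).
#' @return Tibble of the `top_k` leading rows with a `rank` column.
#' @export
rank_tfs <- function(results, top_k = 10L) {
  if (top_k < 1L) abort("`top_k` must be >= 1.")
  out <- dplyr::arrange(results, .data$p_value, dplyr::desc(.data$overlap),
                        .data$set)
  out <- head(out, top_k)
  dplyr::bind_cols(tibble(rank = seq_len(nrow(out))), out)
}
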