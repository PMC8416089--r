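#' Build a ranked gene list from a two-group log-scale matrix
#'
#' Ranks genes by a case-versus-control metric, descending. The default
#' signal-to-noise metric is
#' `(mean_case - mean_control) / (sd_case + sd_control)` with each group's
#' SD floored at `max(0.2 * |group mean|, 0.2)` — the classic broad
#' enrichment-analysis convention that keeps near-constant genes from
#' dominating the ranking. `"log2fc"` uses the difference of group means
#' on the log scale. Ties are broken by gene symbol so the order is
#' strictly deterministic.
#'
#' @param log_x Log-scale tibble (e.g. [log_transform()] output).
#' @param annotation Sample annotation tibble.
#' @param metric `"signal_to_noise"` (needs >= 2 samples per group) or
#'   `"log2fc"`.
#' @return Tibble with columns `gene`, `score`, ordered by descending
#'   score; attribute `"metric"` records the metric used.
#' @export
rank_genes <- function(log_x, annotation,
                       metric = c("signal_to_noise", "log2fc")) {
  metric <- match.arg(metric)
  m <- intensity_matrix_any(log_x)
  ann <- validate_annotation(annotation, colnames(m))
  ranked_from_matrix(m, ann$group == "case", metric)
}

ranked_from_matrix <- function(m, is_case, metric) {
  mc <- m[, is_case, drop = FALSE]
  mk <- m[, !is_case, drop = FALSE]
  mu1 <- rowMeans(mc); mu2 <- rowMeans(mk)
  if (metric == "signal_to_noise") {
    if (ncol(mc) < 2L || ncol(mk) < 2L) {
      abort("signal_to_noise requires >= 2 samples per group.")
    }
    s1 <- pmax(apply(mc, 1L, sd), 0.2 * abs(mu1), 0.2)
    s2 <- pmax(apply(mk, 1L, sd), 0.2 * abs(mu2), 0.2)
    score <- (mu1 - mu2) / (s1 + s2)
  } else {
    score <- mu1 - mu2
  }
  ord <- order(-score, rownames(m))
  out <- tibble(gene = rownames(m)[ord], score = unname(score[ord]))
  attr(out, "metric") <- metric
  out
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating `|score|^p / sum_hits |score|^p` at
#' each set member ("hit") and subtracting `1 / (N - K)` at each
#' non-member. The enrichment score (ES) is the running-sum value of
#' maximal absolute deviation from zero; the leading edge contains the
#' members at or before the ES position (after it, for negative ES).
#' With `weight_p = 0` this reduces to the classic unweighted
#' Kolmogorov-Smirnov statistic (hit step `1/K`).
#'
#' @param ranked Ranked tibble from [rank_genes()] (columns `gene`,
#'   `score`).
#' @param members Character vector of set members.
#' @param weight_p Non-negative metric weight (default 1).
#' @return List with `es`, `running_sum` (length-N numeric),
#'   `leading_edge` (character), `position` (index of the extremum).
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  if (weight_p < 0) abort("`weight_p` must be >= 0.")
  members <- unique(normalize_ids(members))
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% members
  K <- sum(hit)
  if (K == 0L) abort("No set member is present in the ranked list.")
  w <- abs(ranked$score)^weight_p
  w[!hit] <- 0
  tot <- sum(w[hit])
  hit_step <- if (tot > 0) w / tot else ifelse(hit, 1 / K, 0)
  miss_step <- if (N > K) 1 / (N - K) else 0
  steps <- ifelse(hit, hit_step, -miss_step)
  running <- cumsum(steps)
  pos <- which.max(abs(running))
  es <- running[pos]
  leading <- if (es >= 0) genes[seq_len(pos)][hit[seq_len(pos)]]
             else genes[pos:N][hit[pos:N]]
  list(es = unname(es), running_sum = running, leading_edge = leading,
       position = pos)
}

# ES magnitude/sign only, from sorted hit positions -- O(K) instead of
# O(N), used for the permutation null. The running sum is piecewise linear
# and decreasing between hits, so its extrema occur immediately after a
# hit (maxima) or immediately before one (minima).
es_from_positions <- function(pos, w, N) {
  K <- length(pos)
  ord <- order(pos)
  pos <- pos[ord]
  w <- w[ord]
  tot <- sum(w)
  cw <- if (tot > 0) cumsum(w) / tot else seq_len(K) / K
  miss <- if (N > K) 1 / (N - K) else 0
  after <- cw - (pos - seq_len(K)) * miss
  before <- c(0, cw[-K]) - (pos - seq_len(K)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Permutation significance and NES for one gene set
#'
#' Builds a null ES distribution by permutation and reports a signed-side
#' p-value with the add-one estimator over the matching sign side,
#' `p = (1 + #\{same-sign null with |ES_null| >= |ES|\}) /
#' (#\{same-sign null\} + 1)` (the side-normalized convention of the
#' standard GSEA implementations, which keeps the null type-I rate at its
#' nominal level), and the normalized enrichment score
#' `NES = ES / mean(|null ES| on the matching sign side)`.
#'
#' `perm_type = "gene_set"` draws random member sets of the same size from
#' the ranked list (stable for small cohorts, the default);
#' `"phenotype"` shuffles group labels and re-ranks, which requires the
#' log-scale matrix and annotation and at least 6 samples in total.
#'
#' @param ranked Ranked tibble from [rank_genes()].
#' @param members Character vector of set members.
#' @param n_perm Number of permutations (>= 100).
#' @param perm_type `"gene_set"` or `"phenotype"`.
#' @param seed Optional integer seed; identical seeds give identical
#'   results. `NULL` uses (and advances) the current RNG stream.
#' @param weight_p Metric weight passed to [enrichment_score()].
#' @param log_x,annotation Required for phenotype permutation: the
#'   log-scale matrix and sample annotation to re-rank from.
#' @param metric Ranking metric for phenotype re-ranking.
#' @return A `gsea_result`: list with `es`, `nes`, `p_value`, `n_perm`,
#'   `leading_edge`, `running_sum`, `size` (members present in the list).
#' @export
gsea_significance <- function(ranked, members, n_perm = 1000L,
                              perm_type = c("gene_set", "phenotype"),
                              seed = NULL, weight_p = 1,
                              log_x = NULL, annotation = NULL,
                              metric = "signal_to_noise") {
  perm_type <- match.arg(perm_type)
  if (n_perm < 100L) abort("`n_perm` must be at least 100.")
  obs <- enrichment_score(ranked, members, weight_p)
  members <- unique(normalize_ids(members))
  N <- nrow(ranked)
  K <- sum(ranked$gene %in% members)

  null_es <- with_seed_if(seed, {
    if (perm_type == "gene_set") {
      absw <- abs(ranked$score)^weight_p
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(N, K)
        es_from_positions(idx, absw[idx], N)
      }, numeric(1))
    } else {
      if (is.null(log_x) || is.null(annotation)) {
        abort("Phenotype permutation needs `log_x` and `annotation`.")
      }
      m <- intensity_matrix_any(log_x)
      ann <- validate_annotation(annotation, colnames(m))
      if (ncol(m) < 6L) {
        abort("Phenotype permutation needs >= 6 samples; use perm_type = \"gene_set\".")
      }
      is_case <- ann$group == "case"
      vapply(seq_len(n_perm), function(i) {
        perm <- sample(is_case)
        rk <- ranked_from_matrix(m, perm, metric)
        idx <- which(rk$gene %in% members)
        es_from_positions(idx, abs(rk$score[idx])^weight_p, N)
      }, numeric(1))
    }
  })

  same_side <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p <- (1 + sum(abs(same_side) >= abs(obs$es))) / (length(same_side) + 1)
  denom <- if (length(same_side)) mean(abs(same_side)) else mean(abs(null_es))
  nes <- if (denom > 0) obs$es / denom else 0

  structure(list(es = obs$es, nes = nes, p_value = p, n_perm = as.integer(n_perm),
                 leading_edge = obs$leading_edge, running_sum = obs$running_sum,
                 position = obs$position, size = K, perm_type = perm_type),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (%d members, %d %s permutations)\n",
              x$es, x$nes, x$p_value, x$size, x$n_perm, x$perm_type))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gsea_result <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, p_value = x$p_value, size = x$size,
         n_perm = x$n_perm, n_leading_edge = length(x$leading_edge))
}

#' @exportS3Method generics::tidy
tidy.gsea_result <- function(x, ...) {
  tibble(position = seq_along(x$running_sum), running_sum = x$running_sum)
}

#' GSEA over a whole gene-set collection
#'
#' Runs [gsea_significance()] for every set under one shared seed stream
#' (so a singleton collection reproduces a direct call with the same
#' seed), appends BH q-values over the collection, and sorts by p-value.
#' Sets with no member in the ranked list are dropped with a warning.
#'
#' @param ranked Ranked tibble from [rank_genes()].
#' @param collection Gene-set tibble (see [read_gmt()]).
#' @param n_perm Permutations per set.
#' @param seed Optional integer seed for the shared stream.
#' @param weight_p Metric weight.
#' @param ... Passed to [gsea_significance()] (e.g. `perm_type`).
#' @return Tibble with columns `set`, `size`, `es`, `nes`, `p_value`,
#'   `q_value`, `leading_edge` (list-column), sorted by (p, set).
#' @export
run_gsea_collection <- function(ranked, collection, n_perm = 1000L,
                                seed = NULL, weight_p = 1, ...) {
  validate_collection(collection)
  if (nrow(collection) == 0L) abort("`collection` is empty.")
  present <- vapply(collection$genes,
                    function(g) any(ranked$gene %in% normalize_ids(g)),
                    logical(1))
  if (any(!present)) {
    warn(sprintf("Dropping %d set(s) with no member in the ranked list.",
                 sum(!present)))
    collection <- collection[present, , drop = FALSE]
    if (nrow(collection) == 0L) abort("No set overlaps the ranked list.")
  }
  rows <- with_seed_if(seed, {
    purrr::map(seq_len(nrow(collection)), function(i) {
      r <- gsea_significance(ranked, collection$genes[[i]], n_perm = n_perm,
                             seed = NULL, weight_p = weight_p, ...)
      tibble(set = collection$set[i], size = r$size, es = r$es, nes = r$nes,
             p_value = r$p_value, leading_edge = list(r$leading_edge))
    })
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- dplyr::relocate(out, "q_value", .after = "p_value")
  dplyr::arrange(out, .data$p_value, .data$set)
}
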