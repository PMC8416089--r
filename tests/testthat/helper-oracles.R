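# Independent oracles, deliberately written from first principles and
# kept separate from the package's code paths.

# One-tailed (case > control) Mann-Whitney p by full enumeration of all
# C(n1+n2, n1) assignments of the pooled values to the case group.
# Assumes no ties.
mwu_enum_p <- function(case, control, alternative = "greater") {
  pooled <- c(case, control)
  n1 <- length(case)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2L, u_of)
  switch(alternative,
         greater = mean(us >= u_obs),
         less = mean(us <= u_obs),
         two.sided = min(1, 2 * min(mean(us >= u_obs), mean(us <= u_obs))))
}

# Upper-tail hypergeometric probability P(X >= k) by direct pmf summation.
hyper_tail_p <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Brute-force weighted running-sum enrichment score via an explicit loop.
es_brute <- function(scores_desc, is_hit, p = 1) {
  N <- length(scores_desc)
  K <- sum(is_hit)
  denom <- sum(abs(scores_desc[is_hit])^p)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      acc <- acc + (if (denom > 0) abs(scores_desc[i])^p / denom else 1 / K)
    } else {
      acc <- acc - 1 / (N - K)
    }
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# Unweighted (classic Kolmogorov-Smirnov) enrichment score: hit step 1/K.
es_unweighted <- function(is_hit) {
  N <- length(is_hit); K <- sum(is_hit)
  run <- cumsum(ifelse(is_hit, 1 / K, -1 / (N - K)))
  run[which.max(abs(run))]
}

# Small intensity tibble from a named list of sample vectors.
toy_matrix <- function(proteins, ...) {
  cols <- list(...)
  dplyr::bind_cols(tibble::tibble(protein = proteins), tibble::as_tibble(cols))
}

toy_annotation <- function(case, control) {
  tibble::tibble(sample = c(case, control),
                 group = rep(c("case", "control"), c(length(case), length(control))))
}

# Random intensity tibble with all-positive entries (no dropout).
random_matrix <- function(n_prot, samples) {
  m <- matrix(stats::rexp(n_prot * length(samples)) + 0.01, n_prot,
              dimnames = list(NULL, samples))
  dplyr::bind_cols(tibble::tibble(protein = sprintf("P%03d", seq_len(n_prot))),
                   tibble::as_tibble(m))
}
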