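ranked_tbl <- function(genes, scores) tibble::tibble(gene = genes, score = scores)

test_that("rank_genes computes metrics, breaks ties by symbol, ignores row order", {
  m <- toy_matrix(c("B", "A"), K1 = c(1, 3), K2 = c(3, 1), C1 = c(1, 3), C2 = c(3, 1))
  ann <- toy_annotation(c("K1", "K2"), c("C1", "C2"))
  rk <- rank_genes(m, ann, metric = "log2fc")
  expect_equal(rk$score, c(0, 0))
  expect_equal(rk$gene, c("A", "B"))  # tie broken by symbol

  # hand-computed signal-to-noise on a 2-gene 2v2 toy
  m2 <- toy_matrix(c("G1", "G2"),
                   K1 = c(1, 0), K2 = c(3, 2), C1 = c(0, 1), C2 = c(2, 3))
  sn <- rank_genes(m2, ann, metric = "signal_to_noise")
  s <- sqrt(2)  # sd of each pair; floors max(0.2*|mean|, 0.2) inactive
  expect_equal(sn$score[sn$gene == "G1"], (2 - 1) / (s + s), tolerance = 1e-12)
  expect_equal(sn$score[sn$gene == "G2"], (1 - 2) / (s + s), tolerance = 1e-12)

  shuffled <- m2[c(2, 1), ]
  expect_equal(rank_genes(shuffled, ann, metric = "signal_to_noise"), sn)
  expect_error(rank_genes(toy_matrix("G", K1 = 1, C1 = 2),
                          toy_annotation("K1", "C1")), "2 samples|sample")
})

test_that("enrichment_score reproduces hand-computed running sums", {
  rk <- ranked_tbl(paste0("G", 1:5), c(5, 4, 3, 2, 1))
  top <- enrichment_score(rk, "G1")
  expect_equal(top$es, 1)
  expect_equal(top$running_sum[1], 1)
  expect_equal(top$leading_edge, "G1")

  bottom <- enrichment_score(rk, "G5")
  expect_equal(bottom$running_sum, c(-0.25, -0.5, -0.75, -1, 0))
  expect_equal(bottom$es, -1)
  expect_equal(bottom$leading_edge, "G5")
  expect_error(enrichment_score(rk, "ABSENT"), "No set member")
})

test_that("ES matches a brute-force oracle and stays within [-1, 1]", {
  set.seed(61)
  for (i in 1:200) {
    N <- sample(20:150, 1)
    genes <- sprintf("G%03d", seq_len(N))
    scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    members <- sample(genes, sample(2:12, 1))
    rk <- ranked_tbl(genes, scores)
    es <- enrichment_score(rk, members)$es
    expect_equal(es, es_brute(scores, genes %in% members), tolerance = 1e-12)
    expect_gte(es, -1); expect_lte(es, 1)
  }
})

test_that("weight 0 reduces to the classic unweighted KS statistic", {
  set.seed(62)
  for (i in 1:25) {
    N <- 60
    genes <- sprintf("G%03d", 1:N)
    rk <- ranked_tbl(genes, sort(rnorm(N), decreasing = TRUE))
    members <- sample(genes, 8)
    expect_equal(enrichment_score(rk, members, weight_p = 0)$es,
                 es_unweighted(genes %in% members), tolerance = 1e-12)
  }
})

test_that("ES agrees with an independent reference implementation", {
  set.seed(63)
  for (i in 1:50) {
    N <- sample(50:200, 1)
    genes <- sprintf("G%03d", seq_len(N))
    scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    members <- sample(genes, sample(3:15, 1))
    ours <- enrichment_score(ranked_tbl(genes, scores), members)$es
    ref <- fgsea::calcGseaStat(stats::setNames(scores, genes),
                               selectedStats = which(genes %in% members),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("negating and reversing the ranked list negates the ES", {
  set.seed(64)
  for (i in 1:20) {
    N <- 80
    genes <- sprintf("G%03d", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    members <- sample(genes, 6)
    es <- enrichment_score(ranked_tbl(genes, scores), members)$es
    es_rev <- enrichment_score(ranked_tbl(rev(genes), rev(-scores)), members)$es
    expect_equal(es_rev, -es, tolerance = 1e-12)
  }
})

test_that("gsea_significance is seeded, bounded, and finds a planted set", {
  set.seed(65)
  genes <- sprintf("G%04d", 1:1000)
  rk <- ranked_tbl(genes, sort(rnorm(1000, sd = 1.5), decreasing = TRUE))
  planted <- sample(genes[1:100], 20)  # all members in the top decile
  r1 <- gsea_significance(rk, planted, n_perm = 1000, seed = 99)
  r2 <- gsea_significance(rk, planted, n_perm = 1000, seed = 99)
  expect_identical(r1, r2)
  expect_lte(r1$p_value, 0.01)
  expect_gt(r1$nes, 0)
  expect_gte(r1$p_value, 1 / 1001)

  rand <- gsea_significance(rk, sample(genes, 20), n_perm = 200, seed = 1)
  expect_gte(rand$p_value, 1 / 201)
  expect_error(gsea_significance(rk, planted, n_perm = 50), "n_perm")
})

test_that("phenotype permutation re-ranks labels and guards tiny cohorts", {
  ch <- generate_cohort(cohort_config(n_proteins = 150, n_case = 5, n_control = 5,
                                      n_up = 15, n_down = 5, seed = 66,
                                      dropout_slope = 0, dropout_intercept = Inf))
  logm <- log_transform(ifot_normalize(ch$matrix))
  rk <- rank_genes(logm, ch$annotation)
  r <- gsea_significance(rk, ch$truth$up_proteins, n_perm = 100,
                         perm_type = "phenotype", seed = 5,
                         log_x = logm, annotation = ch$annotation)
  expect_gt(r$es, 0)
  expect_lte(r$p_value, 0.1)

  tiny <- generate_cohort(cohort_config(n_proteins = 50, n_case = 3, n_control = 2,
                                        n_up = 5, n_down = 0, seed = 67))
  tl <- log_transform(ifot_normalize(tiny$matrix))
  trk <- rank_genes(tl, tiny$annotation, metric = "log2fc")
  expect_error(gsea_significance(trk, tiny$truth$up_proteins, n_perm = 100,
                                 perm_type = "phenotype", seed = 1,
                                 log_x = tl, annotation = tiny$annotation),
               "gene_set")
})

test_that("run_gsea_collection is consistent with single-set runs and ranks planted sets first", {
  set.seed(68)
  genes <- sprintf("G%04d", 1:500)
  rk <- ranked_tbl(genes, sort(rnorm(500, sd = 1.5), decreasing = TRUE))
  members <- sample(genes, 15)
  single <- run_gsea_collection(rk, tibble::tibble(set = "ONLY", description = "",
                                                   genes = list(members)),
                                n_perm = 200, seed = 7)
  direct <- gsea_significance(rk, members, n_perm = 200, seed = 7)
  expect_equal(single$es, direct$es)
  expect_equal(single$p_value, direct$p_value)
  expect_equal(single$nes, direct$nes)

  wins <- 0L
  for (s in 1:20) {
    set.seed(800 + s)
    scores <- sort(rnorm(500, sd = 1.5), decreasing = TRUE)
    rk2 <- ranked_tbl(genes, scores)
    coll <- tibble::tibble(
      set = c("PLANTED", sprintf("R%02d", 1:5)), description = "",
      genes = c(list(sample(genes[1:50], 15)),
                replicate(5, sample(genes, 15), simplify = FALSE)))
    g <- run_gsea_collection(rk2, coll, n_perm = 200, seed = 900 + s)
    if (g$set[1] == "PLANTED") wins <- wins + 1L
  }
  expect_gte(wins, 18L)

  absent <- tibble::tibble(set = c("OK", "GONE"), description = "",
                           genes = list(members, c("NOPE1", "NOPE2")))
  expect_warning(g2 <- run_gsea_collection(rk, absent, n_perm = 100, seed = 1),
                 "Dropping")
  expect_equal(g2$set, "OK")
})
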