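test_that("partition_by_detection does the Fig-1A set algebra", {
  # case detects {A,B,C,D}, control detects {C,D,E}, F nowhere
  m <- toy_matrix(c("A", "B", "C", "D", "E", "F"),
                  K1 = c(1, 1, 1, 1, 0, 0), K2 = c(1, 0, 1, 1, 0, 0),
                  C1 = c(0, 0, 1, 1, 1, 0), C2 = c(0, 0, 1, 0, 1, 0))
  part <- partition_by_detection(m, toy_annotation(c("K1", "K2"), c("C1", "C2")))
  expect_setequal(part$only_case, c("A", "B"))
  expect_setequal(part$only_control, "E")
  expect_setequal(part$shared, c("C", "D"))
  expect_setequal(part$undetected, "F")
  expect_error(partition_by_detection(m, toy_annotation(c("K1", "K2"), c("C1", "C2")),
                                      min_detect = 3), "min_detect")
})

test_that("the partition is a disjoint cover on random dropout matrices", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    m <- random_matrix(n, c("K1", "K2", "K3", "C1", "C2"))
    vals <- as.matrix(m[-1])
    vals[sample(length(vals), length(vals) %/% 3)] <- 0
    m[-1] <- tibble::as_tibble(vals)
    part <- partition_by_detection(m, toy_annotation(c("K1", "K2", "K3"), c("C1", "C2")))
    all_ids <- c(part$only_case, part$only_control, part$shared, part$undetected)
    expect_equal(sort(all_ids), sort(m$protein))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("Welch test matches the textbook implementation and handles degeneracy", {
  m <- toy_matrix("A", K1 = -10, K2 = -9, K3 = -11,
                  C1 = -14, C2 = -13, C3 = -15)
  ann <- toy_annotation(c("K1", "K2", "K3"), c("C1", "C2", "C3"))
  part <- list(shared = "A")
  res <- test_shared_proteins(m, ann, part)
  oracle <- stats::t.test(c(-10, -9, -11), c(-14, -13, -15))
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)

  flat <- toy_matrix("A", K1 = 2, K2 = 2, C1 = 2, C2 = 2)
  rf <- test_shared_proteins(flat, toy_annotation(c("K1", "K2"), c("C1", "C2")), part)
  expect_equal(rf$p_value, 1)

  sep <- toy_matrix("A", K1 = 3, K2 = 3, C1 = 2, C2 = 2)
  rs <- test_shared_proteins(sep, toy_annotation(c("K1", "K2"), c("C1", "C2")), part)
  expect_equal(rs$p_value, 0)
})

test_that("null p-values are uniform for both test methods", {
  set.seed(32)
  n <- 1000
  vals <- matrix(rnorm(n * 12), n)
  colnames(vals) <- c(paste0("K", 1:6), paste0("C", 1:6))
  m <- dplyr::bind_cols(tibble::tibble(protein = sprintf("P%04d", 1:n)),
                        tibble::as_tibble(vals))
  ann <- toy_annotation(paste0("K", 1:6), paste0("C", 1:6))
  part <- list(shared = m$protein)
  p_welch <- test_shared_proteins(m, ann, part)$p_value
  expect_gt(stats::ks.test(p_welch, "punif")$p.value, 0.01)
})

test_that("bh_adjust implements step-up BH", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 7)), rep(0.04, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("compute_fold_change matches closed forms", {
  ann <- toy_annotation(c("K1", "K2"), c("C1", "C2"))
  eq <- toy_matrix("A", K1 = 0.3, K2 = 0.5, C1 = 0.4, C2 = 0.4)
  expect_equal(compute_fold_change(eq, ann)$log2fc, 0, tolerance = 1e-6)

  quad <- toy_matrix("A", K1 = 0.4, K2 = 0.4, C1 = 0.1, C2 = 0.1)
  expect_equal(compute_fold_change(quad, ann)$log2fc, 2, tolerance = 1e-6)

  excl <- toy_matrix("A", K1 = 1e-4, K2 = 1e-4, C1 = 0, C2 = 0)
  expect_equal(compute_fold_change(excl, ann, 1e-8)$log2fc,
               log2((1e-4 + 1e-8) / 1e-8), tolerance = 1e-9)
})

test_that("define_signature applies threshold, union, and stays deterministic", {
  dt <- tibble::tibble(
    protein = sprintf("P%d", 1:7),
    log2fc = c(2, 1.5, 0.8, -2, 3, 4, -1),
    p_value = c(0.001, 0.002, 0.5, 0.001, NA, NA, NA),
    q_value = c(0.01, 0.02, 0.7, 0.01, NA, NA, NA),
    status = c("up", "up", "ns", "down", "case_only", "case_only", "control_only"))
  sig <- define_signature(dt, alpha = 0.05, include_exclusive = FALSE)
  expect_setequal(sig$up, c("P1", "P2"))
  expect_setequal(sig$down, "P4")

  sig2 <- define_signature(dt, alpha = 0.05, include_exclusive = TRUE)
  expect_setequal(sig2$up, c("P1", "P2", "P5", "P6"))
  expect_setequal(sig2$down, c("P4", "P7"))

  none <- define_signature(dplyr::mutate(dt, q_value = ifelse(is.na(q_value), NA, 0.9)))
  expect_length(none$up, 0)
  expect_error(define_signature(dt, alpha = 1.2), "alpha")
})

test_that("swapping group labels mirrors the signature and negates fold changes", {
  ch <- generate_cohort(cohort_config(n_proteins = 200, n_case = 6, n_control = 6,
                                      n_up = 15, n_down = 10, seed = 33))
  ifot <- ifot_normalize(ch$matrix)
  swapped <- dplyr::mutate(ch$annotation,
                           group = ifelse(group == "case", "control", "case"))
  d1 <- differential_table(ifot, ch$annotation)
  d2 <- differential_table(ifot, swapped)
  j <- dplyr::inner_join(d1, d2, by = "protein")
  expect_equal(j$log2fc.x, -j$log2fc.y, tolerance = 1e-9)
  s1 <- define_signature(d1, include_exclusive = TRUE)
  s2 <- define_signature(d2, include_exclusive = TRUE)
  expect_setequal(s1$up, s2$down)
  expect_setequal(s1$down, s2$up)
})
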