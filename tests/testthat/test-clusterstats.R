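test_that("pointwise above-chance test is one-tailed and exact at chance", {
  acc <- matrix(0.5, 10, 50)
  expect_false(any(pointwise_above_chance(acc)))
  set.seed(20)
  acc2 <- matrix(0.5 + rnorm(20 * 60, sd = 0.002), 20, 60)
  acc2[, 21:40] <- 0.75 + rnorm(20 * 20, sd = 0.002)
  mask <- pointwise_above_chance(acc2)
  expect_true(all(mask[21:40]))
  expect_true(sum(mask[-(21:40)]) <= 4)      # alpha-level leakage only
  expect_false(any(pointwise_above_chance(matrix(0.3, 10, 30))))
  expect_error(pointwise_above_chance(matrix(0.6, 1, 10)), "2 subjects")
})

test_that("cluster finding equals an exhaustive scan", {
  m <- rep(FALSE, 50); m[10:20] <- TRUE; m[40:41] <- TRUE
  cl <- find_clusters(m)
  expect_equal(cl$size, c(11L, 2L))
  expect_equal(cl$start, c(10L, 40L))
  expect_equal(nrow(find_clusters(rep(FALSE, 30))), 0L)
  set.seed(21)
  for (i in 1:25) {
    mask <- runif(40) > 0.6
    cl <- find_clusters(mask)
    # brute force: scan every index
    sizes <- integer(0); run <- 0L
    for (t in seq_along(mask)) {
      if (mask[t]) run <- run + 1L
      if ((!mask[t] || t == length(mask)) && run > 0) {
        sizes <- c(sizes, run); run <- 0L
      }
    }
    expect_equal(cl$size, sizes)
    expect_true(all(mask[unlist(Map(seq, cl$start, cl$end))]))
  }
})

test_that("sign-flip permutation null is reproducible and detects effects", {
  set.seed(22)
  acc <- matrix(0.5 + rnorm(12 * 80, sd = 0.05), 12, 80)
  r1 <- permutation_null_single(acc, n_perm = 200, seed = 5)
  r2 <- permutation_null_single(acc, n_perm = 200, seed = 5)
  expect_identical(r1, r2)
  expect_error(permutation_null_single(acc, n_perm = 0), "n_perm")

  eff <- acc
  eff[, 30:50] <- eff[, 30:50] + 0.1
  re <- permutation_null_single(eff, n_perm = 200, seed = 6)
  big <- re$clusters[which.max(re$clusters$size), ]
  expect_lte(big$p_value, 2 / 201)           # minimal attainable region
  expect_true(big$start <= 31 && big$end >= 49)
  # every reported p respects the permutation smoothing floor
  expect_true(all(re$clusters$p_value >= 1 / 201))
})

test_that("Bonferroni gate reproduces the 39-ROI threshold", {
  expect_true(bonferroni_gate(0.001, n_rois = 39))
  expect_false(bonferroni_gate(0.0013, n_rois = 39))
  expect_equal(bonferroni_gate(c(0.04, 0.06), n_rois = 1),
               c(TRUE, FALSE))
})

test_that("between-condition clusters need both above-chance and difference", {
  set.seed(23)
  A <- matrix(0.5 + rnorm(10 * 60, sd = 0.03), 10, 60)
  res_eq <- between_condition_clusters(A, A, n_perm = 100, seed = 7)
  expect_equal(nrow(res_eq$clusters_A_gt_B), 0L)
  expect_equal(nrow(res_eq$clusters_B_gt_A), 0L)

  # both conditions share the same strong signal: difference gate fails
  shared <- A; shared[, 20:40] <- shared[, 20:40] + 0.3
  shared_B <- shared + matrix(rnorm(length(shared), sd = 0.01), nrow(shared))
  res_sh <- between_condition_clusters(shared, shared_B, n_perm = 100,
                                       seed = 8)
  expect_true(all(res_sh$clusters_A_gt_B$size < 5))
  expect_true(all(res_sh$clusters_B_gt_A$size < 5))

  # A-only effect in 20:40 produces an A>B cluster there and none for B>A
  B2 <- matrix(0.5 + rnorm(10 * 60, sd = 0.05), 10, 60)
  Aeff <- B2 + matrix(rnorm(length(B2), sd = 0.05), nrow(B2))
  Aeff[, 20:40] <- Aeff[, 20:40] + 0.15
  res <- between_condition_clusters(Aeff, B2, n_perm = 200, seed = 9)
  main <- res$clusters_A_gt_B[which.max(res$clusters_A_gt_B$size), ]
  expect_gte(main$size, 15L)
  expect_lte(main$p_value, 0.01)
  expect_true(all(res$clusters_B_gt_A$size <= 3))
  expect_error(between_condition_clusters(A, A[, 1:10]), "identical dimensions")
})

test_that("larger injected effects never shrink the recovered cluster", {
  set.seed(24)
  base <- matrix(0.5 + rnorm(12 * 60, sd = 0.05), 12, 60)
  sizes <- sapply(c(0.05, 0.1, 0.2, 0.4), function(amp) {
    acc <- base
    acc[, 25:45] <- acc[, 25:45] + amp
    cl <- find_clusters(pointwise_above_chance(acc))
    if (nrow(cl) == 0) 0L else max(cl$size)
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("cluster_test assembles records across an ROI family", {
  set.seed(25)
  acc <- array(0.5 + rnorm(12 * 3 * 60, sd = 0.05), c(12, 3, 60))
  acc[, 2, 20:45] <- acc[, 2, 20:45] + 0.1
  time <- seq(-100, 1080, by = 20)
  recs <- cluster_test(acc, time, n_perm = 200, seed = 10,
                       n_rois_family = 3)
  sig <- recs[recs$significant, ]
  expect_true("roi_2" %in% sig$roi)
  expect_false(any(c("roi_1", "roi_3") %in% sig$roi))
  expect_true(all(recs$start_ms <= recs$end_ms))
  expect_s3_class(recs, "cluster_records")
  tmp <- tempfile(fileext = ".tsv")
  write_cluster_records(recs, tmp)
  expect_equal(nrow(read.table(tmp, header = TRUE, sep = "\t")), nrow(recs))
})
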