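test_that("lagged design matrices are built correctly", {
  M <- cbind(1:6, 11:16)
  Phi <- lexidecode:::make_lags(M, 2L)
  expect_equal(dim(Phi), c(4L, 4L))
  # row t predicts sample t+order: lags 1..2 of each channel
  expect_equal(Phi[1, ], c(2, 1, 12, 11))
  expect_equal(Phi[4, ], c(5, 4, 15, 14))
  expect_equal(lexidecode:::lag_cols(2L, 3L), 4:6)
})

test_that("GC index detects directed coupling and agrees with the OLS oracle", {
  sig_c <- make_signals(6, 150, coupled = TRUE, seed = 30)
  kal_fwd <- kal_rev <- ols_fwd <- ols_rev <- numeric(6)
  for (si in 1:6) {
    s <- sig_c[[si]]
    src <- s$map$column[s$map$roi == 2]
    non <- s$map$column[s$map$roi == 3]
    kal_fwd[si] <- mean(kalman_mvar_gc(s$target, s$pred, src, order = 3,
                                       adapt_const = 0.05)$gc)
    kal_rev[si] <- mean(kalman_mvar_gc(s$target, s$pred, non, order = 3,
                                       adapt_const = 0.05)$gc)
    ols_fwd[si] <- lexidecode:::ols_gc(s$target, s$pred, src, order = 3)
    ols_rev[si] <- lexidecode:::ols_gc(s$target, s$pred, non, order = 3)
  }
  expect_gt(mean(kal_fwd), mean(kal_rev))
  expect_gt(mean(ols_fwd), mean(ols_rev))
  # ranking agreement between the adaptive estimator and the oracle
  expect_equal(order(c(mean(kal_fwd), mean(kal_rev))),
               order(c(mean(ols_fwd), mean(ols_rev))))
  # determinism
  s <- sig_c[[1]]
  g1 <- kalman_mvar_gc(s$target, s$pred, 1:8, order = 3)
  g2 <- kalman_mvar_gc(s$target, s$pred, 1:8, order = 3)
  expect_identical(g1, g2)
  expect_true(all(g1$gc >= 0))
  # errors
  bad <- s$pred; bad[3, 1] <- NA
  expect_error(kalman_mvar_gc(s$target, bad, 1:8, order = 3), "non-finite")
  expect_error(kalman_mvar_gc(s$target[1:8], s$pred[1:8, ], 1:8, order = 5),
               "too short")
})

test_that("surrogate thresholding is calibrated on stationary null signals", {
  hits <- 0L; total <- 0L
  for (rep in 1:6) {
    sig <- make_signals(6, 120, coupled = FALSE, seed = 40 + rep)
    cur <- lexidecode:::gc_pair_curves(sig, 2, 3L, 0.05, 1.0, 100L, TRUE,
                                       40 + rep,
                                       surrogate = "circular_shift")
    mask <- gc_significance(cur$gc_raw, cur$surrogates, alpha = 0.05)
    hits <- hits + sum(mask[cur$win])
    total <- total + sum(cur$win)
  }
  frac <- hits / total
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / total) + 0.02)
})

test_that("gc_significance applies quantile thresholds and degenerate alphas", {
  set.seed(31)
  surr <- matrix(runif(150 * 20), 150, 20)
  obs <- apply(surr, 2, max) + 1
  expect_true(all(gc_significance(obs, surr, 0.05)))
  expect_true(all(gc_significance(rep(-1, 20), surr, alpha = 1)))
  expect_false(any(gc_significance(rep(-1, 20), surr, 0.05)))
  expect_error(gc_significance(obs, surr[1:50, ], 0.05), "100 surrogates")
  expect_error(gc_significance(obs[1:5], surr, 0.05), "mismatch")
})

test_that("binomial test against the control rate matches direct summation", {
  p <- binomial_vs_control(60, 301, 15 / 301)
  direct <- sum(dbinom(60:301, 301, 15 / 301))
  expect_lt(abs(p - direct), 1e-12)
  expect_equal(binomial_vs_control(0, 301, 0.05), 1.0)
  expect_lt(binomial_vs_control(301, 301, 0.05), 1e-100)
  expect_error(binomial_vs_control(302, 301, 0.05), "exceeds")
  expect_error(binomial_vs_control(10, 301, 0), "control_rate")
  expect_error(binomial_vs_control(10, 301, 1), "control_rate")
})

test_that("Benjamini-Hochberg flags match hand-computed thresholds", {
  # thresholds for m = 3 at q = 0.05: 0.0167, 0.0333, 0.05
  expect_equal(fdr_correct(c(0.001, 0.2, 0.9)), c(TRUE, FALSE, FALSE))
  expect_equal(fdr_correct(c(0.016, 0.033, 0.049)), c(TRUE, TRUE, TRUE))
  expect_true(all(fdr_correct(rep(0.001, 20))))
  expect_identical(fdr_correct(numeric(0)), logical(0))
  set.seed(32)
  p <- runif(50)
  expect_equal(fdr_correct(p, q = 0.1), p.adjust(p, "BH") <= 0.1)
})

test_that("node assembly substitutes accuracy for the target ROI", {
  cfg <- design_config(n_subjects = 1L, n_rois = 2L, sample_rate = 1000,
                       seed = 81L)
  tr <- ground_truth(cfg)
  ep <- prepped_epochs(cfg, tr, seed = 14L)
  Tn <- length(ep[[1]]$time)
  dec <- list(acc = array(runif(1 * 2 * 1 * Tn, 0.4, 0.6),
                          c(1, 2, 1, Tn)),
              conditions = "words_only", rois = 1:2, chance = 0.5)
  sig <- assemble_node_signals(ep, dec, target_roi = 2,
                               window = c(250, 550), burn_ms = 100,
                               demean = "none")
  s <- sig[[1]]
  expect_equal(sum(s$win), 301L)             # inclusive 250..550 at 1 kHz
  expect_equal(ncol(s$pred), 8L)             # (n_rois - 1) x 8 subdivisions
  expect_true(all(s$map$roi == 1))
  expect_lt(abs(mean(s$target[s$win])), 1e-9)
  expect_lt(abs(sd(s$target[s$win]) - 1), 1e-9)
  expect_lt(max(abs(colMeans(s$pred[s$win, ]))), 1e-9)
  expect_error(assemble_node_signals(ep, dec, 2, decoding_rois = c(1)),
               "not in the candidate")
  expect_error(assemble_node_signals(ep, dec, 2, condition = "vc_overlap"),
               "lacks condition")
})
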