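test_that("single-timepoint SVM behaves on separable data", {
  set.seed(10)
  tr_x <- rbind(matrix(rnorm(40, mean = 3), 5, 8),
                matrix(rnorm(40, mean = -3), 5, 8))
  tr_y <- rep(c("A", "B"), each = 5)
  te_x <- rbind(matrix(rnorm(24, mean = 3), 3, 8),
                matrix(rnorm(24, mean = -3), 3, 8))
  te_y <- rep(c("A", "B"), each = 3)
  expect_equal(train_test_timepoint(tr_x, tr_y, te_x, te_y), 1.0)
  expect_equal(train_test_timepoint(tr_x, tr_y, te_x, rev(te_y)), 0.0)
  expect_error(train_test_timepoint(tr_x, rep("A", 10), te_x, te_y),
               "exactly 2 classes")
  expect_error(train_test_timepoint(tr_x, tr_y, te_x[, 1:4], te_y),
               "dimension mismatch")
})

test_that("label-shuffled training gives chance accuracy", {
  set.seed(11)
  n_draw <- 200
  acc <- replicate(n_draw, {
    X <- matrix(rnorm(96), 12, 8)
    y <- sample(rep(c("A", "B"), 6))
    Xt <- matrix(rnorm(64), 8, 8)
    yt <- rep(c("A", "B"), 4)
    train_test_timepoint(X, y, Xt, yt)
  })
  se <- sd(acc) / sqrt(n_draw)
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 1e-12)
})

test_that("internal SMO solver matches libsvm (e1071) on random problems", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(6:16, 1)
    X <- matrix(rnorm(n * 8), n, 8)
    y <- c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))
    fit <- lexidecode:::cpp_svm_fit(X, y)
    ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1, scale = FALSE)
    w_ref <- drop(t(ref$coefs) %*% ref$SV)
    b_ref <- -ref$rho
    obj <- function(w, b)
      0.5 * sum(w^2) + sum(pmax(0, 1 - y * (X %*% w + b)))
    expect_lt(max(abs(fit$w - w_ref)), 0.05)
    expect_lt(abs(obj(fit$w, fit$b) - obj(w_ref, b_ref)), 0.01)
  }
})

test_that("pair aggregation averages all 15 neighborhood contrasts", {
  pairs <- apply(combn(0:5, 2), 2, paste, collapse = "-")
  expect_length(pairs, 15L)
  const <- array(0.6, c(2, 15, 10), dimnames = list(NULL, pairs, NULL))
  expect_true(all(aggregate_pairs(const) == 0.6))
  set.seed(13)
  rnd <- array(runif(2 * 15 * 10), c(2, 15, 10),
               dimnames = list(NULL, pairs, NULL))
  brute <- apply(rnd, c(1, 3), mean)
  expect_lt(max(abs(aggregate_pairs(rnd) - brute)), 1e-12)
  expect_error(aggregate_pairs(rnd[, 1:14, , drop = FALSE]),
               "missing pair.*4-5")
  lst <- setNames(lapply(pairs, function(p) rep(0.6, 10)), pairs)
  expect_equal(aggregate_pairs(lst), rep(0.6, 10))
  expect_error(aggregate_pairs(lst[-3]), "missing pair")
})

test_that("transfer decoding recovers injected structure in its window only", {
  cfg <- small_config(n_subjects = 2L, seed = 61L)
  tr <- ground_truth(cfg, lexical_amp = c(2.5, 0),
                     lexical_window = c(400, 600),
                     segmental_amp = c(0, 1.5))
  ep <- prepped_epochs(cfg, tr, seed = 6L)
  st <- build_stimulus_set(cfg)
  dec <- decode_study(ep, st,
                      conditions = c("words_only", "nonwords_only",
                                     "cv_overlap"),
                      n_assignments = 5, seed = 9L)
  tm <- dec$time
  lex_win <- tm > 430 & tm <= 600
  pre <- tm > -100 & tm <= 0
  stim_win <- tm > 50 & tm <= 350

  # lexical ROI, word training: strong transfer inside the window ...
  expect_gt(mean(dec$acc[, 1, 1, lex_win]), 0.9)
  # ... and chance outside any signal window
  expect_lt(abs(mean(dec$acc[, 1, 1, pre]) - 0.5), 0.05)
  # nonword neighbors carry no lexical pattern: post-offset chance
  nw <- dec$acc[, 1, 2, lex_win]
  expect_lt(abs(mean(nw) - 0.5), 3 * sd(nw) / sqrt(length(nw)) + 0.02)
  # segmental ROI, CV training: above chance only during the stimulus
  expect_gt(mean(dec$acc[, 2, 3, stim_win]), 0.7)
  expect_lt(abs(mean(dec$acc[, 2, 3, lex_win]) - 0.5), 0.05)
  expect_true(all(dec$acc >= 0 & dec$acc <= 1))

  # long-format export round-trips values
  tmp <- tempfile(fileext = ".tsv")
  write_decoding_tsv(dec, tmp)
  long <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(nrow(long), length(dec$acc))
  expect_equal(long$accuracy[1], dec$acc[1, 1, 1, 1])
})

test_that("hub trials never enter training and pair labels are symmetric", {
  cfg <- small_config(n_subjects = 1L, n_rois = 1L, seed = 71L)
  tr <- ground_truth(cfg, lexical_amp = 1.5)
  ep <- prepped_epochs(cfg, tr, seed = 7L)[[1]]
  st <- build_stimulus_set(cfg)
  bins <- make_decoding_bins(ep, st, "words_only", n_assignments = 2,
                             seed = 8L)
  for (asg in bins$assignments) {
    train_idx <- unlist(asg[grep("^train_", names(asg))])
    hub_idx <- unlist(asg[grep("^hub_", names(asg))])
    expect_length(intersect(train_idx, hub_idx), 0L)
    expect_true(all(ep$trials$role[unlist(asg$train_0)] == "neighbor"))
    expect_true(all(ep$trials$role[hub_idx] == "hub"))
  }
  a01 <- transfer_decode(ep, 1, c(0, 1), bins)
  a10 <- transfer_decode(ep, 1, c(1, 0), bins)
  expect_equal(a01, a10)
  expect_error(transfer_decode(ep, 1, c(1, 1), bins), "distinct")
  # corrupted bins with a hub trial in training must be caught
  bad <- bins
  bad$assignments[[1]]$train_0[[1]][1] <-
    bad$assignments[[1]]$hub_0[[1]][1]
  expect_error(transfer_decode(ep, 1, c(0, 1), bad), "transfer integrity")
})
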