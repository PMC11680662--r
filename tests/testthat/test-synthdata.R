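test_that("epoch length follows the closed-interval sampling convention", {
  cfg <- design_config(n_subjects = 1L, n_rois = 1L, sample_rate = 1000)
  tr <- ground_truth(cfg)
  ep <- simulate_epochs(make_schedule(cfg, 1L), tr, cfg)[[1]]
  expect_equal(dim(ep$data)[3], 1101L)
  expect_equal(ep$time[101], 0)
  expect_equal(range(ep$time), c(-100, 1000))
})

test_that("zero-amplitude truth yields pure noise", {
  cfg <- small_config(seed = 21L)
  tr <- ground_truth(cfg, noise_sd = 1, talker_offset_sd = 0)
  ep <- simulate_epochs(make_schedule(cfg, 2L), tr, cfg)[[1]]
  n_tr <- dim(ep$data)[1]
  ch_means <- rowMeans(colMeans(ep$data))     # per-channel grand mean
  se <- 1 / sqrt(n_tr * dim(ep$data)[3])
  expect_true(all(abs(ch_means) < 4 * se))
})

test_that("lexical patterns are shared by hub and word neighbors only", {
  cfg <- small_config(seed = 31L)
  tr <- ground_truth(cfg, lexical_amp = c(3, 0), lexical_window = c(400, 600))
  st <- build_stimulus_set(cfg)
  ep <- simulate_epochs(make_schedule(cfg, 3L, st), tr, cfg, st)[[1]]
  win <- ep$time > 400 & ep$time <= 600
  mean_pat <- function(rows) {
    m <- colMeans(ep$data[rows, 1:cfg$n_subdivisions, win, drop = FALSE])
    rowMeans(m)
  }
  tm <- ep$trials
  for (nb in 0:1) {
    hub <- mean_pat(which(tm$neighborhood_id == nb & tm$role == "hub"))
    wn <- mean_pat(which(tm$neighborhood_id == nb & tm$role == "neighbor" &
                           tm$lexicality == "word"))
    nn <- mean_pat(which(tm$neighborhood_id == nb & tm$role == "neighbor" &
                           tm$lexicality == "nonword"))
    expect_gt(cor(hub, wn), cor(hub, nn))
    expect_gt(cor(hub, wn), 0.5)
  }
  # with noise off, nonword neighbors carry no in-window signal at all
  tr0 <- ground_truth(cfg, lexical_amp = c(3, 0),
                      lexical_window = c(400, 600), noise_sd = 1e-8,
                      talker_offset_sd = 0)
  ep0 <- simulate_epochs(make_schedule(cfg, 3L, st), tr0, cfg, st)[[1]]
  nn_rows <- which(ep0$trials$lexicality == "nonword")
  hub_rows <- which(ep0$trials$role == "hub")
  expect_lt(max(abs(ep0$data[nn_rows, 1:8, win])), 1e-6)
  expect_gt(mean(abs(ep0$data[hub_rows, 1:8, win])), 0.1)
})

test_that("signal injection is window-limited", {
  cfg <- small_config(seed = 41L)
  tr <- ground_truth(cfg, lexical_amp = c(2, 0), lexical_window = c(400, 600),
                     talker_offset_sd = 0)
  ep <- simulate_epochs(make_schedule(cfg, 4L), tr, cfg)[[1]]
  d <- cfg$n_subdivisions
  outside <- ep$time > 600 | (ep$time > 0 & ep$time <= 350)
  v_sig <- var(as.numeric(ep$data[, 1:d, outside]))
  v_null <- var(as.numeric(ep$data[, d + 1:d, outside]))
  expect_lt(abs(v_sig / v_null - 1), 0.05)
})

test_that("simulation is bit-reproducible", {
  cfg <- small_config(n_subjects = 1L, seed = 51L)
  tr <- ground_truth(cfg, lexical_amp = 1, segmental_amp = 0.5)
  sch <- make_schedule(cfg, 5L)
  e1 <- simulate_epochs(sch, tr, cfg)
  e2 <- simulate_epochs(sch, tr, cfg)
  expect_identical(e1, e2)
})

test_that("behavioral error marking matches the requested rates", {
  cfg <- design_config(n_subjects = 8L, n_rois = 1L, sample_rate = 50)
  eps <- metadata_tensors(cfg)
  eps0 <- mark_behavioral_errors(eps, 0, 0, seed = 1L)
  expect_true(all(vapply(eps0, function(e) all(e$trials$correct), TRUE)))
  eps1 <- mark_behavioral_errors(eps, 0.08, 0.14, seed = 2L)
  tm <- do.call(rbind, lapply(eps1, `[[`, "trials"))
  w_err <- mean(!tm$correct[tm$lexicality == "word"])
  n_err <- mean(!tm$correct[tm$lexicality == "nonword"])
  n_w <- sum(tm$lexicality == "word")
  n_n <- sum(tm$lexicality == "nonword")
  expect_lt(abs(w_err - 0.08), 3 * sqrt(0.08 * 0.92 / n_w))
  expect_lt(abs(n_err - 0.14), 3 * sqrt(0.14 * 0.86 / n_n))
  expect_identical(mark_behavioral_errors(eps, 0.08, 0.14, seed = 2L), eps1)
  expect_error(mark_behavioral_errors(eps, 1.0, 0.1), "rates")
  expect_error(mark_behavioral_errors(eps, -0.1, 0.1), "rates")
})

test_that("ground truth validates windows, coupling and noise", {
  cfg <- small_config()
  expect_error(ground_truth(cfg, noise_sd = 0), "noise_sd")
  expect_error(ground_truth(cfg, segmental_window = c(0, 400)),
               "segmental_window")
  expect_error(ground_truth(cfg, lexical_window = c(100, 600)),
               "lexical_window")
  expect_error(ground_truth(cfg, coupling = data.frame(
    source_roi = 1, target_roi = 5, lag_ms = 10, gain = 1)), "out of range")
  expect_error(ground_truth(cfg, coupling = data.frame(
    source_roi = 1, target_roi = 2, lag_ms = 10, gain = Inf)), "finite")
  tr <- ground_truth(cfg)
  nrm <- apply(tr$patterns$lex, c(1, 2), function(v) sqrt(sum(v^2)))
  expect_true(all(abs(nrm - 1) < 1e-12))
})
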