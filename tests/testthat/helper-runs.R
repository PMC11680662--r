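# Reduced-scale study runs used by the calibration and recovery tests.

# One lexical-injection run: does word-neighbor training produce a
# post-offset Bonferroni-significant cluster while nonword training does
# not? Returns c(word_post, nonword_post).
lexical_recovery_run <- function(seed) {
  cfg <- design_config(n_subjects = 10L, n_rois = 2L, sample_rate = 50,
                       seed = seed)
  tr <- ground_truth(cfg, lexical_amp = c(0.8, 0),
                     lexical_window = c(400, 600))
  ep <- prepped_epochs(cfg, tr, seed = seed + 1L)
  st <- build_stimulus_set(cfg)
  dec <- decode_study(ep, st, conditions = c("words_only", "nonwords_only"),
                      n_assignments = 5L, seed = seed + 2L)
  post <- function(ci, s) {
    recs <- cluster_test(condition_acc(dec, dec$conditions[ci]), dec$time,
                         n_perm = 200L, seed = s, n_rois_family = 2L,
                         condition = dec$conditions[ci])
    any(recs$significant & recs$start_ms >= 350)
  }
  c(word_post = post(1L, seed + 3L), nonword_post = post(2L, seed + 4L))
}

# One segmental-injection run: CV-overlap training must decode during the
# stimulus window (a significant cluster overlapping (0, 350]) and nowhere
# after offset (no significant cluster starting past 350 ms; cluster extent
# is not pointwise-exact, so overlap semantics are used).
segmental_recovery_run <- function(seed) {
  cfg <- design_config(n_subjects = 10L, n_rois = 2L, sample_rate = 50,
                       seed = seed)
  tr <- ground_truth(cfg, segmental_amp = c(1.0, 0),
                     segmental_window = c(0, 350))
  ep <- prepped_epochs(cfg, tr, seed = seed + 1L)
  st <- build_stimulus_set(cfg)
  dec <- decode_study(ep, st, conditions = "cv_overlap",
                      n_assignments = 5L, seed = seed + 2L)
  recs <- cluster_test(condition_acc(dec, "cv_overlap"), dec$time,
                       n_perm = 200L, seed = seed + 3L, n_rois_family = 2L,
                       condition = "cv_overlap")
  sig <- recs[recs$significant, , drop = FALSE]
  c(inside = any(sig$start_ms <= 350 & sig$end_ms > 0),
    post = any(sig$start_ms > 350))
}

# One coupled-system run: 5 ROIs, candidates 1-3 carry wordform signal,
# ROI 1 drives ROI 2 at a 20-ms lag, ROIs 4-5 form the control pair.
# Returns the gc_result.
coupled_gc_run <- function(seed, gain = 0.8) {
  cfg <- design_config(n_subjects = 10L, n_rois = 5L, sample_rate = 100,
                       seed = seed)
  cp <- if (gain > 0)
    data.frame(source_roi = 1, target_roi = 2, lag_ms = 20, gain = gain)
  else NULL
  tr <- ground_truth(cfg, lexical_amp = c(0.5, 0.5, 0.5, 0, 0),
                     lexical_window = c(350, 1000),
                     amp_jitter_sd = 0.7, amp_jitter_smooth_ms = 10,
                     coupling = cp)
  ep <- prepped_epochs(cfg, tr, seed = seed + 1L)
  st <- build_stimulus_set(cfg)
  dec <- decode_study(ep, st, conditions = "words_only",
                      n_assignments = 15L, seed = seed + 2L)
  gc_study(ep, dec, decoding_rois = c(1, 2, 3), control_pair = c(4, 5),
           window = c(450, 950), burn_ms = 250, downsample = 1L,
           order = 2L, adapt_const = 0.05, error_smooth = 0.5,
           n_surrogates = 150L, seed = seed + 3L)
}

# Abstract node-signal lists in the shape assemble_node_signals returns:
# per subject a target series, a time x channels predictor matrix with a
# channel map, and an analysis-window mask. Used to exercise the MVAR
# machinery on stationary data with a known coupling direction.
make_signals <- function(n_subj, Tn, coupled = FALSE, lag = 2L,
                         beta = 0.8, seed = 1) {
  set.seed(seed)
  d <- 8L
  lapply(seq_len(n_subj), function(si) {
    x <- rnorm(Tn)                              # source latent
    pat <- rnorm(d); pat <- pat / sqrt(sum(pat^2))
    src <- outer(x, pat) + matrix(rnorm(Tn * d, sd = 0.3), Tn, d)
    oth <- matrix(rnorm(Tn * d), Tn, d)
    y <- rnorm(Tn, sd = 0.5)
    if (coupled) y <- y + beta * c(rep(0, lag), x[seq_len(Tn - lag)])
    list(target = as.numeric(scale(y)),
         pred = cbind(scale(src), scale(oth)),
         map = data.frame(column = 1:(2 * d), roi = rep(2:3, each = d),
                          subdivision = rep(1:d, 2)),
         win = c(rep(FALSE, 20), rep(TRUE, Tn - 20)),
         time = seq_len(Tn))
  })
}
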