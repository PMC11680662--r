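# Shared fixtures: all built in code at test time.

# Small design used by most simulation-backed tests.
small_config <- function(n_subjects = 2L, n_rois = 2L, sample_rate = 50,
                         seed = 7L, ...) {
  design_config(n_subjects = n_subjects, n_rois = n_rois,
                sample_rate = sample_rate, seed = seed, ...)
}

# Simulate, mark errors and preprocess in one step.
prepped_epochs <- function(cfg, truth, seed = 1L,
                           error_rates = c(0.08, 0.14)) {
  st <- build_stimulus_set(cfg)
  sch <- make_schedule(cfg, seed, st)
  ep <- simulate_epochs(sch, truth, cfg, st)
  ep <- mark_behavioral_errors(ep, error_rates[1], error_rates[2],
                               seed = seed + 1L)
  vector_normalize(baseline_correct(ep))
}

# Hand-built epoch tensor for preprocessing unit tests.
make_tensor <- function(data, sample_rate = 100, epoch_start = -100,
                        n_subdivisions = 2L) {
  n_ch <- dim(data)[2]
  time <- seq(epoch_start, by = 1000 / sample_rate,
              length.out = dim(data)[3])
  structure(list(
    data = data, time = time,
    trials = data.frame(item_id = seq_len(dim(data)[1]),
                        lexicality = "word", correct = TRUE),
    channels = data.frame(channel = seq_len(n_ch),
                          roi = rep(seq_len(n_ch / n_subdivisions),
                                    each = n_subdivisions),
                          subdivision = rep(seq_len(n_subdivisions),
                                            n_ch / n_subdivisions)),
    subject_id = 1L, n_rois = as.integer(n_ch / n_subdivisions),
    n_subdivisions = as.integer(n_subdivisions),
    baseline_corrected = FALSE, normalized = FALSE),
    class = "epoch_tensor")
}

# Lightweight epoch tensors (metadata only) for behavioral-error tests.
metadata_tensors <- function(cfg, seed = 3L) {
  st <- build_stimulus_set(cfg)
  sch <- make_schedule(cfg, seed, st)
  lapply(split(sch, sch$subject_id), function(s) {
    meta <- cbind(s, st[match(s$item_id, st$item_id),
                        c("lexicality", "role", "neighborhood_id")])
    meta$correct <- TRUE
    structure(list(trials = meta, subject_id = s$subject_id[1]),
              class = "epoch_tensor")
  })
}
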