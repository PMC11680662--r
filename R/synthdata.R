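#' Ground truth for the synthetic epoch generator
#'
#' Describes the generative model used to emulate ROI-subdivision source
#' time courses of the lexical-decision experiment. Signals are additive on
#' top of Gaussian background noise:
#' \itemize{
#'   \item \strong{Segmental structure.} Each neighborhood owns three
#'     unit-norm phoneme-slot patterns (onset, vowel, coda) per ROI. During
#'     \code{segmental_window} an item expresses the slot patterns it shares
#'     with its hub plus an item-specific pattern for its changed phoneme, so
#'     phonologically overlapping items carry correlated patterns.
#'   \item \strong{Lexical structure.} Each neighborhood owns one unit-norm
#'     wordform pattern per ROI, expressed during \code{lexical_window} by
#'     the hub and its \emph{word} neighbors only; nonword neighbors never
#'     carry it.
#'   \item \strong{Coupling.} Directed edges add a lag-shifted, gain-scaled
#'     copy of the source ROI's lexical amplitude envelope into the target
#'     ROI's lexical amplitude, creating a ground-truth directed influence
#'     at the latent-amplitude level.
#' }
#' Amplitude envelopes are rectangular windows modulated by a smooth,
#' subject-specific random envelope (\code{amp_jitter_sd}); subject-level
#' pattern variability is a small random rotation of all pattern vectors
#' (\code{subject_jitter_sd}); virtual talkers contribute a small additive
#' offset common to all items of a block during the stimulus window.
#'
#' @param config a \code{\link{design_config}}.
#' @param segmental_amp per-ROI segmental amplitude (scalar recycled).
#' @param segmental_window (ms, ms) within \code{(0, stim_offset]}.
#' @param lexical_amp per-ROI lexical amplitude (scalar recycled).
#' @param lexical_window (ms, ms) within \code{[stim_offset, epoch_end]}.
#' @param coupling \code{data.frame(source_roi, target_roi, lag_ms, gain)}
#'   or \code{NULL}.
#' @param noise_sd background noise SD (> 0).
#' @param subject_jitter_sd SD of the skew entries of the per-subject
#'   pattern rotation (radian scale; 0 disables).
#' @param talker_offset_sd SD of the per-talker additive offset.
#' @param amp_jitter_sd SD of the smooth subject-level amplitude envelope
#'   modulation (fraction of the nominal amplitude).
#' @param amp_jitter_smooth_ms smoothing width of the envelope modulation.
#' @param ar_coef optional AR(1) coefficient for temporally correlated noise
#'   (0 = white noise; stationary SD kept at \code{noise_sd}).
#' @param seed integer seed controlling patterns and all draws.
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(config,
                         segmental_amp = 0,
                         segmental_window = c(0, 350),
                         lexical_amp = 0,
                         lexical_window = c(400, 600),
                         coupling = NULL,
                         noise_sd = 1,
                         subject_jitter_sd = 0.1,
                         talker_offset_sd = 0.1,
                         amp_jitter_sd = 0.5,
                         amp_jitter_smooth_ms = 30,
                         ar_coef = 0,
                         seed = derive_seed(config$seed, "truth")) {
  validate_design_config(config)
  R <- config$n_rois; d <- config$n_subdivisions
  seg <- rep_len(as.numeric(segmental_amp), R)
  lex <- rep_len(as.numeric(lexical_amp), R)
  if (noise_sd <= 0) stop_mod("synthdata", "noise_sd must be > 0")
  if (!(segmental_window[1] >= 0 && segmental_window[1] < segmental_window[2] &&
        segmental_window[2] <= config$stim_offset))
    stop_mod("synthdata", "segmental_window must lie within (0, stim_offset]")
  if (!(lexical_window[1] >= config$stim_offset &&
        lexical_window[1] < lexical_window[2] &&
        lexical_window[2] <= config$epoch_end))
    stop_mod("synthdata", "lexical_window must lie within [stim_offset, epoch_end]")
  if (!is.null(coupling)) {
    needed <- c("source_roi", "target_roi", "lag_ms", "gain")
    if (!all(needed %in% names(coupling)))
      stop_mod("synthdata", "coupling needs columns %s",
               paste(needed, collapse = ", "))
    if (!all(is.finite(coupling$gain)) || !all(is.finite(coupling$lag_ms)))
      stop_mod("synthdata", "coupling gains and lags must be finite")
    if (any(coupling$source_roi < 1 | coupling$source_roi > R |
            coupling$target_roi < 1 | coupling$target_roi > R))
      stop_mod("synthdata", "coupling ROI indices out of range 1..%d", R)
    if (any(coupling$lag_ms < 0))
      stop_mod("synthdata", "coupling lags must be >= 0")
  }
  stimuli <- build_stimulus_set(config)
  unit <- function(v) v / sqrt(sum(v^2))
  pats <- with_seed(derive_seed(seed, "patterns"), {
    slot <- array(0, c(R, 6L, 3L, d))
    lexp <- array(0, c(R, 6L, d))
    item <- array(0, c(R, nrow(stimuli), d))
    for (r in seq_len(R)) {
      for (nb in 1:6) {
        for (s in 1:3) slot[r, nb, s, ] <- unit(rnorm(d))
        lexp[r, nb, ] <- unit(rnorm(d))
      }
      for (i in seq_len(nrow(stimuli))) item[r, i, ] <- unit(rnorm(d))
    }
    list(slot = slot, lex = lexp, item = item)
  })
  tr <- list(
    n_rois = R, pattern_dim = d,
    segmental_amp = seg, segmental_window = as.numeric(segmental_window),
    lexical_amp = lex, lexical_window = as.numeric(lexical_window),
    coupling = coupling,
    noise_sd = noise_sd, subject_jitter_sd = subject_jitter_sd,
    talker_offset_sd = talker_offset_sd,
    amp_jitter_sd = amp_jitter_sd,
    amp_jitter_smooth_ms = amp_jitter_smooth_ms,
    ar_coef = ar_coef, seed = as.integer(seed),
    patterns = pats
  )
  class(tr) <- "ground_truth"
  tr
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  segmental ROIs: %s (window %g-%g ms)\n",
              paste(which(x$segmental_amp > 0), collapse = ","),
              x$segmental_window[1], x$segmental_window[2]))
  cat(sprintf("  lexical ROIs:   %s (window %g-%g ms)\n",
              paste(which(x$lexical_amp > 0), collapse = ","),
              x$lexical_window[1], x$lexical_window[2]))
  cat(sprintf("  coupling edges: %d; noise SD %g; AR(1) %g\n",
              if (is.null(x$coupling)) 0L else nrow(x$coupling),
              x$noise_sd, x$ar_coef))
  invisible(x)
}

# Small random rotation via the Cayley transform of a skew-symmetric matrix:
# exactly orthogonal, identity at sd = 0.
random_rotation <- function(d, sd) {
  if (sd <= 0) return(diag(d))
  S <- matrix(rnorm(d * d, sd = sd), d, d)
  S <- (S - t(S)) / 2
  I <- diag(d)
  solve(I - S / 2) %*% (I + S / 2)
}

# Smooth zero-mean envelope noise: moving-average of white noise rescaled
# to the requested SD.
smooth_noise <- function(n, sd, width) {
  if (sd <= 0) return(numeric(n))
  w <- max(1L, as.integer(width))
  x <- rnorm(n + 2L * w)
  k <- rep(1 / w, w)
  sm <- stats::filter(x, k, sides = 2)
  sm <- sm[(w + 1L):(w + n)]
  sm <- sm - mean(sm)
  s <- sd(sm)
  if (s > 0) sm * sd / s else numeric(n)
}

# Which slot patterns does an item share with its hub?
shared_slots <- function(changed_position) {
  switch(changed_position,
         none = 1:3,                 # hub: onset, vowel, coda all shared
         onset = 2:3, vowel = c(1L, 3L), coda = 1:2)
}

#' Simulate ROI-subdivision epoch tensors for all subjects
#'
#' Generates, for each subject in the schedule, a trials x channels x time
#' array of synthetic source activations (channels = ROIs x subdivisions)
#' following the generative model in \code{\link{ground_truth}}. All
#' randomness derives from \code{truth$seed} and the subject index, so the
#' output is bit-reproducible.
#'
#' @param schedule a \code{\link{make_schedule}} trial schedule.
#' @param truth a \code{\link{ground_truth}}.
#' @param config the matching \code{\link{design_config}}.
#' @param stimuli the stimulus set (rebuilt from \code{config} if omitted).
#' @param subjects optional subset of subject ids to simulate.
#' @return a named list of \code{epoch_tensor} objects, one per subject.
#' @export
simulate_epochs <- function(schedule, truth, config,
                            stimuli = build_stimulus_set(config),
                            subjects = NULL) {
  validate_design_config(config)
  if (truth$n_rois != config$n_rois || truth$pattern_dim != config$n_subdivisions)
    stop_mod("synthdata", "truth dimensions do not match config")
  sids <- sort(unique(schedule$subject_id))
  if (!is.null(subjects)) sids <- intersect(sids, subjects)
  out <- lapply(sids, function(sj)
    simulate_subject(schedule[schedule$subject_id == sj, , drop = FALSE],
                     truth, config, stimuli, sj))
  names(out) <- paste0("subject_", sids)
  out
}

simulate_subject <- function(sch, truth, config, stimuli, subject_id) {
  d <- config$n_subdivisions; R <- config$n_rois
  time <- seq(config$epoch_start, config$epoch_end, by = 1000 / config$sample_rate)
  Tn <- length(time)
  n_trials <- nrow(sch)
  item_row <- match(sch$item_id, stimuli$item_id)
  meta <- cbind(sch,
                stimuli[item_row, c("label", "lexicality", "neighborhood_id",
                                    "role", "changed_position", "overlap_class")])
  rownames(meta) <- NULL
  meta$correct <- TRUE

  w_seg <- as.numeric(time > truth$segmental_window[1] &
                        time <= truth$segmental_window[2])
  w_lex <- as.numeric(time > truth$lexical_window[1] &
                        time <= truth$lexical_window[2])
  w_stim <- as.numeric(time > 0 & time <= config$stim_offset)
  smooth_w <- truth$amp_jitter_smooth_ms * config$sample_rate / 1000

  with_seed(derive_seed(truth$seed, 1000 + subject_id), {
    rot <- random_rotation(d, truth$subject_jitter_sd)
    # Subject-specific smooth amplitude envelopes per ROI.
    env_seg <- sapply(seq_len(R), function(r)
      1 + smooth_noise(Tn, truth$amp_jitter_sd, smooth_w))
    env_lex <- sapply(seq_len(R), function(r)
      1 + smooth_noise(Tn, truth$amp_jitter_sd, smooth_w))
    a_seg <- sweep(env_seg * w_seg, 2, truth$segmental_amp, `*`)   # Tn x R
    a_lex <- sweep(env_lex * w_lex, 2, truth$lexical_amp, `*`)
    # Directed coupling: add lagged, scaled source envelope into the
    # target's lexical amplitude (single pass over base envelopes).
    if (!is.null(truth$coupling) && nrow(truth$coupling) > 0) {
      a_base <- a_lex
      for (e in seq_len(nrow(truth$coupling))) {
        src <- truth$coupling$source_roi[e]
        tgt <- truth$coupling$target_roi[e]
        lag <- round(truth$coupling$lag_ms[e] * config$sample_rate / 1000)
        shifted <- c(rep(0, lag), a_base[seq_len(Tn - lag), src])
        a_lex[, tgt] <- a_lex[, tgt] + truth$coupling$gain[e] * shifted
      }
    }
    # Per-talker additive offsets (per ROI), active during the stimulus.
    talkers <- sort(unique(sch$talker_id))
    toff <- array(rnorm(length(talkers) * R * d, sd = truth$talker_offset_sd),
                  c(length(talkers), R, d))

    data <- array(0, c(n_trials, R * d, Tn))
    for (r in seq_len(R)) {
      # Per-item pattern matrices (items x d), indexed per trial below.
      n_items <- nrow(stimuli)
      ItemSeg <- matrix(0, n_items, d)
      ItemLex <- matrix(0, n_items, d)
      for (i in seq_len(n_items)) {
        st <- stimuli[i, ]
        nb <- st$neighborhood_id + 1L
        sl <- shared_slots(st$changed_position)
        p <- colSums(matrix(truth$patterns$slot[r, nb, sl, ], nrow = length(sl)))
        if (st$role == "neighbor")
          p <- p + truth$patterns$item[r, st$item_id, ]
        ItemSeg[i, ] <- p / sqrt(3)
        if (st$role == "hub" ||
            (st$role == "neighbor" && st$lexicality == "word"))
          ItemLex[i, ] <- truth$patterns$lex[r, nb, ]
      }
      Sseg <- (ItemSeg %*% t(rot))[item_row, , drop = FALSE]
      Slex <- (ItemLex %*% t(rot))[item_row, , drop = FALSE]
      Off <- toff[match(sch$talker_id, talkers), r, , drop = FALSE]
      dim(Off) <- c(n_trials, d)
      ch <- (r - 1L) * d + seq_len(d)
      # outer products: (trials x d) x (Tn) -> trials x d x Tn
      data[, ch, ] <- outer(Sseg, a_seg[, r]) + outer(Slex, a_lex[, r]) +
        outer(Off, w_stim)
    }
    noise <- rnorm(length(data), sd = truth$noise_sd)
    if (truth$ar_coef > 0) {
      # AR(1) along time with stationary SD = noise_sd.
      M <- matrix(noise * sqrt(1 - truth$ar_coef^2), nrow = Tn,
                  ncol = n_trials * R * d, byrow = TRUE)
      M <- stats::filter(M, truth$ar_coef, method = "recursive")
      noise <- as.numeric(t(M))
    }
    data <- data + array(noise, dim(data))

    channels <- data.frame(channel = seq_len(R * d),
                           roi = rep(seq_len(R), each = d),
                           subdivision = rep(seq_len(d), R))
    structure(list(data = data, time = time, trials = meta,
                   channels = channels, subject_id = subject_id,
                   n_rois = R, n_subdivisions = d,
                   baseline_corrected = FALSE, normalized = FALSE),
              class = "epoch_tensor")
  })
}

#' @export
print.epoch_tensor <- function(x, ...) {
  cat(sprintf("Epoch tensor: subject %s, %d trials x %d channels (%d ROIs x %d) x %d timepoints\n",
              x$subject_id, dim(x$data)[1], dim(x$data)[2],
              x$n_rois, x$n_subdivisions, dim(x$data)[3]))
  cat(sprintf("  time: [%g, %g] ms; baseline_corrected=%s; normalized=%s\n",
              min(x$time), max(x$time), x$baseline_corrected, x$normalized))
  cat(sprintf("  correct trials: %d/%d\n", sum(x$trials$correct), nrow(x$trials)))
  invisible(x)
}

#' Mark simulated behavioral errors
#'
#' Sets each trial's \code{correct} flag by an independent Bernoulli draw at
#' a lexicality-specific error rate, emulating lexical-decision performance
#' (words are answered more accurately than nonwords).
#'
#' @param epochs an \code{epoch_tensor} or a list of them.
#' @param error_rate_words,error_rate_nonwords error probabilities in [0,1).
#' @param seed integer seed.
#' @return the input with updated \code{correct} flags.
#' @export
mark_behavioral_errors <- function(epochs, error_rate_words = 0.08,
                                   error_rate_nonwords = 0.14, seed = 1L) {
  rates <- c(error_rate_words, error_rate_nonwords)
  if (any(rates < 0 | rates >= 1))
    stop_mod("synthdata", "error rates must lie in [0, 1)")
  if (inherits(epochs, "epoch_tensor")) {
    return(mark_one(epochs, rates, derive_seed(seed, epochs$subject_id)))
  }
  lapply(epochs, function(ep) mark_one(ep, rates, derive_seed(seed, ep$subject_id)))
}

mark_one <- function(ep, rates, seed) {
  with_seed(seed, {
    p_err <- ifelse(ep$trials$lexicality == "word", rates[1], rates[2])
    ep$trials$correct <- runif(nrow(ep$trials)) >= p_err
    ep
  })
}
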