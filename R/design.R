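#' Experimental design configuration
#'
#' Bundles the parameters of the blocked lexical-decision design: six hub
#' words, each with three word and three nonword CVC neighbors obtained by
#' changing exactly one phoneme (onset, vowel or coda, counterbalanced),
#' presented by virtual talkers in blocks.
#'
#' The defaults reproduce the full study design: 20 subjects, 8 virtual
#' talkers owning two non-consecutive blocks each (16 blocks), hubs presented
#' twice and neighbors once per block (48 trials/block), epochs spanning
#' \code{[-100, 1000]} ms around stimulus onset at 1 kHz, stimuli duration
#' normalized to 350 ms, and 39 cortical ROIs split into 8 subdivisions.
#'
#' @param n_subjects number of subjects.
#' @param n_talkers number of virtual talkers; each owns exactly two
#'   non-consecutive blocks, so \code{n_blocks = 2 * n_talkers}.
#' @param hub_reps_per_block presentations of each hub word per block.
#' @param neighbor_reps_per_block presentations of each neighbor per block.
#' @param sample_rate sampling rate of the source time courses, Hz.
#' @param epoch_start,epoch_end epoch limits relative to stimulus onset, ms.
#' @param stim_offset auditory stimulus offset, ms after onset.
#' @param n_rois number of cortical regions of interest.
#' @param n_subdivisions spatial subdivisions per ROI (decoding features).
#' @param seed default seed for stochastic stages that take no explicit seed.
#' @return an object of class \code{design_config} (a validated list).
#' @export
design_config <- function(n_subjects = 20L,
                          n_talkers = 8L,
                          hub_reps_per_block = 2L,
                          neighbor_reps_per_block = 1L,
                          sample_rate = 1000,
                          epoch_start = -100,
                          epoch_end = 1000,
                          stim_offset = 350,
                          n_rois = 39L,
                          n_subdivisions = 8L,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_talkers = as.integer(n_talkers),
    n_blocks = 2L * as.integer(n_talkers),
    hub_reps_per_block = as.integer(hub_reps_per_block),
    neighbor_reps_per_block = as.integer(neighbor_reps_per_block),
    sample_rate = as.numeric(sample_rate),
    epoch_start = as.numeric(epoch_start),
    epoch_end = as.numeric(epoch_end),
    stim_offset = as.numeric(stim_offset),
    n_rois = as.integer(n_rois),
    n_subdivisions = as.integer(n_subdivisions),
    seed = as.integer(seed)
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

validate_design_config <- function(cfg) {
  if (cfg$n_blocks != 2L * cfg$n_talkers)
    stop_mod("design", "n_blocks must equal 2 * n_talkers")
  if (!(cfg$epoch_start < 0 && 0 < cfg$stim_offset &&
        cfg$stim_offset < cfg$epoch_end))
    stop_mod("design", "need epoch_start < 0 < stim_offset < epoch_end")
  if (cfg$n_subjects < 1L || cfg$n_rois < 1L || cfg$n_subdivisions < 1L)
    stop_mod("design", "counts must be positive")
  if (cfg$sample_rate <= 0)
    stop_mod("design", "sample_rate must be positive")
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("Lexical-decision neighborhood design\n")
  cat(sprintf("  subjects: %d; talkers: %d; blocks: %d (%d trials/block)\n",
              x$n_subjects, x$n_talkers, x$n_blocks,
              x$hub_reps_per_block * 6L + 36L * x$neighbor_reps_per_block))
  cat(sprintf("  epoch: [%g, %g] ms @ %g Hz; stimulus offset %g ms\n",
              x$epoch_start, x$epoch_end, x$sample_rate, x$stim_offset))
  cat(sprintf("  ROIs: %d x %d subdivisions\n", x$n_rois, x$n_subdivisions))
  invisible(x)
}

# The six hub words of the design; fixed by the stimulus set.
HUB_WORDS <- c("pig", "toad", "cab", "bike", "dupe", "gut")

#' Build the hub/neighbor stimulus set
#'
#' Constructs the 42-item stimulus inventory: 6 hub words, each with three
#' word and three nonword neighbors that differ from the hub in exactly one
#' phoneme, with the changed position (onset, vowel, coda) counterbalanced
#' within each lexicality. Phoneme content is abstracted: items are
#' identified by generated labels carrying the hub name, lexicality and
#' changed position, since only the overlap structure matters downstream.
#'
#' The overlap class records which part of the CVC frame an item shares with
#' its hub: a coda change leaves the initial CV shared (\code{shares_CV}), a
#' vowel change leaves the consonant frame (\code{shares_frame}), an onset
#' change leaves the final VC (\code{shares_VC}); the hub itself is
#' \code{full}.
#'
#' @param config a \code{\link{design_config}}.
#' @return a \code{data.frame} of class \code{stimulus_set} with one row per
#'   item: \code{item_id}, \code{label}, \code{lexicality},
#'   \code{neighborhood_id} (0-based hub index), \code{role},
#'   \code{changed_position}, \code{overlap_class}.
#' @export
build_stimulus_set <- function(config = design_config()) {
  validate_design_config(config)
  positions <- c("onset", "vowel", "coda")
  overlap_of <- c(onset = "shares_VC", vowel = "shares_frame",
                  coda = "shares_CV", none = "full")
  rows <- list()
  for (nb in 0:5) {
    hub <- HUB_WORDS[nb + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      label = hub, lexicality = "word", neighborhood_id = nb,
      role = "hub", changed_position = "none",
      stringsAsFactors = FALSE)
    for (lex in c("word", "nonword")) {
      for (pos in positions) {
        rows[[length(rows) + 1L]] <- data.frame(
          label = sprintf("%s-%s-%s", hub, substr(lex, 1, 1), substr(pos, 1, 3)),
          lexicality = lex, neighborhood_id = nb,
          role = "neighbor", changed_position = pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  items <- do.call(rbind, rows)
  items$overlap_class <- overlap_of[items$changed_position]
  items <- data.frame(item_id = seq_len(nrow(items)), items,
                      row.names = NULL, stringsAsFactors = FALSE)
  class(items) <- c("stimulus_set", "data.frame")
  items
}

#' Select classifier training items for a neighborhood
#'
#' Returns the neighbor items used to train a transfer classifier under a
#' given training condition. The hub itself is never returned: it is held
#' out for testing by construction of the transfer design.
#'
#' @param stimuli a stimulus set from \code{\link{build_stimulus_set}}.
#' @param neighborhood_id hub index, 0 to 5.
#' @param condition one of \code{"words_only"} (the 3 word neighbors),
#'   \code{"nonwords_only"} (the 3 nonword neighbors), \code{"cv_overlap"}
#'   (the 2 coda-changed neighbors, both lexicalities, sharing the initial
#'   CV with the hub) or \code{"vc_overlap"} (the 2 onset-changed neighbors,
#'   sharing the final VC).
#' @return the matching rows of \code{stimuli}.
#' @export
select_training_items <- function(stimuli, neighborhood_id, condition) {
  if (!neighborhood_id %in% unique(stimuli$neighborhood_id))
    stop_mod("design", "unknown neighborhood_id %s", neighborhood_id)
  nb <- stimuli[stimuli$neighborhood_id == neighborhood_id &
                  stimuli$role == "neighbor", , drop = FALSE]
  out <- switch(condition,
    words_only    = nb[nb$lexicality == "word", , drop = FALSE],
    nonwords_only = nb[nb$lexicality == "nonword", , drop = FALSE],
    cv_overlap    = nb[nb$changed_position == "coda", , drop = FALSE],
    vc_overlap    = nb[nb$changed_position == "onset", , drop = FALSE],
    stop_mod("design", "unknown condition '%s'", condition)
  )
  rownames(out) <- NULL
  out
}

#' Training conditions recognised by the decoding stage
#' @export
decoding_conditions <- function() {
  c("words_only", "nonwords_only", "cv_overlap", "vc_overlap")
}

# One block's item list (item_ids with hub repetitions), before ordering.
block_item_pool <- function(stimuli, config) {
  hubs <- stimuli$item_id[stimuli$role == "hub"]
  nbrs <- stimuli$item_id[stimuli$role == "neighbor"]
  c(rep(hubs, each = config$hub_reps_per_block),
    rep(nbrs, each = config$neighbor_reps_per_block))
}

# Shuffle a block until no hub item occupies two consecutive trials.
shuffle_block <- function(pool, hubs, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    ord <- sample(pool)
    dup <- ord[-1L] == ord[-length(ord)] & ord[-1L] %in% hubs
    if (!any(dup)) return(ord)
  }
  stop_mod("design",
           "could not order a block without adjacent hub repetitions after %d tries",
           max_tries)
}

# Assign each talker to two non-consecutive blocks by rejection sampling.
assign_talkers <- function(n_talkers, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    ord <- sample(rep(seq_len(n_talkers), each = 2L))
    if (!any(ord[-1L] == ord[-length(ord)])) return(ord)
  }
  stop_mod("design",
           "could not assign talkers to non-consecutive blocks after %d tries",
           max_tries)
}

#' Generate the blocked, pseudo-randomized trial schedule
#'
#' For every subject, assigns each virtual talker to two non-consecutive
#' blocks and orders each block's trials (every hub twice, every neighbor
#' once under the defaults) pseudo-randomly under the constraint that the
#' second presentation of a hub word never directly follows its first.
#' Both constraints are enforced by reshuffle-and-check with a bounded
#' retry count; failure to satisfy them signals a degenerate configuration.
#'
#' @param config a \code{\link{design_config}}.
#' @param seed integer seed; the same (config, seed) reproduces the schedule
#'   exactly.
#' @param stimuli optional stimulus set (built from \code{config} if omitted).
#' @return a \code{data.frame} of class \code{trial_schedule} with columns
#'   \code{subject_id}, \code{block_index}, \code{talker_id},
#'   \code{trial_index_in_block}, \code{item_id}, \code{presentation_number}.
#' @export
make_schedule <- function(config = design_config(), seed = config$seed,
                          stimuli = build_stimulus_set(config)) {
  validate_design_config(config)
  hubs <- stimuli$item_id[stimuli$role == "hub"]
  pool <- block_item_pool(stimuli, config)
  res <- with_seed(derive_seed(seed, "schedule"), {
    per_subject <- lapply(seq_len(config$n_subjects), function(sj) {
      talker_of_block <- assign_talkers(config$n_talkers)
      per_block <- lapply(seq_len(config$n_blocks), function(bl) {
        ord <- shuffle_block(pool, hubs)
        pres <- stats::ave(seq_along(ord), ord, FUN = seq_along)
        data.frame(subject_id = sj, block_index = bl,
                   talker_id = talker_of_block[bl],
                   trial_index_in_block = seq_along(ord),
                   item_id = ord, presentation_number = pres)
      })
      do.call(rbind, per_block)
    })
    do.call(rbind, per_subject)
  })
  rownames(res) <- NULL
  class(res) <- c("trial_schedule", "data.frame")
  res
}

#' Write / read a trial schedule as TSV
#'
#' @param schedule a \code{trial_schedule}.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sch <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(sch) <- c("trial_schedule", "data.frame")
  sch
}

#' Write / read a design configuration as YAML
#' @param config a \code{\link{design_config}}.
#' @param path file path.
#' @export
write_design_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(design_config, v[setdiff(names(v), "n_blocks")])
}
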