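#' Train and test a binary classifier at a single timepoint
#'
#' Fits a linear soft-margin SVM (C = 1, no feature scaling beyond the
#' pipeline's vector normalization) on the training bins and returns the
#' fraction of test bins assigned their own label. The first level of
#' \code{factor(train_labels)} plays the role of class A; decision ties are
#' broken toward class A deterministically.
#'
#' @param train_features,test_features numeric matrices (samples x features).
#' @param train_labels,test_labels label vectors (exactly two classes in
#'   training).
#' @return accuracy, a fraction in [0, 1].
#' @export
train_test_timepoint <- function(train_features, train_labels,
                                 test_features, test_labels) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  lv <- levels(factor(train_labels))
  if (length(lv) != 2)
    stop_mod("decode", "training labels must contain exactly 2 classes, got %d",
             length(lv))
  if (ncol(train_features) != ncol(test_features))
    stop_mod("decode", "feature dimension mismatch: train %d vs test %d",
             ncol(train_features), ncol(test_features))
  if (nrow(test_features) < 1)
    stop_mod("decode", "need at least one test sample")
  y <- ifelse(train_labels == lv[1], 1, -1)
  fit <- cpp_svm_fit(train_features, as.numeric(y))
  f <- drop(test_features %*% fit$w) + fit$b
  pred <- ifelse(f >= 0, lv[1], lv[2])
  mean(pred == test_labels)
}

#' Build pseudo-trial bins for transfer decoding
#'
#' Creates the per-neighborhood bin assignments the transfer design needs:
#' one training group per neighborhood (the neighbors selected by
#' \code{condition}) and one test group per neighborhood (its hub trials).
#' Only correct-response trials enter; bins are disjoint random groups of
#' \code{bin_size} trials, re-drawn \code{n_assignments} times.
#'
#' @param epochs an \code{epoch_tensor}.
#' @param stimuli the stimulus set.
#' @param condition a training condition (see
#'   \code{\link{select_training_items}}).
#' @param bin_size trials per bin.
#' @param n_assignments number of random bin assignments.
#' @param seed integer seed.
#' @return a \code{decoding_bins} list: \code{assignments} (from
#'   \code{\link{make_bins}}), group names \code{train_<nb>} /
#'   \code{hub_<nb>}, and provenance fields.
#' @export
make_decoding_bins <- function(epochs, stimuli, condition,
                               bin_size = 8L, n_assignments = 100L,
                               seed = 1L) {
  nbs <- sort(unique(stimuli$neighborhood_id))
  conditions <- list()
  for (nb in nbs) {
    tr_items <- select_training_items(stimuli, nb, condition)$item_id
    hub_item <- stimuli$item_id[stimuli$neighborhood_id == nb &
                                  stimuli$role == "hub"]
    conditions[[sprintf("train_%d", nb)]] <-
      which(epochs$trials$item_id %in% tr_items)
    conditions[[sprintf("hub_%d", nb)]] <-
      which(epochs$trials$item_id == hub_item)
  }
  assignments <- make_bins(epochs$trials, conditions, bin_size = bin_size,
                           n_assignments = n_assignments, seed = seed)
  structure(list(assignments = assignments, neighborhoods = nbs,
                 condition = condition, bin_size = bin_size,
                 n_assignments = n_assignments, seed = seed),
            class = "decoding_bins")
}

# Slice the channels of one ROI from a bins x channels x time array.
roi_slice <- function(arr, roi, d) {
  arr[, (roi - 1L) * d + seq_len(d), , drop = FALSE]
}

#' Per-timepoint transfer decoding for one ROI and neighborhood pair
#'
#' Trains, for every bin assignment and timepoint, a linear SVM on the
#' neighbor bins of the two neighborhoods (selected by the bins object's
#' training condition) and tests it on the corresponding untrained hub
#' bins. Hub trials never appear in training (asserted on every call).
#'
#' @param epochs a preprocessed \code{epoch_tensor} (baseline corrected and
#'   vector normalized).
#' @param roi ROI index.
#' @param pair integer vector of two distinct neighborhood ids.
#' @param bins a \code{\link{make_decoding_bins}} object.
#' @return numeric vector of per-timepoint accuracy, averaged over the bin
#'   assignments.
#' @export
transfer_decode <- function(epochs, roi, pair, bins) {
  check_prepped(epochs)
  if (length(pair) != 2 || pair[1] == pair[2])
    stop_mod("decode", "pair must be two distinct neighborhood ids")
  d <- epochs$n_subdivisions
  Tn <- dim(epochs$data)[3]
  acc <- numeric(Tn)
  for (a in seq_along(bins$assignments)) {
    asg <- bins$assignments[[a]]
    trA <- asg[[sprintf("train_%d", pair[1])]]
    trB <- asg[[sprintf("train_%d", pair[2])]]
    teA <- asg[[sprintf("hub_%d", pair[1])]]
    teB <- asg[[sprintf("hub_%d", pair[2])]]
    assert_transfer_integrity(trA, trB, teA, teB)
    acc <- acc + cpp_pair_accuracy(
      roi_slice(average_bins(epochs, trA), roi, d),
      roi_slice(average_bins(epochs, trB), roi, d),
      roi_slice(average_bins(epochs, teA), roi, d),
      roi_slice(average_bins(epochs, teB), roi, d))
  }
  acc / length(bins$assignments)
}

# transfer_decode above recomputes bin averages; decode_subject below is the
# production path that shares group averages across ROIs and pairs.

assert_transfer_integrity <- function(trA, trB, teA, teB) {
  train_idx <- unique(unlist(c(trA, trB)))
  test_idx <- unique(unlist(c(teA, teB)))
  if (length(intersect(train_idx, test_idx)) > 0)
    stop_mod("decode", "transfer integrity violated: train/test trials overlap")
  invisible(TRUE)
}

#' Transfer decoding of all ROI x pair curves for one subject
#'
#' Runs the pairwise transfer design over all unordered neighborhood pairs
#' and the requested ROIs, sharing bin averages across ROIs and pairs.
#'
#' @inheritParams transfer_decode
#' @param stimuli the stimulus set.
#' @param rois ROI indices to decode (default all).
#' @param bins optional \code{\link{make_decoding_bins}}; built from
#'   \code{condition}/\code{bin_size}/\code{n_assignments}/\code{seed}
#'   if omitted.
#' @param condition,bin_size,n_assignments,seed used when \code{bins} is
#'   missing.
#' @return list with \code{pair_acc} (array rois x pairs x time),
#'   \code{acc} (rois x time, mean over pairs), \code{pairs} (2 x n matrix),
#'   \code{time}.
#' @export
decode_subject <- function(epochs, stimuli, rois = seq_len(epochs$n_rois),
                           bins = NULL, condition = "words_only",
                           bin_size = 8L, n_assignments = 100L, seed = 1L) {
  check_prepped(epochs)
  if (is.null(bins))
    bins <- make_decoding_bins(epochs, stimuli, condition, bin_size,
                               n_assignments, seed)
  d <- epochs$n_subdivisions
  Tn <- dim(epochs$data)[3]
  nbs <- bins$neighborhoods
  pairs <- combn(nbs, 2)
  n_pairs <- ncol(pairs)
  acc <- array(0, c(length(rois), n_pairs, Tn))
  for (a in seq_along(bins$assignments)) {
    asg <- bins$assignments[[a]]
    group_avg <- lapply(asg, function(b) average_bins(epochs, b))
    for (pi in seq_len(n_pairs)) {
      A <- pairs[1, pi]; B <- pairs[2, pi]
      assert_transfer_integrity(asg[[sprintf("train_%d", A)]],
                                asg[[sprintf("train_%d", B)]],
                                asg[[sprintf("hub_%d", A)]],
                                asg[[sprintf("hub_%d", B)]])
      for (ri in seq_along(rois)) {
        acc[ri, pi, ] <- acc[ri, pi, ] + cpp_pair_accuracy(
          roi_slice(group_avg[[sprintf("train_%d", A)]], rois[ri], d),
          roi_slice(group_avg[[sprintf("train_%d", B)]], rois[ri], d),
          roi_slice(group_avg[[sprintf("hub_%d", A)]], rois[ri], d),
          roi_slice(group_avg[[sprintf("hub_%d", B)]], rois[ri], d))
      }
    }
  }
  acc <- acc / length(bins$assignments)
  dimnames(acc) <- list(paste0("roi_", rois),
                        paste(pairs[1, ], pairs[2, ], sep = "-"), NULL)
  list(pair_acc = acc, acc = aggregate_pairs(acc), pairs = pairs,
       time = epochs$time)
}

#' Aggregate per-pair accuracy curves
#'
#' Unweighted mean over all unordered neighborhood pairs. All 15 pairs (for
#' the 6-neighborhood design) must be present.
#'
#' @param pair_acc array (rois x pairs x time) with pair names
#'   \code{"A-B"} on the second dimension, or a named list of per-pair
#'   curves.
#' @param n_neighborhoods number of neighborhoods (default 6).
#' @return rois x time matrix (or a single curve for list input).
#' @export
aggregate_pairs <- function(pair_acc, n_neighborhoods = 6L) {
  nbs <- 0:(n_neighborhoods - 1L)
  expected <- apply(combn(nbs, 2), 2, paste, collapse = "-")
  if (is.list(pair_acc)) {
    missing <- setdiff(expected, names(pair_acc))
    if (length(missing) > 0)
      stop_mod("decode", "missing pair(s): %s", paste(missing, collapse = ", "))
    return(Reduce(`+`, pair_acc[expected]) / length(expected))
  }
  missing <- setdiff(expected, dimnames(pair_acc)[[2]])
  if (length(missing) > 0)
    stop_mod("decode", "missing pair(s): %s", paste(missing, collapse = ", "))
  out <- apply(pair_acc[, expected, , drop = FALSE], c(1, 3), mean)
  dimnames(out) <- list(dimnames(pair_acc)[[1]], NULL)
  out
}

check_prepped <- function(epochs) {
  if (!inherits(epochs, "epoch_tensor"))
    stop_mod("decode", "expected an epoch_tensor")
  if (!isTRUE(epochs$baseline_corrected) || !isTRUE(epochs$normalized))
    stop_mod("decode", "epochs must be baseline corrected and normalized")
  invisible(TRUE)
}

#' Group-level transfer decoding time courses
#'
#' Runs preprocessing-ready epoch tensors of several subjects through the
#' pairwise transfer decoder for one or more training conditions and
#' collects the accuracy into a subjects x ROIs x conditions x timepoints
#' array (chance = 0.5 for pairwise classification).
#'
#' @param epochs_list list of preprocessed \code{epoch_tensor}s.
#' @param stimuli the stimulus set.
#' @param conditions character vector of training conditions.
#' @param rois ROI indices to decode (default all).
#' @param bin_size,n_assignments,seed binning parameters; each
#'   subject x condition gets an independent derived seed.
#' @return object of class \code{decoding_timecourse}: \code{acc} array,
#'   \code{pair_acc} per subject/condition (list), \code{time},
#'   \code{chance}, provenance.
#' @export
decode_study <- function(epochs_list, stimuli,
                         conditions = decoding_conditions(),
                         rois = NULL, bin_size = 8L, n_assignments = 100L,
                         seed = 1L) {
  stopifnot(length(epochs_list) > 0)
  ep1 <- epochs_list[[1]]
  if (is.null(rois)) rois <- seq_len(ep1$n_rois)
  Tn <- dim(ep1$data)[3]
  ns <- length(epochs_list)
  acc <- array(NA_real_,
               c(ns, length(rois), length(conditions), Tn),
               dimnames = list(names(epochs_list), paste0("roi_", rois),
                               conditions, NULL))
  pair_acc <- list()
  for (si in seq_len(ns)) {
    ep <- epochs_list[[si]]
    for (ci in seq_along(conditions)) {
      res <- decode_subject(
        ep, stimuli, rois = rois, condition = conditions[ci],
        bin_size = bin_size, n_assignments = n_assignments,
        seed = derive_seed(seed, paste0("decode", si, "_", conditions[ci])))
      acc[si, , ci, ] <- res$acc
      pair_acc[[sprintf("s%d_%s", si, conditions[ci])]] <- res$pair_acc
    }
  }
  structure(list(acc = acc, pair_acc = pair_acc, time = ep1$time,
                 chance = 0.5, conditions = conditions, rois = rois,
                 n_assignments = n_assignments, seed = seed),
            class = "decoding_timecourse")
}

#' Extract one condition's accuracy array
#'
#' @param dec a \code{decoding_timecourse}.
#' @param condition a training condition name.
#' @return subjects x ROIs x timepoints array.
#' @export
condition_acc <- function(dec, condition) {
  ci <- match(condition, dec$conditions)
  if (is.na(ci))
    stop_mod("decode", "condition '%s' not present", condition)
  out <- dec$acc[, , ci, , drop = FALSE]
  array(out, dim(dec$acc)[c(1, 2, 4)],
        dimnames = list(NULL, dimnames(dec$acc)[[2]], NULL))
}

#' Write decoding time courses as long-format TSV
#'
#' One row per subject x ROI x condition x timepoint, suitable for
#' plotting.
#'
#' @param dec a \code{decoding_timecourse}.
#' @param path file path.
#' @export
write_decoding_tsv <- function(dec, path) {
  dm <- dim(dec$acc)
  long <- expand.grid(subject = seq_len(dm[1]),
                      roi = dimnames(dec$acc)[[2]],
                      condition = dec$conditions,
                      time_ms = dec$time,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$accuracy <- as.numeric(dec$acc)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  dm <- dim(x$acc)
  cat(sprintf("Transfer decoding time courses: %d subjects x %d ROIs x %d conditions x %d timepoints\n",
              dm[1], dm[2], dm[3], dm[4]))
  cat(sprintf("  conditions: %s; chance = %.2f; %d bin assignments\n",
              paste(x$conditions, collapse = ", "), x$chance, x$n_assignments))
  gm <- apply(x$acc, 3, mean)
  cat("  grand-mean accuracy per condition:\n")
  for (i in seq_along(x$conditions))
    cat(sprintf("    %-14s %.3f\n", x$conditions[i], gm[i]))
  invisible(x)
}
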