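#' Baseline-correct an epoch tensor
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus baseline
#' period (all samples with time < 0 ms). Guarded against double
#' application via the tensor's \code{baseline_corrected} flag.
#'
#' @param epochs an \code{epoch_tensor} or list of them.
#' @return the corrected tensor(s) with the state flag set.
#' @export
baseline_correct <- function(epochs) {
  if (!inherits(epochs, "epoch_tensor"))
    return(lapply(epochs, baseline_correct))
  if (isTRUE(epochs$baseline_corrected))
    stop_mod("preprocess", "epochs are already baseline corrected")
  base_idx <- which(epochs$time < 0)
  if (length(base_idx) == 0)
    stop_mod("preprocess", "no pre-stimulus samples to use as baseline")
  bl <- rowMeans(epochs$data[, , base_idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Vector-normalize subdivision patterns
#'
#' For every epoch and timepoint, scales the vector of subdivision values to
#' unit Euclidean norm. By default normalization is within each ROI (its 8
#' subdivisions form one feature vector), so each ROI's evidence is purely
#' pattern-directional; \code{scope = "global"} instead normalizes across
#' all channels jointly. Exact zero vectors are left at zero.
#'
#' @param epochs a baseline-corrected \code{epoch_tensor} or list of them.
#' @param scope \code{"roi"} (default) or \code{"global"}.
#' @return the normalized tensor(s) with the state flag set.
#' @export
vector_normalize <- function(epochs, scope = c("roi", "global")) {
  scope <- match.arg(scope)
  if (!inherits(epochs, "epoch_tensor"))
    return(lapply(epochs, vector_normalize, scope = scope))
  if (!isTRUE(epochs$baseline_corrected))
    stop_mod("preprocess", "baseline correction must precede normalization")
  if (isTRUE(epochs$normalized))
    stop_mod("preprocess", "epochs are already normalized")
  d <- epochs$n_subdivisions
  dm <- dim(epochs$data)
  if (scope == "roi") {
    for (r in seq_len(epochs$n_rois)) {
      ch <- (r - 1L) * d + seq_len(d)
      block <- epochs$data[, ch, , drop = FALSE]
      nrm <- sqrt(colSums(aperm(block^2, c(2, 1, 3)))) # trials x time
      nrm[nrm == 0] <- 1
      epochs$data[, ch, ] <- block /
        aperm(array(nrm, c(dm[1], dm[3], d)), c(1, 3, 2))
    }
  } else {
    nrm <- sqrt(colSums(aperm(epochs$data^2, c(2, 1, 3))))
    nrm[nrm == 0] <- 1
    epochs$data <- epochs$data /
      aperm(array(nrm, c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  }
  epochs$normalized <- TRUE
  epochs
}

#' Random pseudo-trial bin assignments
#'
#' Randomly partitions each condition's correct trials into disjoint bins of
#' \code{bin_size} trials, repeated \code{n_assignments} times. Within an
#' assignment, \code{floor(n_correct / bin_size)} bins are formed per
#' condition and leftover trials are dropped at random, keeping bin
#' signal-to-noise homogeneous across assignments.
#'
#' @param metadata a trial metadata data.frame with a logical
#'   \code{correct} column (e.g. \code{epochs$trials}).
#' @param conditions named list of integer vectors of candidate trial row
#'   indices (into \code{metadata}) per condition.
#' @param bin_size trials per bin.
#' @param n_assignments number of independent random assignments.
#' @param seed integer seed.
#' @return a list of \code{n_assignments} assignments; each is a named list
#'   (per condition) of lists of integer trial-index vectors.
#' @export
make_bins <- function(metadata, conditions, bin_size = 8L,
                      n_assignments = 100L, seed = 1L) {
  stopifnot(is.list(conditions), length(names(conditions)) == length(conditions))
  usable <- lapply(conditions, function(idx) idx[metadata$correct[idx]])
  n_ok <- vapply(usable, length, 1L)
  bad <- names(usable)[n_ok < bin_size]
  if (length(bad) > 0)
    stop_mod("preprocess",
             "condition(s) with fewer than %d correct trials: %s",
             bin_size, paste(bad, collapse = ", "))
  with_seed(derive_seed(seed, "bins"), {
    lapply(seq_len(n_assignments), function(a) {
      lapply(usable, function(idx) {
        n_bins <- length(idx) %/% bin_size
        perm <- sample(idx)[seq_len(n_bins * bin_size)]
        split(perm, rep(seq_len(n_bins), each = bin_size))
      })
    })
  })
}

#' Average epochs within bins
#'
#' @param epochs an \code{epoch_tensor}.
#' @param bins a list of integer trial-index vectors (one bin assignment for
#'   one condition, as produced by \code{\link{make_bins}}).
#' @return an array \code{bins x channels x timepoints} of bin means.
#' @export
average_bins <- function(epochs, bins) {
  dm <- dim(epochs$data)
  idx_all <- unlist(bins)
  if (any(idx_all < 1 | idx_all > dm[1]))
    stop_mod("preprocess", "bin trial index out of range 1..%d", dm[1])
  out <- array(0, c(length(bins), dm[2], dm[3]))
  for (b in seq_along(bins)) {
    out[b, , ] <- colMeans(epochs$data[bins[[b]], , , drop = FALSE])
  }
  out
}
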