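# Decoding-informed time-varying Granger causality.
#
# A candidate source ROI contributes its 8 subdivision event-related time
# courses; the target ROI is represented by its within-subject transfer
# decoding accuracy time course (word-neighbor training, averaged across
# pairwise contrasts). The target is predicted one step ahead by an
# adaptive MVAR (Kalman filter with random-walk coefficients); the GC index
# is the log ratio of reduced-model to full-model smoothed prediction error
# variance, floored at zero.

# Build a lagged design matrix: Phi[t - order, (ch-1)*order + l] = M[t - l, ch].
make_lags <- function(M, order) {
  Tn <- nrow(M); nc <- ncol(M)
  Te <- Tn - order
  Phi <- matrix(0, Te, nc * order)
  for (ch in seq_len(nc))
    for (l in seq_len(order))
      Phi[, (ch - 1L) * order + l] <- M[(order - l + 1L):(Tn - l), ch]
  Phi
}

# Columns of the lag matrix belonging to a set of channels.
lag_cols <- function(channels, order) {
  order <- as.integer(order)
  as.vector(vapply(as.integer(channels), function(ch)
    (ch - 1L) * order + seq_len(order), integer(order)))
}

zscore_by_window <- function(x, win) {
  mu <- mean(x[win]); s <- sd(x[win])
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mu) / s
}

# Moving-average downsampling by an integer factor.
decimate <- function(x, factor) {
  if (factor <= 1) return(x)
  n <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(n * factor)], nrow = factor))
}

#' Assemble node signals for the Granger analysis
#'
#' For each subject, pairs the target ROI's decoding-accuracy time course
#' (word-neighbor training condition, averaged across pairwise contrasts)
#' with the event-related subdivision time courses of every other ROI as
#' predictors. All signals are restricted to the analysis window plus a
#' leading adaptation segment, optionally decimated, and z-scored using the
#' analysis-window statistics.
#'
#' @param epochs_list list of preprocessed \code{epoch_tensor}s (one per
#'   subject, same order as the decoding result).
#' @param dec a \code{\link{decode_study}} result containing the
#'   \code{condition} accuracy.
#' @param target_roi the ROI whose decoding accuracy is to be predicted.
#' @param decoding_rois optional set of candidate (significantly decoding)
#'   ROIs; if given, \code{target_roi} must belong to it.
#' @param condition training condition of the accuracy curves.
#' @param window analysis window in ms (default 250-550).
#' @param burn_ms leading segment before the window used for filter
#'   adaptation and lag history.
#' @param downsample integer decimation factor applied to all signals.
#' @param demean \code{"ensemble"} (default) subtracts the cross-subject
#'   mean from every signal before z-scoring, so prediction operates on
#'   induced, subject-specific fluctuations rather than the evoked
#'   component shared by all subjects (which is symmetric between regions
#'   and uninformative about direction); \code{"none"} keeps raw signals.
#' @return list with one element per subject: \code{target} (numeric),
#'   \code{pred} (time x channels matrix), \code{map} (channel-to-ROI map),
#'   \code{win} (logical analysis-window mask), \code{time}.
#' @export
assemble_node_signals <- function(epochs_list, dec, target_roi,
                                  decoding_rois = NULL,
                                  condition = "words_only",
                                  window = c(250, 550), burn_ms = 150,
                                  downsample = 1L,
                                  demean = c("ensemble", "none")) {
  demean <- match.arg(demean)
  if (!is.null(decoding_rois) && !(target_roi %in% decoding_rois))
    stop_mod("connectivity", "target ROI %d is not in the candidate decoding set",
             target_roi)
  if (!(condition %in% dec$conditions))
    stop_mod("connectivity", "decoding result lacks condition '%s'", condition)
  ci <- match(condition, dec$conditions)
  ti <- match(target_roi, dec$rois)
  if (is.na(ti))
    stop_mod("connectivity", "target ROI %d was not decoded", target_roi)
  raw <- lapply(seq_along(epochs_list), function(si) {
    ep <- epochs_list[[si]]
    d <- ep$n_subdivisions
    seg <- which(ep$time >= window[1] - burn_ms & ep$time <= window[2])
    tseg <- ep$time[seg]
    ok <- ep$trials$correct
    erp <- colMeans(ep$data[ok, , seg, drop = FALSE])  # channels x window
    y <- dec$acc[si, ti, ci, seg]
    pred_rois <- setdiff(seq_len(ep$n_rois), target_roi)
    cols <- unlist(lapply(pred_rois, function(r) (r - 1L) * d + seq_len(d)))
    X <- t(erp[cols, , drop = FALSE])
    if (downsample > 1L) {
      y <- decimate(y, downsample)
      X <- apply(X, 2, decimate, factor = downsample)
      tseg <- decimate(tseg, downsample)
    }
    list(target = y, pred = X,
         map = data.frame(column = seq_along(cols),
                          roi = rep(pred_rois, each = d),
                          subdivision = rep(seq_len(d), length(pred_rois))),
         time = tseg)
  })
  if (demean == "ensemble" && length(raw) > 1) {
    my <- Reduce(`+`, lapply(raw, `[[`, "target")) / length(raw)
    mX <- Reduce(`+`, lapply(raw, `[[`, "pred")) / length(raw)
    raw <- lapply(raw, function(sg) {
      sg$target <- sg$target - my
      sg$pred <- sg$pred - mX
      sg
    })
  }
  lapply(raw, function(sg) {
    win <- sg$time >= window[1] & sg$time <= window[2]
    sg$target <- zscore_by_window(sg$target, win)
    sg$pred <- apply(sg$pred, 2, zscore_by_window, win = win)
    sg$win <- win
    sg
  })
}

#' Time-varying Granger causality index via an adaptive Kalman MVAR
#'
#' Fits two adaptive one-step predictors of the target signal from lagged
#' values of the target itself and the predictor channels: the full model
#' uses all channels, the reduced model excludes \code{source_cols}. The GC
#' index at each timepoint is \code{ln(reduced error variance / full error
#' variance)}, floored at 0, where error variances are exponentially
#' smoothed squared one-step prediction errors.
#'
#' @param target numeric target series.
#' @param pred time x channels predictor matrix.
#' @param source_cols columns of \code{pred} belonging to the tested source
#'   ROI.
#' @param order MVAR model order (lags).
#' @param adapt_const Kalman adaptation constant (coefficient random-walk
#'   gain and observation-noise tracking).
#' @param error_smooth exponential smoothing constant of the reported
#'   error-variance time course (shorter memory than \code{adapt_const}
#'   keeps the GC index temporally localized).
#' @param p0 initial coefficient prior variance.
#' @return list: \code{gc} (length \code{length(target) - order}, aligned
#'   to times \code{(order+1):T}), \code{ema_full}, \code{ema_reduced}.
#' @export
kalman_mvar_gc <- function(target, pred, source_cols, order = 5L,
                           adapt_const = 0.02, error_smooth = 0.2, p0 = 10) {
  if (order < 1) stop_mod("connectivity", "order must be >= 1")
  Tn <- length(target)
  if (Tn - order < 2 * order)
    stop_mod("connectivity", "series too short for order %d", order)
  if (!all(is.finite(target)) || !all(is.finite(pred)))
    stop_mod("connectivity", "non-finite values in signals")
  M <- cbind(target, pred)
  Phi <- make_lags(M, order)
  y <- target[(order + 1L):Tn]
  full <- cpp_kalman_errors(y, Phi, adapt_const, error_smooth, p0)
  drop_cols <- lag_cols(source_cols + 1L, order)  # +1: target is column 1
  red <- cpp_kalman_errors(y, Phi[, -drop_cols, drop = FALSE],
                           adapt_const, error_smooth, p0)
  raw <- log(red$ema / full$ema)
  list(gc = pmax(0, raw), gc_raw = raw,
       ema_full = full$ema, ema_reduced = red$ema)
}

# Stationary OLS-VAR Granger index on the same signals; independent
# reference route used to sanity-check the adaptive estimator.
ols_gc <- function(target, pred, source_cols, order = 5L) {
  Tn <- length(target)
  M <- cbind(target, pred)
  Phi <- make_lags(M, order)
  y <- target[(order + 1L):Tn]
  rss <- function(X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    sum(fit$residuals^2)
  }
  drop_cols <- lag_cols(source_cols + 1L, order)
  log(rss(Phi[, -drop_cols, drop = FALSE]) / rss(Phi))
}

#' Per-timepoint significance of a GC index against surrogates
#'
#' A timepoint is significant when the observed GC index exceeds the
#' (1 - alpha) quantile of the surrogate GC ensemble at that timepoint.
#'
#' @param gc_index observed GC index time course.
#' @param surrogate_ensemble matrix (surrogates x timepoints) of GC indices
#'   computed on source-shuffled data; at least 100 surrogates.
#' @param alpha per-timepoint alpha.
#' @return logical significance mask.
#' @export
gc_significance <- function(gc_index, surrogate_ensemble, alpha = 0.05) {
  surrogate_ensemble <- as.matrix(surrogate_ensemble)
  if (nrow(surrogate_ensemble) < 100)
    stop_mod("connectivity", "need at least 100 surrogates, got %d",
             nrow(surrogate_ensemble))
  if (ncol(surrogate_ensemble) != length(gc_index))
    stop_mod("connectivity", "surrogate/observed timepoint mismatch")
  if (alpha >= 1) return(rep(TRUE, length(gc_index)))
  thr <- apply(surrogate_ensemble, 2, quantile, probs = 1 - alpha,
               names = FALSE)
  gc_index > thr
}

#' Exact one-tailed binomial test against a control connection rate
#'
#' Tail probability of observing at least \code{sig_count} significant
#' timepoints among \code{window_len} at the control pair's rate.
#'
#' @param sig_count observed count of significant timepoints.
#' @param window_len number of timepoints in the analysis window.
#' @param control_rate control pair's significant-timepoint rate, in (0,1).
#' @return one-tailed p-value.
#' @export
binomial_vs_control <- function(sig_count, window_len, control_rate) {
  if (sig_count > window_len)
    stop_mod("connectivity", "sig_count exceeds window length")
  if (control_rate <= 0 || control_rate >= 1)
    stop_mod("connectivity", "control_rate must lie in (0,1)")
  pbinom(sig_count - 1, window_len, control_rate, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up FDR control over the candidate directed ROI pairs.
#'
#' @param p_values numeric vector in (0, 1].
#' @param q FDR level.
#' @return logical flags.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  p.adjust(p_values, method = "BH") <= q
}

# GC curve (group mean over subjects) and surrogate ensemble for one
# directed pair. Surrogate schemes:
#   donor_shift (default): each target is re-paired with the source
#     channels of a different subject, additionally rotated in time by a
#     random circular shift. Re-pairing destroys the subject-level
#     dependence that carries genuine directed influence while preserving
#     the marginal structure of a realistic source; the extra shift makes
#     the surrogate pool effectively continuous, so ensemble quantiles are
#     not deflated by the small number of subject pairings.
#   subject_shuffle: re-pairing only; preserves evoked alignment exactly,
#     at the cost of a finite (n_subj^2 - n_subj) surrogate pool.
#   circular_shift: within-subject rotation only; exact for stationary
#     signals but anticonservative when evoked variance is time-locked
#     inside the analysis segment.
# Only the full model is recomputed per surrogate; the reduced model does
# not involve the source.
gc_pair_curves <- function(signals, source_roi, order, adapt_const,
                           error_smooth, n_surrogates, compress, seed,
                           surrogate = c("donor_shift", "subject_shuffle",
                                         "circular_shift")) {
  surrogate <- match.arg(surrogate)
  per_subj <- lapply(seq_along(signals), function(si) {
    sg <- signals[[si]]
    src_cols <- sg$map$column[sg$map$roi == source_roi]
    if (length(src_cols) == 0)
      stop_mod("connectivity", "source ROI %d not among predictors", source_roi)
    other_rois <- setdiff(unique(sg$map$roi), source_roi)
    if (compress && length(other_rois) > 0) {
      comp <- vapply(other_rois, function(r) {
        cols <- sg$map$column[sg$map$roi == r]
        sc <- prcomp(sg$pred[, cols, drop = FALSE], center = FALSE,
                     scale. = FALSE)$x[, 1]
        sc / max(sd(sc), 1e-12)
      }, numeric(nrow(sg$pred)))
      X <- cbind(sg$pred[, src_cols, drop = FALSE], comp)
      src_idx <- seq_along(src_cols)
    } else {
      X <- sg$pred
      src_idx <- src_cols
    }
    list(y = sg$target, X = X, src_idx = src_idx, win = sg$win)
  })
  n_subj <- length(per_subj)
  obs <- lapply(per_subj, function(ps)
    kalman_mvar_gc(ps$y, ps$X, ps$src_idx, order, adapt_const, error_smooth))
  obs_red <- lapply(obs, `[[`, "ema_reduced")
  gc_obs <- Reduce(`+`, lapply(obs, `[[`, "gc")) / n_subj
  # Unfloored group-mean log ratio: the quantity thresholded against the
  # surrogate ensemble (flooring first would let near-zero observed values
  # beat a floored null wherever most surrogates are negative).
  gc_obs_raw <- Reduce(`+`, lapply(obs, `[[`, "gc_raw")) / n_subj

  gc_full <- function(si, Xsrc) {
    ps <- per_subj[[si]]
    Xs <- ps$X
    Xs[, ps$src_idx] <- Xsrc
    full <- cpp_kalman_errors(ps$y[-seq_len(order)],
                              make_lags(cbind(ps$y, Xs), order),
                              adapt_const, error_smooth, 10)
    log(obs_red[[si]] / full$ema)
  }
  Tn <- length(per_subj[[1]]$y)
  surr <- with_seed(derive_seed(seed, paste0("surr", source_roi)), {
    t(vapply(seq_len(n_surrogates), function(k) {
      if (surrogate != "circular_shift" && n_subj > 1) {
        # permutation of subjects without fixed points
        repeat {
          perm <- sample(n_subj)
          if (!any(perm == seq_len(n_subj))) break
        }
        gs <- lapply(seq_len(n_subj), function(si) {
          donor <- per_subj[[perm[si]]]
          Xsrc <- donor$X[, donor$src_idx, drop = FALSE]
          if (surrogate == "donor_shift") {
            sh <- sample(Tn - 1L, 1L)
            Xsrc <- Xsrc[c((sh + 1L):Tn, seq_len(sh)), , drop = FALSE]
          }
          gc_full(si, Xsrc)
        })
      } else {
        gs <- lapply(seq_len(n_subj), function(si) {
          ps <- per_subj[[si]]
          sh <- sample(Tn - 1L, 1L)
          idx <- c((sh + 1L):Tn, seq_len(sh))
          gc_full(si, ps$X[idx, ps$src_idx, drop = FALSE])
        })
      }
      Reduce(`+`, gs) / n_subj
    }, numeric(length(gc_obs))))
  })
  win_gc <- per_subj[[1]]$win[-seq_len(order)]
  list(gc = gc_obs, gc_raw = gc_obs_raw, surrogates = surr, win = win_gc)
}

#' Decoding-informed Granger causality over candidate ROI pairs
#'
#' For every ordered pair of candidate (decoding) ROIs, asks whether the
#' source ROI's subdivision activity improves one-step prediction of the
#' target ROI's decoding-accuracy time course beyond all other ROIs'
#' activity. Per-timepoint significance is calibrated against circular-shift
#' surrogates; the count of significant timepoints in the analysis window
#' is compared with a control ROI pair by an exact binomial test, and the
#' resulting p-values are Benjamini-Hochberg corrected over the candidate
#' directed pairs.
#'
#' @inheritParams assemble_node_signals
#' @param decoding_rois candidate ROI indices (those with significant
#'   word-trained transfer decoding).
#' @param control_pair length-2 ROI indices of the control pair (regions
#'   without transfer decoding or a plausible processing relationship).
#' @param order,adapt_const,error_smooth adaptive MVAR parameters.
#' @param n_surrogates surrogates per pair (>= 100).
#' @param surrogate null scheme: \code{"donor_shift"} (default) re-pairs
#'   each target with another subject's source channels and additionally
#'   rotates them in time; \code{"subject_shuffle"} re-pairs only;
#'   \code{"circular_shift"} rotates within subject only.
#' @param demean see \code{\link{assemble_node_signals}}.
#' @param alpha per-timepoint alpha for the GC index.
#' @param q FDR level over directed pairs.
#' @param compress compress non-source predictor ROIs to their first
#'   principal component (keeps the model well-posed at full ROI count).
#' @param seed integer seed.
#' @return object of class \code{gc_result}: a table with one row per
#'   directed candidate pair (\code{source}, \code{target},
#'   \code{sig_count}, \code{window_len}, \code{binomial_p},
#'   \code{fdr_significant}, \code{reciprocal}) plus curves and the control
#'   rate.
#' @export
gc_study <- function(epochs_list, dec, decoding_rois, control_pair,
                     condition = "words_only", window = c(250, 550),
                     burn_ms = 150, downsample = 1L, order = 5L,
                     adapt_const = 0.02, error_smooth = 0.2,
                     n_surrogates = 200L, alpha = 0.05,
                     q = 0.05, compress = TRUE,
                     surrogate = c("donor_shift", "subject_shuffle",
                                   "circular_shift"),
                     demean = c("ensemble", "none"), seed = 1L) {
  surrogate <- match.arg(surrogate)
  demean <- match.arg(demean)
  if (length(decoding_rois) < 2)
    stop_mod("connectivity", "need at least 2 candidate ROIs")
  sig_cache <- new.env(parent = emptyenv())
  signals_for <- function(tgt) {
    key <- as.character(tgt)
    if (is.null(sig_cache[[key]]))
      sig_cache[[key]] <- assemble_node_signals(
        epochs_list, dec, tgt, decoding_rois = NULL, condition = condition,
        window = window, burn_ms = burn_ms, downsample = downsample,
        demean = demean)
    sig_cache[[key]]
  }
  run_pair <- function(src, tgt) {
    cur <- gc_pair_curves(signals_for(tgt), src, order, adapt_const,
                          error_smooth, n_surrogates, compress,
                          derive_seed(seed, src * 1000L + tgt),
                          surrogate = surrogate)
    mask <- gc_significance(cur$gc_raw, cur$surrogates, alpha)
    list(sig_count = sum(mask[cur$win]), window_len = sum(cur$win),
         gc = cur$gc, mask = mask, win = cur$win)
  }
  # Control rate from the designated non-decoding pair (both directions).
  c12 <- run_pair(control_pair[1], control_pair[2])
  c21 <- run_pair(control_pair[2], control_pair[1])
  wl <- c12$window_len
  # Pool both control directions and shrink toward the nominal
  # per-timepoint level with one pseudo-window of weight: the control pair
  # contributes only 2 x window_len timepoints, and its raw rate is too
  # noisy to serve as a binomial null on its own. Floor at 1/window_len.
  control_rate <- max(
    (c12$sig_count + c21$sig_count + wl * alpha) / (3 * wl),
    1 / wl)

  pairs <- expand.grid(source = decoding_rois, target = decoding_rois)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  rownames(pairs) <- NULL
  curves <- vector("list", nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- run_pair(pairs$source[i], pairs$target[i])
    curves[[i]] <- r
    rows[[i]] <- data.frame(
      source = pairs$source[i], target = pairs$target[i],
      sig_count = r$sig_count, window_len = r$window_len,
      binomial_p = binomial_vs_control(r$sig_count, r$window_len,
                                       control_rate))
  }
  tab <- do.call(rbind, rows)
  tab$fdr_significant <- fdr_correct(tab$binomial_p, q)
  tab$reciprocal <- mapply(function(s, t) {
    rev_i <- which(tab$source == t & tab$target == s)
    tab$fdr_significant[tab$source == s & tab$target == t] &&
      length(rev_i) == 1 && tab$fdr_significant[rev_i]
  }, tab$source, tab$target)
  structure(list(table = tab, curves = curves, control_rate = control_rate,
                 window = window, alpha = alpha, q = q, order = order,
                 adapt_const = adapt_const, n_surrogates = n_surrogates),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("Granger causality over %d directed pairs (window %g-%g ms)\n",
              nrow(x$table), x$window[1], x$window[2]))
  cat(sprintf("  control rate: %.4f; FDR q = %g\n", x$control_rate, x$q))
  sig <- x$table[x$table$fdr_significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    cat("  no significant interactions\n")
  } else {
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  ROI %d -> ROI %d: %d/%d sig. timepoints, p = %.3g%s\n",
                  sig$source[i], sig$target[i], sig$sig_count[i],
                  sig$window_len[i], sig$binomial_p[i],
                  ifelse(sig$reciprocal[i], " (reciprocal)", "")))
  }
  invisible(x)
}

#' Write a GC result table to TSV
#' @param gc a \code{gc_result}.
#' @param path file path.
#' @export
write_gc_result <- function(gc, path) {
  write.table(gc$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
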