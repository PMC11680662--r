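#' Null calibration of the decoding and cluster-inference pipeline
#'
#' Generates repeated zero-signal datasets (pure-noise source activity
#' under the full experimental design), runs each through preprocessing,
#' pairwise transfer decoding and the single-condition cluster permutation
#' test, and summarizes two calibration quantities: the grand-mean decoding
#' accuracy (which must converge to the 50\% pairwise chance level) and the
#' family-wise false-positive rate of the Bonferroni-gated cluster
#' procedure (which must not exceed the nominal level).
#'
#' Problem sizes default to the package's desk-scale calibration
#' conditions: 8 subjects, 5 ROIs, 40 Hz source sampling, 3 bin
#' assignments, 200 sign-flip permutations.
#'
#' @param n_datasets number of independent simulated datasets.
#' @param n_subjects,n_rois,sample_rate design dimensions per dataset.
#' @param n_assignments,bin_size binning parameters for decoding.
#' @param n_perm permutations for the cluster null.
#' @param cluster_alpha cluster-forming (pointwise) alpha.
#' @param fw_alpha family-wise alpha for the Bonferroni gate (over the
#'   simulated ROI family).
#' @param error_rates c(word, nonword) behavioral error rates.
#' @param condition training condition decoded.
#' @param seed master seed; dataset k uses seeds derived from (seed, k).
#' @param verbose print a progress line every 25 datasets.
#' @return object of class \code{null_calibration}: per-dataset table
#'   (\code{mean_acc}, \code{n_clusters}, \code{any_significant}),
#'   \code{grand_mean_acc}, \code{acc_se} (SE of the grand mean over
#'   datasets), \code{fwer} and its Monte-Carlo SE.
#' @export
null_calibration <- function(n_datasets = 200L, n_subjects = 8L,
                             n_rois = 5L, sample_rate = 40,
                             n_assignments = 3L, bin_size = 8L,
                             n_perm = 200L, cluster_alpha = 0.05,
                             fw_alpha = 0.05, error_rates = c(0.08, 0.14),
                             condition = "words_only", seed = 1L,
                             verbose = FALSE) {
  rows <- vector("list", n_datasets)
  for (k in seq_len(n_datasets)) {
    sk <- derive_seed(seed, 10000 + k)
    cfg <- design_config(n_subjects = n_subjects, n_rois = n_rois,
                         sample_rate = sample_rate, seed = sk)
    truth <- ground_truth(cfg, segmental_amp = 0, lexical_amp = 0)
    stimuli <- build_stimulus_set(cfg)
    sch <- make_schedule(cfg, derive_seed(sk, "sched"), stimuli)
    ep <- simulate_epochs(sch, truth, cfg, stimuli)
    ep <- mark_behavioral_errors(ep, error_rates[1], error_rates[2],
                                 seed = derive_seed(sk, "beh"))
    ep <- vector_normalize(baseline_correct(ep))
    dec <- decode_study(ep, stimuli, conditions = condition,
                        bin_size = bin_size,
                        n_assignments = n_assignments,
                        seed = derive_seed(sk, "dec"))
    recs <- cluster_test(sub_acc(dec$acc, 1L), dec$time,
                         chance = dec$chance, alpha = cluster_alpha,
                         n_perm = n_perm, seed = derive_seed(sk, "clu"),
                         n_rois_family = n_rois, condition = condition)
    rows[[k]] <- data.frame(dataset = k, mean_acc = mean(dec$acc),
                            n_clusters = nrow(recs),
                            any_significant = any(recs$significant))
    if (verbose && k %% 25 == 0)
      message(sprintf("null_calibration: %d/%d datasets", k, n_datasets))
  }
  tab <- do.call(rbind, rows)
  fwer <- mean(tab$any_significant)
  structure(list(
    datasets = tab,
    grand_mean_acc = mean(tab$mean_acc),
    acc_se = sd(tab$mean_acc) / sqrt(n_datasets),
    fwer = fwer,
    fwer_mc_se = sqrt(fw_alpha * (1 - fw_alpha) / n_datasets),
    n_datasets = n_datasets, n_subjects = n_subjects, n_rois = n_rois,
    n_perm = n_perm, fw_alpha = fw_alpha, seed = seed),
    class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf("Null calibration over %d zero-signal datasets (%d subjects, %d ROIs)\n",
              x$n_datasets, x$n_subjects, x$n_rois))
  cat(sprintf("  grand-mean accuracy: %.4f (SE %.5f; chance 0.5)\n",
              x$grand_mean_acc, x$acc_se))
  cat(sprintf("  family-wise cluster false-positive rate: %.3f (nominal %.2f, MC-SE %.3f)\n",
              x$fwer, x$fw_alpha, x$fwer_mc_se))
  invisible(x)
}
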