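#' Run the full synthetic study end to end
#'
#' Orchestrates design, simulation, preprocessing, transfer decoding (all
#' requested training conditions), cluster-based permutation inference
#' (single-condition, lexicality contrast, positional contrast) and the
#' decoding-informed Granger analysis on the word-trained decoding ROIs.
#' Every stochastic stage draws its seed deterministically from \code{seed},
#' and all seeds are recorded in the returned manifest.
#'
#' @param config a \code{\link{design_config}}.
#' @param truth a \code{\link{ground_truth}}.
#' @param seed master seed.
#' @param conditions training conditions to decode.
#' @param rois ROI indices to decode (default all).
#' @param bin_size,n_assignments binning parameters.
#' @param n_perm permutations for the cluster tests.
#' @param error_rates c(word, nonword) behavioral error rates.
#' @param control_pair ROI pair for the GC control connection; defaults to
#'   the two highest-numbered ROIs without significant word-trained
#'   decoding.
#' @param decoding_rois candidate ROIs for the GC stage; defaults to the
#'   ROIs with Bonferroni-significant word-trained clusters.
#' @param gc_window,gc_downsample,gc_order,gc_surrogates GC stage settings.
#' @param out_dir optional directory: stage outputs are also written as TSV.
#' @param verbose print stage progress.
#' @return object of class \code{study_result}: cluster record tables,
#'   decoding time courses, GC table and a run manifest.
#' @export
run_study <- function(config, truth, seed = config$seed,
                      conditions = decoding_conditions(), rois = NULL,
                      bin_size = 8L, n_assignments = 10L, n_perm = 200L,
                      error_rates = c(0.08, 0.14), control_pair = NULL,
                      decoding_rois = NULL, gc_window = c(250, 550),
                      gc_downsample = 1L, gc_order = 5L,
                      gc_surrogates = 100L, out_dir = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  timings <- c()
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  clock <- function(stage, expr) {
    st <- Sys.time()
    val <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    val
  }
  seeds <- list(schedule = derive_seed(seed, "stage_design"),
                behavior = derive_seed(seed, "stage_behavior"),
                decode = derive_seed(seed, "stage_decode"),
                clusters = derive_seed(seed, "stage_clusters"),
                gc = derive_seed(seed, "stage_gc"))

  say("design: building stimulus set and schedule")
  stimuli <- build_stimulus_set(config)
  schedule <- clock("design", make_schedule(config, seeds$schedule, stimuli))

  say("synthdata: simulating %d subject(s)", config$n_subjects)
  epochs <- clock("synthdata", {
    ep <- simulate_epochs(schedule, truth, config, stimuli)
    mark_behavioral_errors(ep, error_rates[1], error_rates[2],
                           seed = seeds$behavior)
  })

  say("preprocess: baseline correction and vector normalization")
  epochs <- clock("preprocess", vector_normalize(baseline_correct(epochs)))

  if (is.null(rois)) rois <- seq_len(config$n_rois)
  say("decode: %d condition(s) x %d ROI(s) x %d subject(s)",
      length(conditions), length(rois), length(epochs))
  dec <- clock("decode",
               decode_study(epochs, stimuli, conditions = conditions,
                            rois = rois, bin_size = bin_size,
                            n_assignments = n_assignments,
                            seed = seeds$decode))

  say("clusterstats: single-condition and contrast tests (n_perm = %d)", n_perm)
  cluster_tabs <- clock("clusterstats", {
    single <- lapply(seq_along(conditions), function(ci)
      cluster_test(sub_acc(dec$acc, ci),
                   dec$time, chance = dec$chance, n_perm = n_perm,
                   seed = derive_seed(seeds$clusters, ci),
                   condition = conditions[ci]))
    names(single) <- conditions
    out <- list(single = do.call(rbind, single))
    contrast <- function(a, b, salt) {
      if (all(c(a, b) %in% conditions)) {
        ai <- match(a, conditions); bi <- match(b, conditions)
        cluster_test_between(
          sub_acc(dec$acc, ai), sub_acc(dec$acc, bi), dec$time,
          chance = dec$chance, n_perm = n_perm,
          seed = derive_seed(seeds$clusters, salt), labels = c(a, b))
      } else NULL
    }
    out$lexicality <- contrast("words_only", "nonwords_only", 101L)
    out$positional <- contrast("cv_overlap", "vc_overlap", 102L)
    out
  })

  sig_words <- unique(cluster_tabs$single$roi[
    cluster_tabs$single$condition == "words_only" &
      cluster_tabs$single$significant])
  sig_word_rois <- as.integer(sub("roi_", "", sig_words))
  if (is.null(decoding_rois)) decoding_rois <- sort(sig_word_rois)

  gc <- NULL
  if (length(decoding_rois) >= 2 && "words_only" %in% conditions) {
    if (is.null(control_pair)) {
      nondec <- setdiff(rois, decoding_rois)
      if (length(nondec) >= 2)
        control_pair <- utils::tail(sort(nondec), 2)
    }
    if (!is.null(control_pair)) {
      say("connectivity: %d candidate ROI(s), control pair (%d, %d)",
          length(decoding_rois), control_pair[1], control_pair[2])
      gc <- clock("connectivity",
                  gc_study(epochs, dec, decoding_rois, control_pair,
                           window = gc_window, downsample = gc_downsample,
                           order = gc_order, n_surrogates = gc_surrogates,
                           seed = seeds$gc))
    } else say("connectivity: skipped (no control pair available)")
  } else {
    say("connectivity: skipped (fewer than 2 word-decoding ROIs)")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lexidecode")),
    config = unclass(config), master_seed = seed, seeds = seeds,
    n_assignments = n_assignments, n_perm = n_perm,
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- structure(list(stimuli = stimuli, schedule = schedule,
                        decoding = dec, clusters = cluster_tabs,
                        decoding_rois = decoding_rois,
                        control_pair = control_pair, gc = gc,
                        manifest = manifest),
                   class = "study_result")
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

sub_acc <- function(acc, ci) {
  out <- acc[, , ci, , drop = FALSE]
  array(out, dim(acc)[c(1, 2, 4)],
        dimnames = list(NULL, dimnames(acc)[[2]], NULL))
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_schedule(res$schedule, file.path(out_dir, "schedule.tsv"))
  write_cluster_records(res$clusters$single,
                        file.path(out_dir, "clusters_single.tsv"))
  if (!is.null(res$clusters$lexicality))
    write_cluster_records(res$clusters$lexicality,
                          file.path(out_dir, "clusters_lexicality.tsv"))
  if (!is.null(res$clusters$positional))
    write_cluster_records(res$clusters$positional,
                          file.path(out_dir, "clusters_positional.tsv"))
  if (!is.null(res$gc))
    write_gc_result(res$gc, file.path(out_dir, "gc_result.tsv"))
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Human-readable study report
#'
#' @param results a \code{\link{run_study}} result.
#' @return character vector of report lines (invisibly); printed.
#' @export
report <- function(results) {
  if (!inherits(results, "study_result"))
    stop_mod("pipeline", "expected a study_result")
  needed <- c("decoding", "clusters", "manifest")
  missing <- needed[!vapply(needed, function(f) !is.null(results[[f]]), TRUE)]
  if (length(missing) > 0)
    stop_mod("pipeline", "missing stage output(s): %s",
             paste(missing, collapse = ", "))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  dm <- dim(results$decoding$acc)
  add("Synthetic study report")
  add("======================")
  add("Decoding: %d subjects x %d ROIs x %d conditions, %d timepoints",
      dm[1], dm[2], dm[3], dm[4])
  for (ci in seq_along(results$decoding$conditions)) {
    cond <- results$decoding$conditions[ci]
    gm <- mean(results$decoding$acc[, , ci, ])
    add("  %-14s grand-mean accuracy %.3f (chance %.2f)",
        cond, gm, results$decoding$chance)
  }
  fmt_clusters <- function(tab, title) {
    add("%s:", title)
    sig <- tab[tab$significant, , drop = FALSE]
    if (nrow(sig) == 0) {
      add("  no significant clusters")
    } else {
      for (i in seq_len(nrow(sig)))
        add("  %-8s %-24s %4g-%4g ms (size %d, p = %.4g)",
            sig$roi[i], sig$condition[i], sig$start_ms[i], sig$end_ms[i],
            sig$size[i], sig$p_value[i])
    }
  }
  fmt_clusters(results$clusters$single, "Single-condition clusters")
  if (!is.null(results$clusters$lexicality))
    fmt_clusters(results$clusters$lexicality,
                 "Lexicality contrast (words vs nonwords)")
  if (!is.null(results$clusters$positional))
    fmt_clusters(results$clusters$positional,
                 "Positional contrast (CV vs VC overlap)")
  if (!is.null(results$gc)) {
    add("Granger causality (window %g-%g ms):",
        results$gc$window[1], results$gc$window[2])
    sig <- results$gc$table[results$gc$table$fdr_significant, , drop = FALSE]
    if (nrow(sig) == 0) {
      add("  no significant interactions")
    } else {
      for (i in seq_len(nrow(sig)))
        add("  ROI %d -> ROI %d%s (%d/%d sig. timepoints, p = %.3g)",
            sig$source[i], sig$target[i],
            ifelse(sig$reciprocal[i], " [reciprocal]", ""),
            sig$sig_count[i], sig$window_len[i], sig$binomial_p[i])
    }
  } else {
    add("Granger causality: not run")
  }
  add("Total runtime: %.1f s", results$manifest$total_sec)
  cat(ln, sep = "\n")
  invisible(ln)
}

#' @export
print.study_result <- function(x, ...) {
  report(x)
  invisible(x)
}
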