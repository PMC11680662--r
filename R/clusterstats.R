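# Group-level cluster-based sign-flip permutation inference on decoding
# accuracy time courses.

# One-sample t statistics per timepoint for a subjects x timepoints matrix
# of deviations. Degenerate zero-variance timepoints get t = sign(mean)*Inf
# (t = 0 when the mean is also zero, i.e. exactly at chance).
t_stats <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  s <- sqrt(v / n)
  t <- ifelse(s > 0, m / s, sign(m) * Inf)
  t[s == 0 & m == 0] <- 0
  t
}

#' Pointwise above-chance mask
#'
#' One-tailed one-sample t-test of accuracy against chance across subjects,
#' per timepoint.
#'
#' @param acc subjects x timepoints accuracy matrix.
#' @param chance chance level (0.5 for pairwise classification).
#' @param alpha uncorrected cluster-forming alpha.
#' @return logical vector over timepoints.
#' @export
pointwise_above_chance <- function(acc, chance = 0.5, alpha = 0.05) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2)
    stop_mod("clusterstats", "need at least 2 subjects, got %d", nrow(acc))
  t <- t_stats(acc - chance)
  t > stats::qt(1 - alpha, df = nrow(acc) - 1)
}

#' Find clusters of consecutive significant timepoints
#'
#' @param mask logical vector.
#' @return data.frame with columns \code{start}, \code{end} (sample
#'   indices, inclusive) and \code{size}.
#' @export
find_clusters <- function(mask) {
  mask <- as.logical(mask)
  if (length(mask) == 0 || !any(mask))
    return(data.frame(start = integer(0), end = integer(0), size = integer(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             size = r$lengths[keep])
}

max_cluster_size <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

#' Sign-flip permutation null for single-condition clusters
#'
#' Builds the null distribution of the maximum cluster size: per
#' permutation, each subject's deviation from chance is multiplied by an
#' independent random sign, the pointwise test and cluster search are
#' recomputed, and the largest cluster size is recorded. Observed cluster
#' p-values use the permutation convention p = (k + 1) / (n_perm + 1).
#'
#' @inheritParams pointwise_above_chance
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return list with \code{clusters} (observed clusters with \code{p_value})
#'   and \code{null_max_sizes}.
#' @export
permutation_null_single <- function(acc, chance = 0.5, alpha = 0.05,
                                    n_perm = 1000L, seed = 1L) {
  acc <- as.matrix(acc)
  if (n_perm < 1) stop_mod("clusterstats", "n_perm must be >= 1")
  if (nrow(acc) < 2)
    stop_mod("clusterstats", "need at least 2 subjects, got %d", nrow(acc))
  n <- nrow(acc)
  D <- acc - chance
  tcrit <- stats::qt(1 - alpha, df = n - 1)
  obs <- find_clusters(t_stats(D) > tcrit)

  null_max <- with_seed(derive_seed(seed, "permnull"), {
    flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    # Sign flips leave squared deviations unchanged, so per-permutation
    # means and t statistics come from one cross-product.
    SS <- colSums(D^2)
    M <- crossprod(D, flips) / n                    # timepoints x n_perm
    V <- (SS - n * M^2) / (n - 1)
    V[V < 0] <- 0
    Tm <- ifelse(V > 0, M / sqrt(V / n), sign(M) * Inf)
    Tm[V == 0 & M == 0] <- 0
    vapply(seq_len(n_perm),
           function(p) max_cluster_size(Tm[, p] > tcrit), 0L)
  })
  obs$p_value <- vapply(obs$size, function(s)
    (sum(null_max >= s) + 1) / (n_perm + 1), 0.0)
  list(clusters = obs, null_max_sizes = null_max)
}

#' Bonferroni gate over the ROI family
#'
#' Cluster p-values are compared against \code{alpha / n_rois}; with the
#' full 39-ROI family and alpha = 0.05 the threshold is 0.00128.
#'
#' @param p_values numeric vector of cluster p-values in (0, 1].
#' @param n_rois size of the ROI family tested.
#' @param alpha family-wise alpha.
#' @return logical significance flags.
#' @export
bonferroni_gate <- function(p_values, n_rois = 39L, alpha = 0.05) {
  p_values < alpha / n_rois
}

#' Dual-constraint between-condition cluster test
#'
#' Tests where condition A decodes better than condition B (and vice
#' versa). Timepoints enter a cluster only if the favored condition is
#' above chance (one-tailed, uncorrected \code{alpha}) \emph{and} the
#' paired difference is significant (two-tailed, uncorrected \code{alpha})
#' in the favored direction. The permutation null flips, per subject, the
#' relationship of the data to both null values: one random sign on the
#' mean deviation from chance and one on the A-B difference
#' (\code{flip = "independent"}, the default) or a single shared sign
#' (\code{flip = "joint"}); the maximum cluster size over both directions
#' is recorded per permutation.
#'
#' @param acc_A,acc_B subjects x timepoints accuracy matrices (matched).
#' @inheritParams permutation_null_single
#' @param flip flipping scheme for the dual null.
#' @return list with \code{clusters_A_gt_B}, \code{clusters_B_gt_A} (each
#'   with permutation \code{p_value}) and \code{null_max_sizes}.
#' @export
between_condition_clusters <- function(acc_A, acc_B, chance = 0.5,
                                       alpha = 0.05, n_perm = 1000L,
                                       seed = 1L,
                                       flip = c("independent", "joint")) {
  flip <- match.arg(flip)
  acc_A <- as.matrix(acc_A); acc_B <- as.matrix(acc_B)
  if (!all(dim(acc_A) == dim(acc_B)))
    stop_mod("clusterstats", "acc_A and acc_B must have identical dimensions")
  if (nrow(acc_A) < 2)
    stop_mod("clusterstats", "need at least 2 subjects")
  n <- nrow(acc_A)
  tcrit1 <- stats::qt(1 - alpha, df = n - 1)      # one-tailed above chance
  tcrit2 <- stats::qt(1 - alpha / 2, df = n - 1)  # two-tailed difference

  masks_both <- function(A, B) {
    d <- A - B
    td <- t_stats(d)
    diff_pos <- td > tcrit2
    diff_neg <- td < -tcrit2
    list(A = (t_stats(A - chance) > tcrit1) & diff_pos,
         B = (t_stats(B - chance) > tcrit1) & diff_neg)
  }
  obs <- masks_both(acc_A, acc_B)
  cl_A <- find_clusters(obs$A)
  cl_B <- find_clusters(obs$B)

  m_mat <- (acc_A + acc_B) / 2 - chance
  d_mat <- acc_A - acc_B
  null_max <- with_seed(derive_seed(seed, "permnull2"), {
    vapply(seq_len(n_perm), function(p) {
      e1 <- sample(c(-1, 1), n, replace = TRUE)
      e2 <- if (flip == "independent") sample(c(-1, 1), n, replace = TRUE) else e1
      Ap <- chance + e1 * m_mat + e2 * d_mat / 2
      Bp <- chance + e1 * m_mat - e2 * d_mat / 2
      mk <- masks_both(Ap, Bp)
      max(max_cluster_size(mk$A), max_cluster_size(mk$B))
    }, 0L)
  })
  pval <- function(cl) {
    cl$p_value <- vapply(cl$size, function(s)
      (sum(null_max >= s) + 1) / (n_perm + 1), 0.0)
    cl
  }
  list(clusters_A_gt_B = pval(cl_A), clusters_B_gt_A = pval(cl_B),
       null_max_sizes = null_max)
}

#' Cluster test over an ROI family
#'
#' Runs the single-condition sign-flip cluster permutation test for every
#' ROI of an accuracy array and applies the Bonferroni gate across the
#' family.
#'
#' @param acc subjects x ROIs x timepoints accuracy array.
#' @param time timepoint axis in ms (length = third dimension).
#' @param chance,alpha,n_perm,seed as in
#'   \code{\link{permutation_null_single}}.
#' @param n_rois_family Bonferroni family size (defaults to the number of
#'   ROIs in \code{acc}; the full design uses 39).
#' @param condition label stored in the output.
#' @return a \code{cluster_records} data.frame: \code{roi},
#'   \code{condition}, \code{start_ms}, \code{end_ms}, \code{size},
#'   \code{p_value}, \code{significant}.
#' @export
cluster_test <- function(acc, time, chance = 0.5, alpha = 0.05,
                         n_perm = 1000L, seed = 1L,
                         n_rois_family = dim(acc)[2],
                         condition = "words_only") {
  stopifnot(length(dim(acc)) == 3, length(time) == dim(acc)[3])
  rois <- dimnames(acc)[[2]] %||% paste0("roi_", seq_len(dim(acc)[2]))
  rows <- lapply(seq_len(dim(acc)[2]), function(ri) {
    res <- permutation_null_single(acc[, ri, ], chance, alpha, n_perm,
                                   seed = derive_seed(seed, ri))
    cl <- res$clusters
    if (nrow(cl) == 0) return(NULL)
    data.frame(roi = rois[ri], condition = condition,
               start_ms = time[cl$start], end_ms = time[cl$end],
               size = cl$size, p_value = cl$p_value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(roi = character(0), condition = character(0),
                      start_ms = numeric(0), end_ms = numeric(0),
                      size = integer(0), p_value = numeric(0))
  out$significant <- bonferroni_gate(out$p_value, n_rois_family, alpha = 0.05)
  class(out) <- c("cluster_records", "data.frame")
  out
}

#' Between-condition cluster test over an ROI family
#'
#' @param acc_A,acc_B subjects x ROIs x timepoints accuracy arrays.
#' @inheritParams cluster_test
#' @param labels length-2 condition labels for the two directions.
#' @param flip flipping scheme (see
#'   \code{\link{between_condition_clusters}}).
#' @return a \code{cluster_records} data.frame; \code{condition} is
#'   \code{"A>B"}-style using \code{labels}.
#' @export
cluster_test_between <- function(acc_A, acc_B, time, chance = 0.5,
                                 alpha = 0.05, n_perm = 1000L, seed = 1L,
                                 n_rois_family = dim(acc_A)[2],
                                 labels = c("A", "B"),
                                 flip = "independent") {
  stopifnot(length(dim(acc_A)) == 3, all(dim(acc_A) == dim(acc_B)))
  rois <- dimnames(acc_A)[[2]] %||% paste0("roi_", seq_len(dim(acc_A)[2]))
  rows <- lapply(seq_len(dim(acc_A)[2]), function(ri) {
    res <- between_condition_clusters(acc_A[, ri, ], acc_B[, ri, ], chance,
                                      alpha, n_perm,
                                      seed = derive_seed(seed, ri),
                                      flip = flip)
    fmt <- function(cl, lab) {
      if (nrow(cl) == 0) return(NULL)
      data.frame(roi = rois[ri], condition = lab,
                 start_ms = time[cl$start], end_ms = time[cl$end],
                 size = cl$size, p_value = cl$p_value)
    }
    rbind(fmt(res$clusters_A_gt_B, paste0(labels[1], ">", labels[2])),
          fmt(res$clusters_B_gt_A, paste0(labels[2], ">", labels[1])))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(roi = character(0), condition = character(0),
                      start_ms = numeric(0), end_ms = numeric(0),
                      size = integer(0), p_value = numeric(0))
  out$significant <- bonferroni_gate(out$p_value, n_rois_family, alpha = 0.05)
  class(out) <- c("cluster_records", "data.frame")
  out
}

#' Write cluster records to TSV
#' @param records a \code{cluster_records} data.frame.
#' @param path file path.
#' @export
write_cluster_records <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
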