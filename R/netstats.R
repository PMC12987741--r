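#' Ward hierarchical clustering of connectivity profiles
#'
#' Each region's feature vector is its row of the connectivity matrix (its
#' connectivity profile); agglomeration uses Ward's criterion on Euclidean
#' distances (the "ward.D2" convention: merge heights equal
#' `sqrt(2 * increase in within-cluster sum of squares)`), which yields
#' compact clusters on continuous-valued similarity matrices.
#'
#' @param matrix A [connectivity_matrix()] with at least 2 regions.
#' @return An object of class `linkage_tree`: merge records (`merge`,
#'   `height`), leaf `region_ids` and the underlying `hclust` object.
#' @export
ward_linkage <- function(matrix) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (nrow(matrix$values) < 2L)
    stop("need at least 2 regions to cluster", call. = FALSE)
  feats <- matrix$values
  rownames(feats) <- as.character(matrix$region_ids)
  hc <- stats::hclust(stats::dist(feats), method = "ward.D2")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 region_ids = matrix$region_ids, hclust = hc),
            class = "linkage_tree")
}

#' Cophenetic correlation of a linkage tree
#'
#' Pearson correlation between the original pairwise Euclidean
#' profile distances and the cophenetic distances (the merge height at
#' which each pair first joins); 1 for perfectly ultrametric input. It
#' quantifies how faithfully the hierarchy preserves the pairwise
#' distances.
#'
#' @param tree A `linkage_tree` built from `matrix`.
#' @param matrix The [connectivity_matrix()] the tree was built from.
#' @return Correlation in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(tree, matrix) {
  stopifnot(inherits(tree, "linkage_tree"),
            inherits(matrix, "connectivity_matrix"))
  if (nrow(matrix$values) < 3L)
    stop("cophenetic correlation needs at least 3 regions", call. = FALSE)
  d <- stats::dist(matrix$values)
  cp <- stats::cophenetic(tree$hclust)
  stats::cor(as.vector(d), as.vector(cp))
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last `k - 1` merges. The default k = 8 mirrors a 7-network
#' cortical partition plus one subcortical cluster.
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters, `1 <= k <= R`.
#' @return Integer cluster labels, length R, named by region id.
#' @export
cut_clusters <- function(tree, k = 8) {
  stopifnot(inherits(tree, "linkage_tree"))
  R <- length(tree$region_ids)
  if (k < 1 || k > R)
    stop("k must lie in [1, ", R, "], got ", k, call. = FALSE)
  stats::cutree(tree$hclust, k = k)
}

#' Contingency table between two cluster labelings
#'
#' Counts `n(a, b)` of regions assigned label a in the first labeling and
#' b in the second; row and column sums recover the cluster sizes. The
#' numeric backbone of a cluster-correspondence (Sankey) display.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Integer matrix with the labels of `labels_a` as rows.
#' @export
cluster_overlap <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings have different lengths", call. = FALSE)
  tab <- table(a = labels_a, b = labels_b)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Permutation split-half reliability of group-mean connectivity
#'
#' For each permutation, every subject's frames are partitioned at random
#' into two disjoint equal-size halves (odd lengths give the extra frame to
#' the first half), the connectivity estimator is run on each half, the
#' subject matrices are averaged per half, and the Pearson correlation of
#' the two group-mean lower triangles is recorded. The distribution over
#' permutations summarizes test-retest reliability.
#'
#' @param subject_region_series Non-empty list of [region_timeseries()],
#'   one per subject, each with at least 6 frames and a common region set.
#' @param estimator Function mapping a [region_timeseries()] to a
#'   [connectivity_matrix()]; default [pearson_connectivity()].
#' @param n_perm Number of random partitions; default 5000.
#' @param seed Optional seed (restored afterwards).
#' @param contiguous If `TRUE`, split into first/second temporal halves
#'   instead of random frame sets (every permutation is then identical).
#' @return An object of class `reliability_result`: per-permutation
#'   correlations `r`, their `mean`, percentile `ci` (2.5/97.5), `n_perm`
#'   and `seed`.
#' @export
split_half_reliability <- function(subject_region_series,
                                   estimator = pearson_connectivity,
                                   n_perm = 5000, seed = NULL,
                                   contiguous = FALSE) {
  subj <- subject_region_series
  if (!length(subj)) stop("empty subject list", call. = FALSE)
  for (s in subj) {
    stopifnot(inherits(s, "region_timeseries"))
    if (ncol(s$values) < 6L)
      stop("each subject needs at least 6 frames", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  with_seed(seed, {
    r <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      lt1 <- lt2 <- NULL
      for (si in seq_along(subj)) {
        T <- ncol(subj[[si]]$values)
        n1 <- ceiling(T / 2)
        i1 <- if (contiguous) seq_len(n1)
              else sort(sample.int(T, n1))
        i2 <- setdiff(seq_len(T), i1)
        halves <- lapply(list(i1, i2), function(idx)
          tryCatch(estimator(subset_frames(subj[[si]], idx)),
                   error = function(e)
                     stop("estimator failed for subject ", si,
                          ", permutation ", p, ": ", conditionMessage(e),
                          call. = FALSE)))
        v1 <- lower_triangle(halves[[1]])
        v2 <- lower_triangle(halves[[2]])
        if (is.null(lt1)) { lt1 <- v1; lt2 <- v2 }
        else { lt1 <- lt1 + v1; lt2 <- lt2 + v2 }
      }
      r[p] <- stats::cor(lt1 / length(subj), lt2 / length(subj))
    }
    ci <- unname(stats::quantile(r, c(0.025, 0.975)))
    structure(list(r = r, mean = mean(r), ci = ci,
                   n_perm = as.integer(n_perm), seed = seed),
              class = "reliability_result")
  })
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> mean r = %.3f, 95%% CI [%.3f, %.3f], %d permutations\n",
              x$mean, x$ci[1], x$ci[2], x$n_perm))
  invisible(x)
}
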