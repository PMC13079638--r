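#' Z-score standardization with the population divisor
#'
#' Centers each column and scales by the population standard deviation
#' (divisor n, not n - 1), so the total sum of squares of the standardized
#' matrix is exactly n x p — the within-cluster sum of squares at k = 1.
#' Constant columns are an error naming the column; drop them explicitly
#' before calling.
#'
#' @param x numeric matrix (rows respondents, columns systems).
#' @return standardized matrix of the same shape.
#' @export
standardize_scores <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sdev == 0)) {
    bad <- colnames(x)[sdev == 0] %||% which(sdev == 0)
    stop_ohs("constant column(s) cannot be standardized: ",
             paste(bad, collapse = ", "))
  }
  sweep(sweep(x, 2, mu), 2, sdev, "/")
}

wcss_of <- function(x, labels, centers) {
  sum((x - centers[labels, , drop = FALSE])^2)
}

#' K-means clustering (Lloyd's algorithm, seeded restarts)
#'
#' Runs Lloyd's algorithm to convergence (assignments unchanged, or
#' `max_sweeps` sweeps) from each of `restarts` random initializations drawn
#' from a stream seeded with `seed`, and returns the restart with minimal
#' within-cluster sum of squares. A cluster that empties during a sweep is
#' reseeded at the point farthest from its assigned center. Results are
#' bitwise reproducible for fixed (seed, restarts).
#'
#' @param x numeric matrix, one row per observation.
#' @param k number of clusters (1 <= k <= n).
#' @param seed RNG seed for the initialization stream.
#' @param restarts number of random restarts.
#' @param max_sweeps maximum Lloyd sweeps per restart.
#' @return list with `labels` (0-based, matching the cluster-0/1/2 reporting
#'   convention), `centers` (k x p), `wcss`, `k`.
#' @export
kmeans_fit <- function(x, k, seed = 42, restarts = 10, max_sweeps = 300) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop_ohs("k must lie in 1..n")
  run_once <- function() {
    centers <- x[sample.int(n, k), , drop = FALSE]
    labels <- integer(n)
    for (sweep_i in seq_len(max_sweeps)) {
      d2 <- dist2_to_centers(x, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      # Reseed any emptied cluster at the point farthest from its assigned
      # center, never stealing from a singleton or another reseed.
      assigned_d2 <- d2[cbind(seq_len(n), new_labels)]
      for (c in seq_len(k)) {
        if (!any(new_labels == c)) {
          sizes <- tabulate(new_labels, k)
          cand <- which(sizes[new_labels] > 1)
          far <- cand[which.max(assigned_d2[cand])]
          centers[c, ] <- x[far, ]
          new_labels[far] <- c
          assigned_d2[far] <- 0
        }
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (c in seq_len(k))
        centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
    }
    list(labels = labels, centers = centers,
         wcss = wcss_of(x, labels, centers))
  }
  best <- with_local_seed(seed, {
    runs <- lapply(seq_len(restarts), function(i) run_once())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "wcss"))]]
  })
  list(labels = best$labels - 1L, centers = best$centers, wcss = best$wcss,
       k = as.integer(k))
}

dist2_to_centers <- function(x, centers) {
  # n x k squared Euclidean distances.
  outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

#' Second-difference curvature of a WCSS curve
#'
#' The elbow is automated as the k maximizing the discrete second difference
#' `WCSS(k-1) - 2 WCSS(k) + WCSS(k+1)` (greatest curvature). The full
#' curvature table is always returned so the choice can be overridden by
#' inspection. The selection's strength is `1 - r`, where `r` is the ratio
#' of the WCSS drop after the selected k to the drop before it: a true
#' elbow flattens abruptly (r near 0), while a structureless smooth decay
#' keeps r large. Selections below `weak_threshold` are flagged for manual
#' confirmation with a warning.
#'
#' @param wcss numeric WCSS values for k = 1, 2, ..., length(wcss).
#' @param weak_threshold strength below which the selection is flagged.
#' @return list with `selected_k`, `curvature` (data.frame k, second_diff),
#'   `strength`, `weak`.
#' @export
wcss_curvature <- function(wcss, weak_threshold = 0.8) {
  if (length(wcss) < 3) stop_ohs("need WCSS at k = 1..3 at least")
  ks <- 2:(length(wcss) - 1)
  d2 <- wcss[ks - 1] - 2 * wcss[ks] + wcss[ks + 1]
  sel <- ks[which.max(d2)]
  drop_before <- wcss[sel - 1] - wcss[sel]
  drop_after <- wcss[sel] - wcss[sel + 1]
  strength <- if (drop_before > 0) 1 - drop_after / drop_before else 0
  weak <- strength < weak_threshold
  if (weak)
    warning("elbow curvature maximum is weak (strength ",
            signif(strength, 3), "); confirm k manually", call. = FALSE)
  list(selected_k = sel,
       curvature = data.frame(k = ks, second_diff = d2, row.names = NULL),
       strength = strength, weak = weak)
}

#' Elbow-method model selection for K-means
#'
#' Computes the WCSS curve for k = 1..`k_max` with [kmeans_fit()] and selects
#' k by maximal second difference ([wcss_curvature()]).
#'
#' @inheritParams kmeans_fit
#' @param k_max largest k to evaluate (>= 3).
#' @param weak_threshold passed to [wcss_curvature()].
#' @return list with `wcss_curve` (data.frame k, wcss), `selected_k`,
#'   `curvature`, `strength`, `weak`.
#' @export
elbow <- function(x, k_max = 8, seed = 42, restarts = 10,
                  weak_threshold = 0.8) {
  if (k_max < 3) stop_ohs("k_max must be at least 3")
  x <- as.matrix(x)
  wcss <- vapply(seq_len(k_max), function(k)
    kmeans_fit(x, k, seed = seed, restarts = restarts)$wcss, numeric(1))
  cv <- wcss_curvature(wcss, weak_threshold = weak_threshold)
  c(list(wcss_curve = data.frame(k = seq_len(k_max), wcss = wcss,
                                 row.names = NULL)), cv)
}

#' Per-cluster burden profiles
#'
#' Cluster sizes, shares, mean total symptom burden, and mean raw system
#' scores (radar-chart data). Clusters are renumbered in descending
#' mean-burden order so cluster 0 is always the highest-burden (worst)
#' group.
#'
#' @param labels cluster labels (0-based) aligned with rows.
#' @param system_scores n x n_systems raw burden matrix.
#' @param tsb per-respondent total symptom burden.
#' @return list with `profiles` (data.frame: cluster, size, share, mean_tsb,
#'   then one column per system) and `labels` (relabeled, 0-based).
#' @export
cluster_profiles <- function(labels, system_scores, tsb) {
  system_scores <- as.matrix(system_scores)
  stopifnot(length(labels) == nrow(system_scores),
            length(tsb) == nrow(system_scores))
  ids <- sort(unique(labels))
  mean_tsb <- vapply(ids, function(c) mean(tsb[labels == c]), numeric(1))
  new_order <- ids[order(-mean_tsb)]
  relab <- match(labels, new_order) - 1L
  prof <- do.call(rbind, lapply(seq_along(new_order), function(i) {
    sel <- relab == (i - 1L)
    data.frame(cluster = i - 1L, size = sum(sel),
               share = sum(sel) / length(relab),
               mean_tsb = mean(tsb[sel]),
               t(colMeans(system_scores[sel, , drop = FALSE])),
               check.names = FALSE, row.names = NULL)
  }))
  list(profiles = prof, labels = relab)
}
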