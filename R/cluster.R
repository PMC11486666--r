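# Sub-population tags, in the fixed reporting order: high activity + high
# persistence, low activity + high persistence, low activity + low
# persistence.
.tag_levels <- c("hi_a_hi_q", "lo_a_hi_q", "lo_a_lo_q")

# z-standardize the (q_bar, a_bar) feature matrix; constant columns get
# scale 1 so degenerate inputs stay finite.
.standardize_qa <- function(summaries) {
  x <- as.matrix(summaries[, c("q_bar", "a_bar")])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# Plain DBSCAN on a feature matrix. Returns integer cluster labels with 0 =
# noise. Neighbourhoods are closed balls of radius eps; a point counts
# itself, so a core point has >= min_pts neighbours including itself.
.dbscan <- function(x, eps, min_pts) {
  n <- nrow(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(x))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Flag low-density outlier cells before clustering
#'
#' Runs DBSCAN on the z-standardized (q_bar, a_bar) features and marks its
#' noise points as outliers; everything belonging to any density-connected
#' cluster is an inlier. q (unitless) and a (µm/min) are standardized first
#' because their scales are not commensurable.
#'
#' @param summaries Tibble of per-cell summaries with `q_bar` and `a_bar`
#'   columns (see [infer_cells()]).
#' @param eps DBSCAN radius in standardized units (default 0.5).
#' @param min_pts Minimum neighbourhood size (including the point itself)
#'   for a core point (default 5).
#' @return Logical inlier mask aligned with the rows of `summaries`. With
#'   fewer rows than `min_pts` all cells are retained, with a warning.
#' @export
remove_outliers <- function(summaries, eps = 0.5, min_pts = 5) {
  n <- nrow(summaries)
  if (n == 0) return(logical(0))
  if (n < min_pts) {
    warn("fewer cells than `min_pts`; all retained")
    return(rep(TRUE, n))
  }
  std <- .standardize_qa(summaries)
  .dbscan(std$x, eps, min_pts) != 0L
}

#' k-means clustering of cells in (q_bar, a_bar) space
#'
#' Clusters the z-standardized per-cell parameter averages with multiple
#' seeded restarts, keeping the solution with the lowest within-cluster sum
#' of squares; each cell is assigned to the centroid minimizing Euclidean
#' distance. Mean silhouette widths for k = 2..6 are reported as a
#' diagnostic only — k is always the caller's choice, never auto-selected.
#'
#' @param summaries Tibble of inlier per-cell summaries (`track_id`,
#'   `q_bar`, `a_bar`).
#' @param k Number of clusters.
#' @param n_restarts Seeded k-means restarts.
#' @param seed Integer seed; identical data + seed give identical
#'   assignments.
#' @return An object of class `cluster_report` (unlabelled until
#'   [label_and_merge()]): `assignments` (`track_id`, `cluster`),
#'   `centroids` in original units, `silhouette_by_k`, `k_used`, scaling
#'   info.
#' @export
cluster_cells <- function(summaries, k = 4, n_restarts = 25, seed = NULL) {
  n <- nrow(summaries)
  if (n < k) {
    abort(sprintf("cannot form %d clusters from %d cells", k, n))
  }
  std <- .standardize_qa(summaries)
  run_kmeans <- function(kk) kmeans(std$x, centers = kk, nstart = n_restarts)
  km <- if (is.null(seed)) run_kmeans(k) else withr::with_seed(seed, run_kmeans(k))
  sil <- lapply(2:6, function(kk) {
    if (kk >= n) return(tibble(k = kk, mean_silhouette = NA_real_))
    skm <- tryCatch(
      if (is.null(seed)) run_kmeans(kk) else withr::with_seed(seed + kk, run_kmeans(kk)),
      error = function(e) NULL)
    if (is.null(skm) || length(unique(skm$cluster)) < 2) {
      return(tibble(k = kk, mean_silhouette = NA_real_))
    }
    sw <- cluster::silhouette(skm$cluster, dist(std$x))
    tibble(k = kk, mean_silhouette = mean(sw[, "sil_width"]))
  })
  cent <- sweep(sweep(km$centers, 2, std$scale, "*"), 2, std$center, "+")
  structure(list(
    assignments = tibble(track_id = summaries$track_id,
                         cluster = as.integer(km$cluster)),
    centroids = tibble(cluster = seq_len(k),
                       q_bar = cent[, "q_bar"], a_bar = cent[, "a_bar"]),
    silhouette_by_k = bind_rows(sil),
    k_used = as.integer(k),
    scaling = list(center = std$center, scale = std$scale),
    tags = NULL, labels = NULL, proportions = NULL,
    n_cells = n, tot_withinss = km$tot.withinss
  ), class = "cluster_report")
}

#' Label clusters by centroid geometry and merge to three sub-populations
#'
#' Maps clusters onto the three motility tags by a deterministic geometric
#' rule, then recomputes proportions over the merged tags:
#' * k = 4: the two centroids with the lowest activity merge into
#'   `lo_a_lo_q` (one of them is typically the near-immobile mode); the
#'   highest-activity centroid becomes `hi_a_hi_q`; the remaining one
#'   `lo_a_hi_q`.
#' * k = 3: the highest-activity centroid becomes `hi_a_hi_q`; of the
#'   remaining two, the higher-persistence one is `lo_a_hi_q`, the other
#'   `lo_a_lo_q`.
#' Activity ties are broken by persistence (the lower-q centroid merges
#' first). The rule depends only on centroid geometry, so relabelling is
#' invariant to cluster index permutation — which is also what makes
#' bootstrap replicates comparable.
#'
#' @param report A [cluster_cells()] result with `k_used` 3 or 4.
#' @return The report with `tags` (per-cluster), `labels` (per-cell tag)
#'   and `proportions` (per-tag fraction of inliers, all three tags always
#'   present) filled in.
#' @export
label_and_merge <- function(report) {
  stopifnot(inherits(report, "cluster_report"))
  k <- report$k_used
  if (!k %in% c(3L, 4L)) abort("labelling rule requires k = 3 or k = 4")
  cen <- report$centroids
  ord <- order(cen$a_bar, cen$q_bar)  # ascending activity, lower q first
  tag_vec <- character(k)
  if (k == 4L) {
    tag_vec[ord[1:2]] <- "lo_a_lo_q"
    tag_vec[ord[3]] <- "lo_a_hi_q"
    tag_vec[ord[4]] <- "hi_a_hi_q"
  } else {
    tag_vec[ord[3]] <- "hi_a_hi_q"
    low <- ord[1:2]
    hi_q <- low[which.max(cen$q_bar[low])]
    tag_vec[hi_q] <- "lo_a_hi_q"
    tag_vec[setdiff(low, hi_q)] <- "lo_a_lo_q"
  }
  report$tags <- mutate(cen,
                        tag = factor(tag_vec[cen$cluster], levels = .tag_levels))
  report$labels <- report$assignments %>%
    mutate(tag = factor(tag_vec[.data$cluster], levels = .tag_levels))
  props <- table(report$labels$tag) / nrow(report$labels)
  report$proportions <- tibble(tag = factor(.tag_levels, levels = .tag_levels),
                               proportion = as.numeric(props[.tag_levels]))
  report
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> k =", x$k_used, "on", x$n_cells, "cells\n")
  if (!is.null(x$proportions)) print(x$proportions)
  invisible(x)
}

#' @export
tidy.cluster_report <- function(x, ...) {
  out <- x$assignments
  if (!is.null(x$labels)) out <- x$labels
  out
}

#' @export
glance.cluster_report <- function(x, ...) {
  out <- tibble(k_used = x$k_used, n_cells = x$n_cells,
                tot_withinss = x$tot_withinss)
  if (!is.null(x$proportions)) {
    wide <- stats::setNames(as.list(x$proportions$proportion),
                            paste0("prop_", x$proportions$tag))
    out <- dplyr::bind_cols(out, as_tibble(wide))
  }
  out
}

#' Bootstrap stability of the merged sub-population proportions
#'
#' Resamples cells (their (q_bar, a_bar) averages) with replacement,
#' reruns the full procedure — outlier removal, k-means, geometric
#' labelling and merging — on every replicate, and summarises the merged
#' proportions across replicates. Replicate labels are comparable because
#' the tag rule depends only on centroid geometry. Degenerate resamples
#' (fewer inliers than clusters, or fewer distinct points than clusters)
#' are redrawn and counted.
#'
#' @param summaries Tibble of eligible per-cell summaries.
#' @param k Clusters per replicate (3 or 4).
#' @param eps,min_pts DBSCAN parameters for the in-loop outlier removal.
#' @param n_restarts k-means restarts per replicate.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param refilter_outliers If `FALSE`, outlier removal runs once on the
#'   original data and the mask is reused, trading fidelity for speed.
#' @return An object of class `bootstrap_result`: per-rep proportions,
#'   per-tag `mean`/`sd`, mean and sd of the cumulative sums (tags in the
#'   order high, medium, low motility), and the redraw count.
#' @export
bootstrap_proportions <- function(summaries, k = 4, eps = 0.5, min_pts = 5,
                                  n_restarts = 10, n_reps = 100, seed = 1L,
                                  refilter_outliers = TRUE) {
  n <- nrow(summaries)
  if (n < k) abort("fewer cells than clusters")
  fixed_mask <- if (!refilter_outliers) {
    suppressWarnings(remove_outliers(summaries, eps, min_pts))
  } else NULL
  reps <- matrix(NA_real_, n_reps, 3L,
                 dimnames = list(NULL, .tag_levels))
  n_redraws <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- (seed + 7919L * r) %% 2147483587L
    done <- FALSE
    tries <- 0L
    while (!done) {
      tries <- tries + 1L
      if (tries > 1L) n_redraws <- n_redraws + 1L
      if (tries > 50L) abort("bootstrap replicate kept degenerating; check input")
      idx <- withr::with_seed(rep_seed + tries - 1L,
                              sample.int(n, n, replace = TRUE))
      boot <- summaries[idx, , drop = FALSE]
      mask <- if (refilter_outliers) {
        suppressWarnings(remove_outliers(boot, eps, min_pts))
      } else fixed_mask[idx]
      inl <- boot[mask, , drop = FALSE]
      if (nrow(inl) < k ||
          nrow(unique(inl[, c("q_bar", "a_bar")])) < k) next
      rep_report <- tryCatch(
        label_and_merge(cluster_cells(inl, k = k, n_restarts = n_restarts,
                                      seed = rep_seed)),
        error = function(e) NULL)
      if (is.null(rep_report)) next
      reps[r, ] <- rep_report$proportions$proportion
      done <- TRUE
    }
  }
  cum <- t(apply(reps, 1, cumsum))
  structure(list(
    n_reps = n_reps,
    replicates = as_tibble(reps) %>% mutate(rep = dplyr::row_number()),
    summary = tibble(
      tag = factor(.tag_levels, levels = .tag_levels),
      mean_proportion = unname(colMeans(reps)),
      sd_proportion = unname(apply(reps, 2, sd)),
      mean_cumsum = unname(colMeans(cum)),
      sd_cumsum = unname(apply(cum, 2, sd))
    ),
    n_redraws = n_redraws,
    k = k, seed = seed
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>", x$n_reps, "replicates, k =", x$k, "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.bootstrap_result <- function(x, ...) x$summary
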