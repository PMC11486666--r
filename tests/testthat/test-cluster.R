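test_that("DBSCAN outlier removal flags exactly the isolated point", {
  withr::with_seed(61, {
    blob <- tibble::tibble(track_id = paste0("c", 1:100),
                           q_bar = runif(100, 0.45, 0.55),
                           a_bar = runif(100, 1.9, 2.1))
    far <- tibble::tibble(track_id = "far", q_bar = 0.9, a_bar = 4)
    cells <- dplyr::bind_rows(blob, far)
    mask <- remove_outliers(cells, eps = 0.5, min_pts = 5)
    expect_equal(which(!mask), 101L)
  })
})

test_that("degenerate outlier inputs are handled conservatively", {
  same <- tibble::tibble(track_id = as.character(1:20),
                         q_bar = 0.4, a_bar = 1.5)
  expect_true(all(remove_outliers(same)))
  expect_length(remove_outliers(same[0, ]), 0L)
  expect_warning(mask <- remove_outliers(same[1:3, ], min_pts = 5),
                 "fewer cells")
  expect_true(all(mask))
})

test_that("k-means recovers well-separated blobs and is deterministic", {
  withr::with_seed(62, {
    a <- qa_blob(40, q = 0.2, a = 1, sd_q = 0.01, sd_a = 0.01, prefix = "a")
    b <- qa_blob(40, q = 0.9, a = 4, sd_q = 0.01, sd_a = 0.01, prefix = "b")
    cells <- dplyr::bind_rows(a, b)
  })
  rep1 <- cluster_cells(cells, k = 2, seed = 7)
  grp <- substr(rep1$assignments$track_id, 1, 1)
  tab <- table(grp, rep1$assignments$cluster)
  expect_equal(sort(apply(tab, 1, max)), c(40, 40), ignore_attr = TRUE)

  rep2 <- cluster_cells(cells, k = 2, seed = 7)
  expect_identical(rep1$assignments, rep2$assignments)

  rep3 <- cluster_cells(cells, k = 1, seed = 7)
  expect_equal(rep3$centroids$q_bar, mean(cells$q_bar))
  expect_equal(rep3$centroids$a_bar, mean(cells$a_bar))

  expect_error(cluster_cells(cells[1:3, ], k = 4), "cannot form")
  expect_true(all(rep1$silhouette_by_k$k == 2:6))
})

test_that("the geometric labelling rule maps centroids to the three tags", {
  fake_report <- function(a, q) {
    k <- length(a)
    structure(list(
      assignments = tibble::tibble(track_id = as.character(seq_len(k)),
                                   cluster = seq_len(k)),
      centroids = tibble::tibble(cluster = seq_len(k), q_bar = q, a_bar = a),
      k_used = as.integer(k), n_cells = k), class = "cluster_report")
  }
  r4 <- label_and_merge(fake_report(a = c(4, 1.5, 0.3, 0.05),
                                    q = c(0.8, 0.7, 0.3, 0.1)))
  expect_equal(as.character(r4$tags$tag),
               c("hi_a_hi_q", "lo_a_hi_q", "lo_a_lo_q", "lo_a_lo_q"))

  r3 <- label_and_merge(fake_report(a = c(4, 1, 1), q = c(0.9, 0.9, 0.2)))
  expect_equal(as.character(r3$tags$tag),
               c("hi_a_hi_q", "lo_a_hi_q", "lo_a_lo_q"))

  expect_error(label_and_merge(fake_report(a = c(1, 2), q = c(0.1, 0.2))),
               "k = 3 or k = 4")
})

test_that("merged proportions follow the 60/25/10/5 arithmetic", {
  counts <- c(60, 25, 10, 5)
  cl <- rep(1:4, counts)
  rep0 <- structure(list(
    assignments = tibble::tibble(track_id = as.character(seq_along(cl)),
                                 cluster = cl),
    centroids = tibble::tibble(cluster = 1:4,
                               q_bar = c(0.8, 0.7, 0.3, 0.1),
                               a_bar = c(4, 1.5, 0.3, 0.05)),
    k_used = 4L, n_cells = length(cl)), class = "cluster_report")
  merged <- label_and_merge(rep0)
  expect_equal(merged$proportions$proportion, c(0.60, 0.25, 0.15))
  expect_equal(sum(merged$proportions$proportion), 1, tolerance = 1e-9)
})

test_that("labelling is invariant to cluster index permutation", {
  withr::with_seed(63, {
    cells <- qa_mixture(120, c(0.4, 0.3, 0.3))
    rep0 <- cluster_cells(cells, k = 3, seed = 5)
    merged <- label_and_merge(rep0)
    perm <- c(3L, 1L, 2L)
    rep_p <- rep0
    rep_p$assignments$cluster <- perm[rep0$assignments$cluster]
    rep_p$centroids <- rep0$centroids[order(perm), ]
    rep_p$centroids$cluster <- 1:3
    merged_p <- label_and_merge(rep_p)
    expect_equal(as.character(merged$labels$tag),
                 as.character(merged_p$labels$tag))
  })
})

test_that("single-rep bootstrap equals a hand-run of the pipeline", {
  withr::with_seed(64, cells <- qa_mixture(90, c(0.4, 0.3, 0.3)))
  bt <- bootstrap_proportions(cells, k = 3, n_reps = 1, seed = 10)
  rep_seed <- (10 + 7919L * 1L) %% 2147483587L
  idx <- withr::with_seed(rep_seed, sample.int(90, 90, replace = TRUE))
  boot <- cells[idx, ]
  mask <- suppressWarnings(remove_outliers(boot, 0.5, 5))
  byhand <- label_and_merge(
    cluster_cells(boot[mask, ], k = 3, n_restarts = 10, seed = rep_seed))
  expect_equal(as.numeric(bt$replicates[1, 1:3]),
               byhand$proportions$proportion, ignore_attr = TRUE)
})

test_that("bootstrap proportions recover a well-separated mixture", {
  withr::with_seed(65, cells <- qa_mixture(150, c(0.5, 0.3, 0.2)))
  bt <- bootstrap_proportions(cells, k = 3, n_reps = 20, seed = 2)
  expect_equal(bt$summary$mean_proportion, c(0.5, 0.3, 0.2), tolerance = 0.25,
               ignore_attr = TRUE)
  expect_true(all(abs(rowSums(as.matrix(bt$replicates[, 1:3])) - 1) < 1e-9))
  expect_equal(bt$summary$mean_cumsum[3], 1, tolerance = 1e-9)
})

test_that("a single-blob cohort concentrates in one tag but still sums to 1", {
  withr::with_seed(66, {
    cells <- qa_blob(60, q = 0.5, a = 2, sd_q = 0.05, sd_a = 0.2)
  })
  bt <- bootstrap_proportions(cells, k = 3, n_reps = 5, seed = 3)
  expect_true(all(abs(rowSums(as.matrix(bt$replicates[, 1:3])) - 1) < 1e-9))
})
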