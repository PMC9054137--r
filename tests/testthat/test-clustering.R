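test_that("DBSCAN matches brute-force density connectivity on random sets", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(10:50, 1)
    xy <- cbind(runif(n, 0, 20000), runif(n, 0, 20000))
    # add a tight blob to guarantee some density
    xy <- rbind(xy, matrix(rnorm(12, 5000, 100), ncol = 2))
    expect_dbscan_matches_oracle(xy, eps = sample(c(300, 1000, 3000), 1),
                                 min_pts = sample(2:4, 1))
  }
})

test_that("basic density clustering behaviour", {
  sig <- make_signals("r1", "noninverted",
                      edge_a = c(1000, 1050, 1100, 980, 1020, 12000),
                      edge_b = c(5000, 5020, 5060, 4990, 5010, 30000))
  sig$read_id <- paste0("r", 1:6)
  out <- cluster_breakpoints(sig, "noninverted", eps = 1000, min_pts = 3)
  expect_equal(nrow(out$clusters), 1L)     # the lone point is noise
  expect_equal(out$clusters$n_signals, 5L)

  two <- make_signals("r1", "noninverted",
                      edge_a = c(1000, 1010, 1020, 6000, 6010, 6020),
                      edge_b = c(9000, 9010, 9020, 14000, 14010, 14020))
  two$read_id <- paste0("r", 1:6)
  out2 <- cluster_breakpoints(two, "noninverted", eps = 1000, min_pts = 3)
  expect_equal(nrow(out2$clusters), 2L)
})

test_that("elbow epsilon follows the curvature of sorted NN distances", {
  # colinear points with NN distances [1,1,1,1,500,600]: elbow at the jump
  sig <- make_signals("r", "inverted",
                      edge_a = c(0, 1, 2, 3, 4, 504, 1104),
                      edge_b = rep(0, 7))
  sig$read_id <- paste0("r", 1:7)
  eps <- select_eps_elbow(sig)
  expect_gte(eps, 1); expect_lte(eps, 500)
  # all NN distances equal: zero curvature, cap returned
  reg <- make_signals("r", "inverted", edge_a = seq(0, 900, by = 100),
                      edge_b = rep(0, 10))
  expect_equal(select_eps_elbow(reg), 1000)
  # elbow beyond the cap is capped
  far <- make_signals("r", "inverted",
                      edge_a = c(0, 2000, 4000, 6000, 20000, 50000),
                      edge_b = rep(0, 6))
  expect_equal(select_eps_elbow(far), 1000)
  # fewer than 3 signals: cap
  expect_equal(select_eps_elbow(sig[1:2, ]), 1000)
})

test_that("2-means split triggers only on within-read transitions", {
  mk <- function(read_ids) {
    s <- make_signals("x", "noninverted",
                      edge_a = c(rnorm(4, 1000, 10), rnorm(4, 1800, 10)),
                      edge_b = c(rnorm(4, 9000, 10), rnorm(4, 9800, 10)),
                      read_pos = rep(c(1000, 5000), 4))
    s$read_id <- read_ids
    s$cluster <- 1L
    s
  }
  set.seed(42)
  # no read spans the two halves: keep whole
  apart <- mk(paste0("r", 1:8))
  expect_equal(length(unique(split_check_kmeans(apart)$cluster)), 1L)
  # one read holds adjacent signals in both halves: split
  linked <- mk(c("r1", "r2", "r3", "link", "link", "r4", "r5", "r6"))
  expect_equal(length(unique(split_check_kmeans(linked)$cluster)), 2L)
  # below the size gate: untouched
  small <- mk(paste0("r", 1:8))[1:3, ]
  expect_equal(length(unique(split_check_kmeans(small)$cluster)), 1L)
})

test_that("cluster filtering enforces read support and votes", {
  clusters <- tibble(cluster_id = 1:4, kind = "noninverted",
                     n_signals = c(10L, 10L, 10L, 2L),
                     n_reads = c(5L, 5L, 5L, 2L),
                     centroid_a = c(1000, 50000, 20000, 70000),
                     centroid_b = c(30000, 60000, 40000, 80000),
                     sd_a = 0, sd_b = 0)
  # hand-built vote evidence
  mk_bp <- function(read_id, cl_centroids, read_pos) {
    make_signals(read_id, "noninverted",
                 edge_a = vapply(cl_centroids, function(i) clusters$centroid_a[i], numeric(1)),
                 edge_b = vapply(cl_centroids, function(i) clusters$centroid_b[i], numeric(1)),
                 read_pos = read_pos)
  }
  bp <- bind_rows(
    # cluster 1: artifact reads recapitulate it across the fold (P votes)
    mk_bp("f1", c(1, 1), c(2000, 8000)),
    mk_bp("f2", c(1, 1), c(2500, 7500)),
    mk_bp("f3", c(1), 3000),                       # one side only: N vote
    # cluster 2: no fold reads; repeats within plain reads (PR votes)
    mk_bp("p1", c(2, 2), c(1000, 4000)),
    mk_bp("p2", c(2, 2), c(1000, 4000)),
    # cluster 3: appears once in reads that repeat cluster 2 (NR votes)
    mk_bp("p3", c(2, 2, 3), c(1000, 4000, 6000)),
    mk_bp("p4", c(2, 2, 3), c(1000, 4000, 6000)),
    # cluster 4: two reads only
    mk_bp("q1", c(4), 1000), mk_bp("q2", c(4), 2000)
  )
  folds <- tibble(read_id = c("f1", "f2", "f3"),
                  fold_read_pos = c(5000, 5000, 5000),
                  read_length = 10000)
  out <- filter_clusters(clusters, bp, folds = folds, min_read_support = 3)
  expect_equal(out$P, c(2L, 0L, 0L, 0L))
  expect_equal(out$N, c(1L, 0L, 0L, 0L))
  expect_equal(out$PR[2], 4L)
  expect_equal(out$NR[3], 2L)
  expect_true(out$retained[1])    # P > N
  expect_true(out$retained[2])    # PR > NR
  expect_false(out$retained[3])   # PR = 0 < NR
  expect_false(out$retained[4])   # only 2 supporting reads
})

test_that("retained clusters partition their members and recover truth", {
  sim <- simulate_reads(inverted_tandem_spec(), default_model(), 500,
                        seed = 41)
  bp <- flag_artifact_candidates(extract_breakpoints(
    filter_alignments(sim$alignments)))
  res <- resolve_artifacts(bp)
  cl <- cluster_all_breakpoints(res$breakpoints, folds = res$folds)
  # no signal sits in two clusters
  expect_false(any(duplicated(
    paste(cl$breakpoints$read_id, cl$breakpoints$read_pos,
          cl$breakpoints$edge_lo))))
  ret <- cl$clusters[cl$clusters$retained, ]
  # noiseless simulation: retained centroids equal the true junctions
  expect_equal(nrow(ret), 2L)
  cent <- ret[order(ret$centroid_a), c("centroid_a", "centroid_b")]
  expect_equal(cent$centroid_a, c(2000, 14000))
  expect_equal(cent$centroid_b, c(20000, 23000))
  expect_equal(ret$sd_a, c(0, 0))
})

test_that("cluster centroids are consistent under jitter", {
  # plus-strand tandem unit: both junctions non-inverted, clustered at the
  # fixed 1 kbp epsilon, so each cluster captures its junction's whole
  # jitter scatter and the centroid error shrinks as s / sqrt(n)
  spec <- structure_spec(tibble(ref_start = c(2000, 20000),
                                ref_end = c(14000, 23000),
                                strand = c("+", "+")), frequency = 1)
  sim <- simulate_reads(spec, default_model(), 600, noise = 100, seed = 43)
  bp <- flag_artifact_candidates(extract_breakpoints(
    filter_alignments(sim$alignments)))
  res <- resolve_artifacts(bp)
  cl <- cluster_all_breakpoints(res$breakpoints, folds = res$folds,
                                eps_noninv = 1000)
  ret <- cl$clusters[cl$clusters$retained, ]
  expect_equal(nrow(ret), 2L)
  truth <- rbind(c(14000, 20000), c(2000, 23000))
  for (i in 1:2) {
    d <- sqrt((ret$centroid_a - truth[i, 1])^2 +
                (ret$centroid_b - truth[i, 2])^2)
    j <- which.min(d)
    expect_lt(d[j], 3 * 100 / sqrt(ret$n_reads[j]) + 5)
  }
})
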