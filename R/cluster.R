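# Breakpoint clustering: DBSCAN over canonical (edge_lo, edge_hi)
# coordinates, elbow-selected epsilon for inverted signals, a 2-means
# over-merge check, and the read-support / majority-voting cluster filter.

# Plain DBSCAN on a 2-column coordinate matrix. Returns an integer cluster
# label per point, 0 = noise. Border points join the first core point that
# reaches them (scan order), which does not affect cluster membership sets
# for the well-separated clusters this pipeline produces.
dbscan_labels <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  d <- as.matrix(dist(xy))
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbours, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (k in neighbours[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Select DBSCAN epsilon by the nearest-neighbour elbow method
#'
#' Sorts each inverted signal's nearest-neighbour distance and returns the
#' distance at the point of largest discrete curvature (second difference)
#' of the sorted curve, capped at `cap` bp. With fewer than three signals,
#' or a curve with no curvature, the cap is returned.
#'
#' @param breakpoints Breakpoint tibble (typically inverted signals only).
#' @param cap Upper bound on epsilon, bp (default 1000).
#' @param log_scale Compute curvature on log-scaled distances instead of raw.
#' @return Epsilon in bp.
#' @export
select_eps_elbow <- function(breakpoints, cap = 1000, log_scale = FALSE) {
  n <- nrow(breakpoints)
  if (n < 3L) return(cap)
  d <- as.matrix(dist(cbind(breakpoints$edge_lo, breakpoints$edge_hi)))
  diag(d) <- Inf
  nn <- sort(apply(d, 1L, min))
  y <- if (log_scale) log1p(nn) else nn
  curv <- abs(diff(y, differences = 2))
  if (length(curv) == 0L || max(curv) <= 0) return(cap)
  # curvature at interior index i+1 of the sorted curve
  idx <- which.max(curv) + 1L
  min(nn[idx], cap)
}

#' Cluster breakpoint signals into junctions
#'
#' Runs DBSCAN separately over one kind of signal (inverted or
#' non-inverted) in the canonically sorted edge plane `(edge_lo, edge_hi)`,
#' so that LH/HL orientation does not split a junction. Noise points are
#' dropped. For inverted signals the radius defaults to
#' `min(select_eps_elbow(), 1000)`; for non-inverted signals to 1 kbp.
#' Clusters whose membership the data show to be too coarse are split by
#' [split_check_kmeans()].
#'
#' @param breakpoints Breakpoint tibble, artifacts already removed.
#' @param kind `"noninverted"` or `"inverted"`; signals of the other kind
#'   are ignored.
#' @param min_pts DBSCAN minPts (default 3).
#' @param eps Radius in bp; `NULL` (default) applies the rules above.
#' @param split_kmeans Apply the 2-means over-merge check (default TRUE).
#' @return List with `breakpoints` (the clustered signals of this kind,
#'   with a `cluster` column; noise dropped) and `clusters` (per-cluster
#'   tibble: `cluster_id`, `kind`, `n_signals`, `n_reads`, `centroid_a`,
#'   `centroid_b`, `sd_a`, `sd_b`). Centroid a/b are means of
#'   `edge_lo`/`edge_hi`.
#' @export
cluster_breakpoints <- function(breakpoints, kind = c("noninverted", "inverted"),
                                min_pts = 3, eps = NULL, split_kmeans = TRUE) {
  kind <- match.arg(kind)
  sig <- filter(breakpoints, .data$kind == .env$kind)
  if (is.null(eps)) {
    eps <- if (kind == "inverted") {
      min(select_eps_elbow(sig), 1000)
    } else 1000
  }
  if (nrow(sig) < min_pts) {
    return(list(breakpoints = mutate(sig[0L, ], cluster = integer()),
                clusters = empty_clusters()))
  }
  xy <- cbind(sig$edge_lo, sig$edge_hi)
  labels <- dbscan_labels(xy, eps = eps, min_pts = min_pts)
  sig$cluster <- labels
  sig <- filter(sig, .data$cluster > 0L)
  if (split_kmeans && nrow(sig)) {
    sig <- split_check_kmeans(sig, min_pts = min_pts)
  }
  # relabel clusters deterministically by centroid order
  summ <- summarise_clusters(sig, kind)
  relabel <- setNames(seq_len(nrow(summ)), summ$cluster_id)
  sig$cluster <- as.integer(relabel[as.character(sig$cluster)])
  summ$cluster_id <- as.integer(relabel[as.character(summ$cluster_id)])
  summ <- arrange(summ, .data$cluster_id)
  list(breakpoints = sig, clusters = summ)
}

summarise_clusters <- function(sig, kind) {
  sig %>%
    group_by(.data$cluster) %>%
    summarise(
      n_signals = dplyr::n(),
      n_reads = n_distinct(.data$read_id),
      centroid_a = mean(.data$edge_lo), centroid_b = mean(.data$edge_hi),
      sd_a = if (dplyr::n() > 1L) sd(.data$edge_lo) else 0,
      sd_b = if (dplyr::n() > 1L) sd(.data$edge_hi) else 0,
      .groups = "drop"
    ) %>%
    rename(cluster_id = "cluster") %>%
    mutate(kind = .env$kind, .after = "cluster_id") %>%
    arrange(.data$centroid_a, .data$centroid_b)
}

empty_clusters <- function() {
  tibble(cluster_id = integer(), kind = character(), n_signals = integer(),
         n_reads = integer(), centroid_a = numeric(), centroid_b = numeric(),
         sd_a = numeric(), sd_b = numeric())
}

#' Split over-coarse DBSCAN clusters with a 2-means check
#'
#' Within each cluster holding at least `2 * min_pts` members, a 2-means
#' partition (deterministically initialised at the two mutually farthest
#' members) is computed on the edge plane. The split is accepted only when
#' (a) at least one read contains a within-read transition between signals
#' assigned to the two halves -- the signature of two distinct junctions
#' having been merged -- and (b) the halves are separated by more than
#' `min_separation` times their internal spread. The second condition
#' exists because 2-means always partitions: halving a single junction's
#' jitter scatter yields a separation of about 2.7 times the within-half
#' spread, while genuinely distinct junctions score far higher.
#'
#' @param sig Clustered breakpoint tibble (`cluster` column).
#' @param min_pts Cluster size gate (default 3).
#' @param min_separation Required ratio of between-half centroid distance
#'   to mean within-half RMS spread (default 4).
#' @return The tibble with clusters possibly split (new labels appended).
#' @export
split_check_kmeans <- function(sig, min_pts = 3, min_separation = 4) {
  next_label <- max(sig$cluster) + 1L
  for (cl in sort(unique(sig$cluster))) {
    idx <- which(sig$cluster == cl)
    if (length(idx) < 2L * min_pts) next
    xy <- cbind(sig$edge_lo[idx], sig$edge_hi[idx])
    d <- as.matrix(dist(xy))
    far <- which(d == max(d), arr.ind = TRUE)[1L, ]
    if (max(d) == 0) next
    centers <- xy[c(far[1], far[2]), , drop = FALSE]
    km <- suppressWarnings(kmeans(xy, centers = centers, iter.max = 50))
    half <- km$cluster
    if (length(unique(half)) < 2L) next
    sep <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
    spread <- mean(vapply(1:2, function(h) {
      m <- xy[half == h, , drop = FALSE]
      sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
    }, numeric(1)))
    if (sep <= min_separation * spread) next
    # does any read transition between the two halves at adjacent signals?
    linked <- sig[idx, ] %>%
      mutate(.half = half) %>%
      group_by(.data$read_id) %>%
      arrange(.data$read_pos, .by_group = TRUE) %>%
      summarise(mix = dplyr::n_distinct(.data$.half) > 1L, .groups = "drop")
    if (any(linked$mix)) {
      sig$cluster[idx[half == 2L]] <- next_label
      next_label <- next_label + 1L
    }
  }
  sig
}

#' Filter clusters by read support and majority voting
#'
#' A cluster is retained when at least `min_read_support` distinct reads
#' support it and it wins its vote. In reads carrying a removed
#' inverted-duplication fold, the mirrored half duplicates every junction it
#' covers: `P` counts fold reads in which the cluster is recapitulated on
#' both sides of the fold, `N` fold reads in which it appears on one side
#' only; `P > N` keeps the cluster. When no fold read contains the cluster
#' (`P = N = 0`), the vote falls back to within-read repetition, the
#' expected signature of concatemers: `PR` counts reads in which the cluster
#' occurs at least twice, `NR` reads that repeat some cluster but contain
#' this one exactly once; `PR > NR` keeps it. A cluster with no votes of
#' either kind (`P = N = PR = NR = 0`) is retained on read support alone.
#' Ties with votes cast (`P == N > 0`, or `PR == NR > 0`) drop the cluster.
#'
#' @param clusters Cluster tibble ([cluster_breakpoints()]; inverted and
#'   non-inverted tables may be row-bound first if their `cluster_id`s are
#'   disjoint -- see [cluster_all_breakpoints()]).
#' @param breakpoints Clustered signals (`cluster` column) for the same ids.
#' @param folds Fold bookkeeping from [resolve_artifacts()].
#' @param min_read_support Minimum distinct supporting reads (default 3).
#' @return `clusters` with vote columns `P`, `N`, `PR`, `NR` and a logical
#'   `retained`.
#' @export
filter_clusters <- function(clusters, breakpoints, folds = NULL,
                            min_read_support = 3) {
  if (nrow(clusters) == 0L) {
    return(mutate(clusters, P = integer(), N = integer(), PR = integer(),
                  NR = integer(), retained = logical()))
  }
  votes <- vote_tallies(clusters, breakpoints, folds)
  clusters <- left_join(clusters, votes, by = "cluster_id")
  clusters %>%
    mutate(
      vote_ok = case_when(
        .data$P + .data$N > 0L ~ .data$P > .data$N,
        .data$PR + .data$NR > 0L ~ .data$PR > .data$NR,
        TRUE ~ TRUE   # no votes of either kind: read support decides
      ),
      retained = .data$n_reads >= min_read_support & .data$vote_ok
    ) %>%
    select(-"vote_ok")
}

# Per-cluster vote tallies. A signal counts as an occurrence of cluster j
# when it lies within `vote_eps` of the cluster centroid in the canonical
# edge plane (same kind); proximity rather than strict DBSCAN membership,
# because the degraded mirrored halves of artifact reads recapitulate real
# junctions with extra coordinate scatter.
vote_tallies <- function(clusters, breakpoints, folds, vote_eps = 1000) {
  k <- nrow(clusters)
  P <- N <- PR <- NR <- integer(k)
  fold_map <- if (!is.null(folds) && nrow(folds)) {
    setNames(folds$fold_read_pos, folds$read_id)
  } else NULL
  fold_pos <- if (!is.null(fold_map)) {
    unname(fold_map[breakpoints$read_id])
  } else rep(NA_real_, nrow(breakpoints))

  # which reads repeat some cluster (among non-fold reads), for NR
  occ <- matrix(FALSE, nrow(breakpoints), k)
  for (j in seq_len(k)) {
    occ[, j] <- breakpoints$kind == clusters$kind[j] &
      sqrt((breakpoints$edge_lo - clusters$centroid_a[j])^2 +
             (breakpoints$edge_hi - clusters$centroid_b[j])^2) <= vote_eps
  }
  rid <- breakpoints$read_id
  for (j in seq_len(k)) {
    hit <- occ[, j]
    if (!any(hit)) next
    fold_reads <- unique(rid[hit & !is.na(fold_pos)])
    for (r in fold_reads) {
      sel <- hit & rid == r
      sides <- unique(breakpoints$read_pos[sel] > fold_map[r])
      if (length(sides) > 1L) P[j] <- P[j] + 1L else N[j] <- N[j] + 1L
    }
    plain <- is.na(fold_pos)
    tab <- table(rid[hit & plain])
    PR[j] <- sum(tab >= 2L)
    # reads that repeat some cluster but hold this one exactly once
    once <- names(tab)[tab == 1L]
    if (length(once)) {
      rep_any <- vapply(once, function(r) {
        sel <- plain & rid == r
        any(colSums(occ[sel, , drop = FALSE]) >= 2L)
      }, logical(1))
      NR[j] <- sum(rep_any)
    }
  }
  tibble(cluster_id = clusters$cluster_id, P = P, N = N, PR = PR, NR = NR)
}

#' Cluster and filter both breakpoint kinds in one call
#'
#' Convenience wrapper: clusters non-inverted and inverted signals
#' separately (disjoint cluster ids, inverted ids offset), concatenates the
#' tables, and applies [filter_clusters()].
#'
#' @inheritParams cluster_breakpoints
#' @inheritParams filter_clusters
#' @param eps_noninv Radius for non-inverted signals, bp (default 1000).
#' @return List with `breakpoints` (clustered signals of both kinds) and
#'   `clusters` (vote-annotated cluster table).
#' @export
cluster_all_breakpoints <- function(breakpoints, folds = NULL, min_pts = 3,
                                    eps_noninv = 1000, min_read_support = 3,
                                    split_kmeans = TRUE) {
  ni <- cluster_breakpoints(breakpoints, "noninverted", min_pts = min_pts,
                            eps = eps_noninv, split_kmeans = split_kmeans)
  iv <- cluster_breakpoints(breakpoints, "inverted", min_pts = min_pts,
                            split_kmeans = split_kmeans)
  offset <- if (nrow(ni$clusters)) max(ni$clusters$cluster_id) else 0L
  iv$clusters$cluster_id <- iv$clusters$cluster_id + offset
  iv$breakpoints$cluster <- iv$breakpoints$cluster + offset
  sig <- bind_rows(ni$breakpoints, iv$breakpoints)
  clusters <- bind_rows(ni$clusters, iv$clusters)
  # votes see every non-artifact signal (including DBSCAN noise points):
  # mirrored-half recapitulations are matched by proximity
  clusters <- filter_clusters(clusters, breakpoints, folds = folds,
                              min_read_support = min_read_support)
  retained_ids <- clusters$cluster_id[clusters$retained]
  sig <- filter(sig, .data$cluster %in% retained_ids)
  list(breakpoints = sig, clusters = clusters)
}
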