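# Repeat-structure reconstruction: direct tandem detection within reads,
# partial (mixed) repeat detection, transition-matrix inference for units
# too large to repeat within reads, primary selection, and excision-class
# labelling of alternates.

#' Detect a tandem repeat unit within one encoded read
#'
#' Computes the shortest unit whose repetition, with no intervening
#' breakpoints and in *both* encoding schemes, covers at least `min_periods`
#' periods of the read's token sequence (the longest-common-prefix
#' criterion). The unit is reported in canonical rotation (lexicographically
#' smallest rotation of the numeric encoding).
#'
#' @param encoded_read One row of [encode_reads()] output (or a list with
#'   `numeric_enc`, `orient_enc`, `labels`, `segments`).
#' @param min_periods Minimum number of observed periods (default 2).
#' @return A one-row structure tibble (`clusters`, `alignments`,
#'   `period_bp`, `span_bp`, `n_periods`, `role = "tandem"`), or `NULL` when
#'   the read shows no qualifying repeat.
#' @export
detect_tandem_repeats <- function(encoded_read, min_periods = 2) {
  num <- unlist(encoded_read$numeric_enc)
  ori <- unlist(encoded_read$orient_enc)
  n <- length(num)
  if (n < 2L) return(NULL)
  p_num <- smallest_period(num)
  p_ori <- smallest_period(ori)
  if (is.na(p_num) || is.na(p_ori)) return(NULL)
  p <- max(p_num, p_ori)   # both encodings must repeat with the unit
  if (n / p < min_periods) return(NULL)
  labels <- unlist(encoded_read$labels)
  segs <- encoded_read$segments[[1]]
  aln <- NULL
  if (!is.null(segs) && nrow(segs) >= p + 1L) {
    cand <- segs[2L:(p + 1L), ]
    if (all(cand$interior)) aln <- select(cand, -"interior")
  }
  unit <- canonical_rotation(num[seq_len(p)])
  tibble(
    clusters = list(sort(unique(labels[seq_len(p)]))),
    unit = list(unit),
    alignments = list(aln),
    period_bp = if (!is.null(aln)) sum(aln$ref_end - aln$ref_start) else NA_real_,
    span_bp = if (!is.null(aln)) max(aln$ref_end) - min(aln$ref_start) else NA_real_,
    n_periods = n / p,
    role = "tandem"
  )
}

#' Detect partially repeated (mixed) units within one encoded read
#'
#' Looks for the non-periodic mixed-structure signature: the same alignment
#' repeated with the same orientation but separated by a single inverted
#' alignment (pattern `A, B', A`), detectable after 1.5 observed periods.
#' Patterns where all three alignments share an orientation are left to the
#' tandem detector; any other pattern yields nothing.
#'
#' @param encoded_read One row of [encode_reads()] output.
#' @param min_periods Minimum observed periods (default 1.5; the `A, B', A`
#'   pattern shows exactly 1.5).
#' @param tol Tolerance in bp when matching the repeated alignment's
#'   junction-facing edges (default 200).
#' @return One-row structure tibble (`role = "mixed-partial"`) or `NULL`.
#' @export
detect_partial_repeats <- function(encoded_read, min_periods = 1.5,
                                   tol = 200) {
  segs <- encoded_read$segments[[1]]
  if (is.null(segs) || nrow(segs) < 3L) return(NULL)
  labels <- unlist(encoded_read$labels)
  for (i in seq_len(nrow(segs) - 2L)) {
    a <- segs[i, ]; b <- segs[i + 1L, ]; c <- segs[i + 2L, ]
    if (a$strand != c$strand || b$strand == a$strand) next
    # the two A copies must be the same alignment: overlapping intervals
    # whose endpoints agree within tol (a copy truncated at a read end is
    # only required to agree at its junction-facing edge)
    overlap <- min(a$ref_end, c$ref_end) - max(a$ref_start, c$ref_start)
    agree_start <- abs(a$ref_start - c$ref_start) <= tol ||
      !a$interior || !c$interior
    agree_end <- abs(a$ref_end - c$ref_end) <= tol ||
      !a$interior || !c$interior
    if (!(overlap > 0 && agree_start && agree_end)) next
    if (1.5 < min_periods) next
    unit_aln <- tibble(
      ref_start = c(if (a$interior) a$ref_start else c$ref_start,
                    b$ref_start),
      ref_end = c(if (a$interior) a$ref_end else c$ref_end, b$ref_end),
      strand = c(a$strand, b$strand)
    )
    return(tibble(
      clusters = list(sort(unique(labels[c(i, i + 1L)]))),
      unit = list(NULL),
      alignments = list(unit_aln),
      period_bp = sum(unit_aln$ref_end - unit_aln$ref_start),
      span_bp = max(unit_aln$ref_end) - min(unit_aln$ref_start),
      n_periods = 1.5,
      role = "mixed-partial"
    ))
  }
  NULL
}

#' Build the breakpoint transition matrix
#'
#' `T[i, j]` counts, across all reads, the number of within-read
#' transitions from a signal in cluster `i` to the next signal in cluster
#' `j` (read order). Reads with a removed fold contribute only their
#' pre-fold half when `folds` is given to [encode_reads()].
#'
#' @param encoded_reads Output of [encode_reads()].
#' @return Integer matrix with cluster-id dimnames (zero matrix when no
#'   read holds two or more signals).
#' @export
build_transition_matrix <- function(encoded_reads) {
  ids <- sort(unique(unlist(encoded_reads$labels)))
  T_ <- matrix(0L, length(ids), length(ids),
               dimnames = list(as.character(ids), as.character(ids)))
  for (lab in encoded_reads$labels) {
    if (length(lab) < 2L) next
    for (k in seq_len(length(lab) - 1L)) {
      i <- as.character(lab[k]); j <- as.character(lab[k + 1L])
      T_[i, j] <- T_[i, j] + 1L
    }
  }
  T_
}

#' Merge breakpoint transitions into candidate repeat structures
#'
#' Transitions sharing a breakpoint whose counts agree -- maximum
#' fractional difference of each count from their mean below
#' `merge_threshold`, a binomial one-standard-deviation criterion -- are
#' merged into lists, recursively (largest counts first, fixed order for
#' reproducibility). A merged list is emitted as a candidate structure only
#' when its number of distinct breakpoints equals its number of unique
#' transitions, the closure condition for a true repeat.
#'
#' @param T_ Transition matrix ([build_transition_matrix()]).
#' @param merge_threshold Fractional-difference threshold (default 0.34).
#' @return Tibble of candidates: `clusters` (list of cluster ids),
#'   `transitions` (list of `"i->j"` strings), `count` (average count),
#'   `is_repeat` (closure condition).
#' @export
merge_transitions <- function(T_, merge_threshold = 0.34) {
  nz <- which(T_ > 0, arr.ind = TRUE)
  if (length(nz) == 0L) {
    return(tibble(clusters = list(), transitions = list(),
                  count = numeric(), is_repeat = logical()))
  }
  ids <- rownames(T_)
  lists <- lapply(seq_len(nrow(nz)), function(r) {
    i <- ids[nz[r, 1]]; j <- ids[nz[r, 2]]
    list(members = unique(c(i, j)),
         transitions = paste0(i, "->", j),
         count = as.numeric(T_[nz[r, 1], nz[r, 2]]))
  })
  repeat {
    ord <- order(vapply(lists, `[[`, numeric(1), "count"), decreasing = TRUE)
    lists <- lists[ord]
    merged <- FALSE
    for (a in seq_along(lists)) {
      for (b in seq_along(lists)) {
        if (b <= a) next
        la <- lists[[a]]; lb <- lists[[b]]
        if (!length(intersect(la$members, lb$members))) next
        cbar <- mean(c(la$count, lb$count))
        if (cbar <= 0) next
        if (max(abs(c(la$count, lb$count) - cbar)) / cbar < merge_threshold) {
          lists[[a]] <- list(
            members = sort(unique(c(la$members, lb$members))),
            transitions = unique(c(la$transitions, lb$transitions)),
            count = cbar
          )
          lists[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  tibble(
    clusters = lapply(lists, function(l) sort(as.integer(l$members))),
    transitions = lapply(lists, `[[`, "transitions"),
    count = vapply(lists, `[[`, numeric(1), "count"),
    is_repeat = vapply(lists, function(l) {
      length(l$members) == length(unique(l$transitions))
    }, logical(1))
  )
}

#' Reconstruct repeat structures from clustered breakpoints
#'
#' The full reconstruction path: encode reads, build and merge the
#' transition matrix, keep closed (true-repeat) candidates, and recover each
#' candidate's alignment intervals from the reference footprints of its
#' supporting reads (reads whose cluster labels all belong to the candidate
#' and to no smaller candidate). The structure spanning the largest
#' reference interval is labelled `primary`, the rest `alternate`, and each
#' alternate receives a Type I/II/III excision class via
#' [classify_excision()].
#'
#' @param breakpoints Clustered, filtered breakpoint tibble.
#' @param clusters Retained cluster tibble.
#' @param alignments Filtered alignment tibble.
#' @param folds Fold bookkeeping ([resolve_artifacts()]).
#' @param merge_threshold Passed to [merge_transitions()].
#' @param merge_gap Reference gap (bp) below which supporting segments are
#'   fused into one alignment interval (default 100).
#' @return Structure tibble: `structure_id`, `role`, `excision_class`,
#'   `clusters` (list), `alignments` (list-tibble), `period_bp`, `span_bp`,
#'   `count`, `n_reads`.
#' @export
reconstruct_structures <- function(breakpoints, clusters, alignments,
                                   folds = NULL, merge_threshold = 0.34,
                                   merge_gap = 100) {
  retained <- clusters$cluster_id[clusters$retained %||% rep(TRUE, nrow(clusters))]
  bp <- filter(breakpoints, .data$cluster %in% retained)
  enc <- encode_reads(bp, alignments, folds = folds)
  T_ <- build_transition_matrix(enc)
  cand <- merge_transitions(T_, merge_threshold = merge_threshold)
  cand <- filter(cand, .data$is_repeat)
  if (nrow(cand) == 0L) return(empty_structures())

  cluster_sets <- cand$clusters
  rows <- vector("list", nrow(cand))
  for (s in seq_len(nrow(cand))) {
    cs <- cluster_sets[[s]]
    # supporting reads: labels within this candidate's clusters, and not
    # fully within a strictly smaller candidate (those belong to it)
    smaller <- cluster_sets[vapply(cluster_sets, function(o) {
      length(o) < length(cs) && all(o %in% cs)
    }, logical(1))]
    sup <- vapply(enc$labels, function(lab) {
      all(lab %in% cs) &&
        !any(vapply(smaller, function(o) all(lab %in% o), logical(1)))
    }, logical(1))
    segs <- bind_rows(enc$segments[sup])
    if (nrow(segs) == 0L) next
    aln <- union_intervals(segs, merge_gap = merge_gap)
    rows[[s]] <- tibble(
      clusters = list(cs),
      alignments = list(aln),
      period_bp = sum(aln$ref_end - aln$ref_start),
      span_bp = max(aln$ref_end) - min(aln$ref_start),
      count = cand$count[s],
      n_reads = sum(sup)
    )
  }
  st <- bind_rows(rows)
  if (nrow(st) == 0L) return(empty_structures())
  st <- st %>%
    mutate(structure_id = row_number(), .before = 1L)
  prim <- select_primary(st)
  st$role <- ifelse(st$structure_id == prim$structure_id, "primary",
                    "alternate")
  st$excision_class <- NA_character_
  for (s in seq_len(nrow(st))) {
    if (st$role[s] == "alternate") {
      st$excision_class[s] <- classify_excision(st[s, ], prim, clusters)
    }
  }
  select(st, "structure_id", "role", "excision_class", "clusters",
         "alignments", "period_bp", "span_bp", "count", "n_reads")
}

empty_structures <- function() {
  tibble(structure_id = integer(), role = character(),
         excision_class = character(), clusters = list(),
         alignments = list(), period_bp = numeric(), span_bp = numeric(),
         count = numeric(), n_reads = integer())
}

# Union of reference intervals with gap fusing; orientation by bp-majority.
union_intervals <- function(segs, merge_gap = 100) {
  segs <- arrange(segs, .data$ref_start)
  out <- list()
  cur_s <- segs$ref_start[1]; cur_e <- segs$ref_end[1]
  members <- 1L
  flush <- function(cur_s, cur_e, members) {
    sub <- segs[members, ]
    w <- tapply(sub$ref_end - sub$ref_start, sub$strand, sum)
    tibble(ref_start = cur_s, ref_end = cur_e,
           strand = names(w)[which.max(w)])
  }
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs$ref_start[i] <= cur_e + merge_gap) {
      cur_e <- max(cur_e, segs$ref_end[i])
      members <- c(members, i)
    } else {
      out[[length(out) + 1L]] <- flush(cur_s, cur_e, members)
      cur_s <- segs$ref_start[i]; cur_e <- segs$ref_end[i]
      members <- i
    }
  }
  out[[length(out) + 1L]] <- flush(cur_s, cur_e, members)
  bind_rows(out)
}

#' Select the primary structure
#'
#' The primary repeat is the structure with the largest span on the
#' reference; ties break toward the higher supporting observation count
#' (supporting reads when available, since within-read transition counts
#' systematically under-count units longer than typical reads), then the
#' lower start coordinate.
#'
#' @param structures Structure tibble.
#' @return The selected one-row tibble (or `NULL` for empty input).
#' @export
select_primary <- function(structures) {
  if (nrow(structures) == 0L) return(NULL)
  start <- vapply(structures$alignments,
                  function(a) min(a$ref_start), numeric(1))
  support <- structures$n_reads %||% structures$count
  ord <- order(-structures$span_bp, -support, start)
  structures[ord[1], ]
}

#' Classify an alternate structure's excision type
#'
#' Compares the alternate's breakpoint-cluster edges with the primary's.
#' An edge is *shared* when the two cluster-edge means agree within one
#' standard deviation (`max` of the two SDs by default, pooled optionally).
#' Type I alternates (excised from the interior of a primary alignment)
#' share no edge; Type II (spanning the primary junction) share both
#' primary edges and hold more than one alignment; Type III share exactly
#' one edge with a single alignment. Anything else is `unclassified`.
#'
#' @param alternate,primary One-row structure tibbles.
#' @param clusters Cluster tibble supplying per-edge means and SDs.
#' @param sd_rule `"max"` (default) or `"pooled"`.
#' @return Class label: `"I"`, `"II"`, `"III"` or `"unclassified"`.
#' @export
classify_excision <- function(alternate, primary, clusters,
                              sd_rule = c("max", "pooled")) {
  sd_rule <- match.arg(sd_rule)
  alt_edges <- structure_edges(alternate, clusters)
  pri_edges <- structure_edges(primary, clusters)
  shared <- 0L
  for (e in seq_len(nrow(alt_edges))) {
    tolerance <- if (sd_rule == "max") {
      pmax(alt_edges$sd[e], pri_edges$sd)
    } else {
      sqrt((alt_edges$sd[e]^2 + pri_edges$sd^2) / 2)
    }
    if (any(abs(alt_edges$pos[e] - pri_edges$pos) <= tolerance)) {
      shared <- shared + 1L
    }
  }
  n_aln <- nrow(alternate$alignments[[1]])
  if (shared == 0L) return("I")
  if (shared == 2L && n_aln > 1L) return("II")
  if (shared == 1L && n_aln == 1L) return("III")
  warn(sprintf("structure %s matches no excision class (%d shared edges, %d alignments)",
               alternate$structure_id %||% "?", shared, n_aln))
  "unclassified"
}

# Per-structure breakpoint edges (position and SD) from its clusters.
structure_edges <- function(structure, clusters) {
  cs <- structure$clusters[[1]]
  cl <- clusters[clusters$cluster_id %in% cs, ]
  tibble(pos = c(cl$centroid_a, cl$centroid_b),
         sd = c(cl$sd_a, cl$sd_b))
}

#' Fractional distances between alternate and primary alignment edges
#'
#' For every breakpoint edge of every alternate structure, the distance to
#' the closest primary alignment edge, normalised by that primary
#' alignment's length. Type III alternates sit at tiny fractional distances
#' (edge reuse); Type I alternates are spread across the alignment body.
#'
#' @param structures Structure tibble (with roles and classes assigned).
#' @param clusters Cluster tibble.
#' @param summarise Return per-class mean/median instead of per-edge rows.
#' @return Tibble of per-edge fractional distances (`structure_id`,
#'   `excision_class`, `edge_pos`, `fractional_distance`), or the per-class
#'   summary.
#' @export
edge_distance_stats <- function(structures, clusters, summarise = FALSE) {
  prim <- filter(structures, .data$role == "primary")
  if (nrow(prim) == 0L) abort("no primary structure present")
  pri_aln <- prim$alignments[[1]]
  pri_edges <- c(pri_aln$ref_start, pri_aln$ref_end)
  pri_lens <- rep(pri_aln$ref_end - pri_aln$ref_start, 2L)
  alts <- filter(structures, .data$role == "alternate")
  rows <- purrr::map_dfr(seq_len(nrow(alts)), function(s) {
    edges <- structure_edges(alts[s, ], clusters)
    purrr::map_dfr(edges$pos, function(p) {
      d <- abs(p - pri_edges)
      k <- which.min(d)
      tibble(structure_id = alts$structure_id[s],
             excision_class = alts$excision_class[s],
             edge_pos = p,
             fractional_distance = d[k] / pri_lens[k])
    })
  })
  if (!summarise) return(rows)
  rows %>%
    group_by(.data$excision_class) %>%
    summarise(mean = mean(.data$fractional_distance),
              median = median(.data$fractional_distance),
              n_edges = dplyr::n(), .groups = "drop")
}
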