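# Read-length sampling-bias correction and structure frequency estimation.
# Long structures are under-observed by finite reads; visibilities Q(L)
# derived from a shifted-exponential read-length fit put raw counts of
# different structures on a common footing.

#' Fit the shifted-exponential read-length model
#'
#' Maximum-likelihood fit of `x ~ mu + Exponential(beta)`:
#' `mu = min(lengths)`, `beta = mean(lengths) - mu`.
#'
#' @param read_lengths Numeric vector of read lengths (>= 10 reads).
#' @return A [read_length_model()] (fields `mu`, `beta`).
#' @export
fit_read_lengths <- function(read_lengths) {
  read_lengths <- read_lengths[!is.na(read_lengths)]
  if (length(read_lengths) < 10L) {
    abort("need at least 10 read lengths to fit the model")
  }
  mu <- min(read_lengths)
  beta <- mean(read_lengths) - mu
  if (beta <= 0) {
    warn("degenerate read-length distribution; beta set to machine epsilon")
    beta <- .Machine$double.eps
  }
  read_length_model(mu, beta)
}

#' Visibility of one mixed-structure alignment
#'
#' The joint probability that a read is long enough to contain an alignment
#' of length `L` and does not truncate it:
#' `Q(L) = (1 - L / sum(all_lengths)) * exp(-(L - mu) / beta)`, with the
#' exponential factor clamped to 1 for `L < mu` (no reads shorter than the
#' location parameter exist under the model).
#'
#' @param L Alignment length, bp (must be one of `all_lengths`).
#' @param all_lengths Lengths of all alignments in the mixed structure.
#' @param fit [read_length_model()] / [fit_read_lengths()] result.
#' @return Visibility in (0, 1].
#' @export
mixed_visibility <- function(L, all_lengths, fit) {
  total <- sum(all_lengths)
  if (total <= 0) abort("alignment lengths sum to zero")
  (1 - L / total) * exp(-pmax(L - fit$mu, 0) / fit$beta)
}

#' Bias-corrected mixed-structure alignment frequencies
#'
#' `nu_i = (N_i / Q(L_i)) / sum_j (N_j / Q(L_j))`; the corrected relative
#' frequency of each alignment of a mixed structure.
#'
#' @param raw_counts Observed (complete) occurrence counts per alignment.
#' @param lengths Alignment lengths, same order.
#' @param fit Read-length model.
#' @return Tibble: `length`, `raw_count`, `raw_frequency`, `Q`,
#'   `frequency` (sums to 1).
#' @export
mixed_frequencies <- function(raw_counts, lengths, fit) {
  stopifnot(length(raw_counts) == length(lengths), all(raw_counts >= 0),
            any(raw_counts > 0))
  Q <- vapply(lengths, mixed_visibility, numeric(1),
              all_lengths = lengths, fit = fit)
  if (any(Q <= 0 & raw_counts > 0)) {
    abort("zero visibility for a counted alignment")
  }
  w <- raw_counts / Q
  tibble(length = lengths, raw_count = raw_counts,
         raw_frequency = raw_counts / sum(raw_counts),
         Q = Q, frequency = w / sum(w))
}

#' Count complete mixed-structure alignment occurrences in reads
#'
#' Counts, per structure alignment, the read segments that are interior
#' (bounded by junctions on both sides, so not truncated by read ends) and
#' whose reference interval matches the alignment within `tol`.
#'
#' @param alignments Filtered alignment segment tibble.
#' @param structure_alignments Tibble of the mixed structure's alignments
#'   (`ref_start`, `ref_end`).
#' @param tol Endpoint matching tolerance, bp (default 300).
#' @return `structure_alignments` with `length` and `count` columns.
#' @export
count_mixed_alignments <- function(alignments, structure_alignments,
                                   tol = 300) {
  interior <- alignments %>%
    group_by(.data$read_id) %>%
    filter(row_number() > 1L, row_number() < dplyr::n()) %>%
    ungroup()
  counts <- integer(nrow(structure_alignments))
  for (k in seq_len(nrow(structure_alignments))) {
    counts[k] <- sum(
      abs(interior$ref_start - structure_alignments$ref_start[k]) <= tol &
        abs(interior$ref_end - structure_alignments$ref_end[k]) <= tol
    )
  }
  structure_alignments %>%
    mutate(length = .data$ref_end - .data$ref_start, count = counts)
}

#' Visibility of a repeat structure of period `Lk`
#'
#' The probability that a read sampled at uniform phase from a concatemer
#' of period `Lk` shows the structure's breakpoint:
#' `Q(Lk) = P(x > Lk) + E[(x / Lk) ; u <= x < Lk]` under the fitted
#' shifted-exponential read-length density, evaluated in closed form
#' (`int x f(x) dx` has antiderivative `-(x + beta) exp(-(x - mu)/beta)`).
#'
#' @param Lk Repeat-unit period, bp (> 0).
#' @param fit Read-length model.
#' @param u Lower integration bound; defaults to `fit$mu` (reads shorter
#'   than the location parameter do not exist under the model).
#' @return Visibility `Q` in (0, 1 + mu/Lk].
#' @export
structure_visibility <- function(Lk, fit, u = NULL) {
  stopifnot(Lk > 0)
  mu <- fit$mu; beta <- fit$beta
  u <- u %||% mu
  term1 <- if (Lk >= mu) exp(-(Lk - mu) / beta) else 1
  lower <- max(u, mu)
  term2 <- 0
  if (lower < Lk) {
    anti <- function(x) -(x + beta) * exp(-(x - mu) / beta)
    term2 <- (anti(Lk) - anti(lower)) / Lk
  }
  term1 + term2
}

#' Assign reads to reconstructed structures
#'
#' Each read goes to the structure sharing the most breakpoint-cluster
#' labels with it, among structures whose reference footprint contains all
#' of the read's mapped content (segments and terminal positions, with
#' `tol` slack). Ties break toward the larger reference span, then the
#' larger supporting count. Reads with no containing structure or no label
#' overlap stay unassigned (`NA`).
#'
#' @param encoded_reads [encode_reads()] output.
#' @param structures Structure tibble ([reconstruct_structures()]).
#' @param tol Containment slack, bp (default 1000).
#' @return Tibble `read_id`, `structure_id` (NA when unassigned).
#' @export
assign_reads_to_structures <- function(encoded_reads, structures,
                                       tol = 1000) {
  if (nrow(structures) == 0L) {
    return(tibble(read_id = encoded_reads$read_id,
                  structure_id = NA_integer_))
  }
  foot <- lapply(structures$alignments, function(a) {
    cbind(a$ref_start - tol, a$ref_end + tol)
  })
  res <- integer(nrow(encoded_reads))
  for (r in seq_len(nrow(encoded_reads))) {
    segs <- encoded_reads$segments[[r]]
    labs <- unique(unlist(encoded_reads$labels[r]))
    best <- NA_integer_; best_key <- c(-Inf, -Inf, -Inf)
    for (s in seq_len(nrow(structures))) {
      fp <- foot[[s]]
      contained <- all(vapply(seq_len(nrow(segs)), function(i) {
        any(segs$ref_start[i] >= fp[, 1] & segs$ref_end[i] <= fp[, 2])
      }, logical(1)))
      if (!contained) next
      overlap <- length(intersect(labs, structures$clusters[[s]]))
      if (overlap == 0L) next
      support <- structures$n_reads[s] %||% structures$count[s]
      key <- c(overlap, structures$span_bp[s], support)
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] &&
             key[3] > best_key[3])) {
        best <- structures$structure_id[s]; best_key <- key
      }
    }
    res[r] <- best
  }
  tibble(read_id = encoded_reads$read_id, structure_id = res)
}

#' Bias-corrected relative frequencies of reconstructed structures
#'
#' Assigned reads are reduced to per-structure breakpoint counts `J_k`
#' (by default the number of assigned reads showing at least one of the
#' structure's breakpoints -- the event whose probability the visibility
#' `Q(L_k)` models; `counting = "instances"` counts every breakpoint
#' occurrence instead), then normalised:
#' `freq_k = (J_k / Q(L_k)) / sum_m (J_m / Q(L_m))`.
#'
#' @param assignments Output of [assign_reads_to_structures()].
#' @param encoded_reads [encode_reads()] output.
#' @param structures Structure tibble.
#' @param fit Read-length model.
#' @param u Lower integration bound for [structure_visibility()].
#' @param counting `"reads"` (default) or `"instances"`.
#' @return `structures` with columns `J`, `Q`, `frequency`.
#' @export
structure_frequencies <- function(assignments, encoded_reads, structures,
                                  fit, u = NULL,
                                  counting = c("reads", "instances")) {
  counting <- match.arg(counting)
  enc <- left_join(encoded_reads, assignments, by = "read_id")
  J <- numeric(nrow(structures))
  for (s in seq_len(nrow(structures))) {
    sid <- structures$structure_id[s]
    cs <- structures$clusters[[s]]
    rows <- which(enc$structure_id == sid)
    hits <- vapply(enc$labels[rows],
                   function(lab) sum(lab %in% cs), numeric(1))
    J[s] <- if (counting == "reads") sum(hits > 0) else sum(hits)
  }
  Q <- vapply(structures$period_bp, structure_visibility, numeric(1),
              fit = fit, u = u)
  w <- J / Q
  structures %>%
    mutate(J = J, Q = Q,
           frequency = if (sum(w) > 0) w / sum(w) else NA_real_)
}

#' Colony-level alternate-structure base-pair fraction
#'
#' The fraction of mitochondrial base pairs contributed by reads showing
#' any breakpoint that is not the primary structure's, lies internal to the
#' primary alignments, and is not accompanied by an inverted-duplication
#' artifact. No cluster-support requirement is applied: in colonies where
#' alternate structures are too rare to form clusters this read-enumeration
#' fraction is still informative.
#'
#' @param breakpoints Breakpoint tibble (artifact candidates flagged;
#'   clustering not required).
#' @param alignments Filtered alignment tibble (defines the read universe
#'   and read lengths).
#' @param primary One-row primary structure tibble.
#' @param clusters Cluster tibble (for the primary's junction centroids).
#' @param artifact_read_ids Reads carrying a removed artifact fold
#'   (excluded from the numerator).
#' @param eps Distance in the edge plane below which a signal is considered
#'   the primary's own junction, bp (default 1000).
#' @return Fraction in `[0, 1]`.
#' @export
alternate_bp_fraction <- function(breakpoints, alignments, primary, clusters,
                                  artifact_read_ids = character(),
                                  eps = 1000) {
  reads <- alignments %>% distinct(.data$read_id, .data$read_length)
  total_bp <- sum(as.numeric(reads$read_length))
  if (total_bp <= 0) abort("no mitochondrial base pairs in input")
  if (nrow(breakpoints) == 0L) return(0)
  pri_cl <- clusters[clusters$cluster_id %in% primary$clusters[[1]], ]
  pri_aln <- primary$alignments[[1]]
  is_primary_junction <- rep(FALSE, nrow(breakpoints))
  for (i in seq_len(nrow(pri_cl))) {
    d <- sqrt((breakpoints$edge_lo - pri_cl$centroid_a[i])^2 +
                (breakpoints$edge_hi - pri_cl$centroid_b[i])^2)
    is_primary_junction <- is_primary_junction | d <= eps
  }
  inside <- function(pos) {
    vapply(pos, function(p) {
      any(p >= pri_aln$ref_start - eps & p <= pri_aln$ref_end + eps)
    }, logical(1))
  }
  internal <- inside(breakpoints$edge_lo) & inside(breakpoints$edge_hi)
  qualifying <- !is_primary_junction & internal &
    !(breakpoints$read_id %in% artifact_read_ids)
  q_reads <- unique(breakpoints$read_id[qualifying])
  sum(as.numeric(reads$read_length[reads$read_id %in% q_reads])) / total_bp
}
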