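# Read encoding over breakpoint-cluster labels. Each read becomes two token
# sequences: numeric encoding (cluster id + LH/HL reference transition) and
# orientation encoding (cluster id + strand pair), e.g. a read sampling a
# tandemly repeated unit on the plus strand looks like
# [2LH, 2LH, ...] / [2++, 2++, ...]. Both schemes are needed for mixed
# structures, where two breakpoints generate four alignments through
# orientation permutations.

#' Encode reads over breakpoint-cluster labels
#'
#' Builds the per-read token sequences used by the repeat detectors and the
#' transition matrix, plus the read's reference footprint (its mapped
#' segments and terminal reference positions) used to assign reads to
#' structures. Reads carrying a removed inverted-duplication fold are
#' truncated at the fold: only the first (clean) half is encoded.
#'
#' @param breakpoints Clustered breakpoint tibble (`cluster` column).
#' @param alignments The filtered alignment tibble the breakpoints were
#'   extracted from.
#' @param folds Fold bookkeeping from [resolve_artifacts()] (optional).
#' @return Tibble, one row per read with at least one clustered signal:
#'   `read_id`, `read_length`, `n_signals`, `labels` (list of cluster ids in
#'   read order), `numeric_enc`, `orient_enc` (list of character tokens),
#'   `end_refs` (list, mapped reference positions of the two read termini),
#'   `segments` (list-tibble of the read's segments:
#'   `ref_start`, `ref_end`, `strand`, `interior`).
#' @export
encode_reads <- function(breakpoints, alignments, folds = NULL) {
  if (!"cluster" %in% names(breakpoints)) {
    abort("breakpoints must carry a 'cluster' column (run clustering first)")
  }
  aln <- alignments %>% arrange(.data$read_id, .data$read_start)
  if (!is.null(folds) && nrow(folds)) {
    fold_map <- setNames(folds$fold_read_pos, folds$read_id)
    fp <- fold_map[breakpoints$read_id]
    breakpoints <- breakpoints[is.na(fp) | breakpoints$read_pos < fp, ]
    fa <- fold_map[aln$read_id]
    aln <- aln[is.na(fa) | aln$read_start < fa, ]
  }
  seg_tbl <- aln %>%
    group_by(.data$read_id) %>%
    mutate(interior = row_number() > 1L & row_number() < dplyr::n()) %>%
    summarise(
      segments = {
        rs <- .data$ref_start; re <- .data$ref_end
        st <- .data$strand; int <- .data$interior
        list(tibble(ref_start = rs, ref_end = re, strand = st,
                    interior = int))
      },
      end_refs = {
        k <- dplyr::n()
        list(c(
          if (.data$strand[1] == "+") .data$ref_start[1] else .data$ref_end[1],
          if (.data$strand[k] == "+") .data$ref_end[k] else .data$ref_start[k]
        ))
      },
      .groups = "drop"
    )
  enc <- breakpoints %>%
    filter(!is.na(.data$cluster)) %>%
    group_by(.data$read_id) %>%
    arrange(.data$read_pos, .by_group = TRUE) %>%
    summarise(
      read_length = first(.data$read_length),
      n_signals = dplyr::n(),
      labels = list(.data$cluster),
      numeric_enc = list(paste0(.data$cluster, .data$transition)),
      orient_enc = list(paste0(.data$cluster, .data$strand_pair)),
      read_positions = list(.data$read_pos),
      .groups = "drop"
    )
  left_join(enc, seg_tbl, by = "read_id")
}

# Lexicographically smallest rotation of a token vector.
canonical_rotation <- function(tokens) {
  n <- length(tokens)
  if (n <= 1L) return(tokens)
  rots <- vapply(seq_len(n), function(k) {
    paste(tokens[c(k:n, seq_len(k - 1L))], collapse = "|")
  }, character(1))
  best <- which.min(rank(rots, ties.method = "min"))
  tokens[c(best:n, seq_len(best - 1L))]
}

# Smallest period p (not necessarily dividing n) under which a token vector
# repeats: tokens[i] == tokens[i - p] for all i > p. Returns NA when only
# the trivial period n exists.
smallest_period <- function(tokens) {
  n <- length(tokens)
  for (p in seq_len(n - 1L)) {
    if (all(tokens[(p + 1L):n] == tokens[seq_len(n - p)])) return(p)
  }
  NA_integer_
}
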