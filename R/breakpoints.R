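# Alignment filtering and breakpoint-signal extraction.

#' Filter alignment segments on mapping quality and length
#'
#' Retains segments with mapping quality strictly above `min_mapq` and
#' reference interval length strictly above `min_len`. The length gate
#' exists because the eight mtDNA replication origins are highly homologous,
#' so short alignments cannot be placed reliably. A mapq of 255
#' ("unavailable") always fails the quality gate.
#'
#' @param alignments Alignment tibble ([read_alignments()]).
#' @param min_mapq Retain mapq > `min_mapq` (default 20).
#' @param min_len Retain `ref_end - ref_start` > `min_len` bp (default 300).
#' @return Filtered alignment tibble, same columns.
#' @export
filter_alignments <- function(alignments, min_mapq = 20, min_len = 300) {
  alignments %>%
    filter(.data$mapq > min_mapq, .data$mapq != 255L,
           (.data$ref_end - .data$ref_start) > min_len)
}

#' Extract breakpoint signals from filtered alignments
#'
#' A breakpoint is a junction between two adjacent alignments within one
#' read. Adjacent alignments on opposite strands always yield an *inverted*
#' signal, regardless of their coordinate separation. Adjacent alignments on
#' the same strand yield a *non-inverted* signal only when the observed
#' reference position of the second alignment deviates by more than
#' `deviation_bp` from the position extrapolated from the first alignment's
#' reference progression across the read-coordinate gap; benign unmapped
#' stretches that advance read and reference together therefore do not
#' produce signals. Read termini are not junctions.
#'
#' The two reported edges are the reference boundaries of the alignment
#' termini facing the junction: `ref_edge_a` from the upstream (in read
#' order) segment, `ref_edge_b` from the downstream segment. `edge_lo` /
#' `edge_hi` hold the same pair canonically sorted, the coordinates used
#' for clustering.
#'
#' @param alignments Filtered alignment tibble (one or many reads).
#' @param deviation_bp Minimum extrapolation deviation for a non-inverted
#'   signal, bp (default 30).
#' @return Breakpoint tibble: `read_id`, `read_length`, `kind`,
#'   `ref_edge_a`, `ref_edge_b`, `edge_lo`, `edge_hi`, `strand_pair`,
#'   `transition`, `read_pos`, `read_pos_fraction`, `mapq_a`, `mapq_b`,
#'   `seg_a`, `seg_b` (row indices of the flanking segments in the
#'   input, after per-read sorting).
#' @export
extract_breakpoints <- function(alignments, deviation_bp = 30) {
  if (nrow(alignments) == 0L) return(empty_breakpoints())
  aln <- alignments %>%
    mutate(.row = row_number()) %>%
    arrange(.data$read_id, .data$read_start)
  a <- aln[-nrow(aln), ]
  b <- aln[-1, ]
  same_read <- a$read_id == b$read_id
  a <- a[same_read, ]; b <- b[same_read, ]
  if (nrow(a) == 0L) return(empty_breakpoints())

  inverted <- a$strand != b$strand
  # facing edges: upstream segment's read-forward right edge, downstream
  # segment's read-forward left edge; a '-' segment reverses reference order
  edge_a <- ifelse(a$strand == "+", a$ref_end, a$ref_start)
  edge_b <- ifelse(b$strand == "+", b$ref_start, b$ref_end)
  read_gap <- b$read_start - a$read_end
  expected_b <- ifelse(a$strand == "+", a$ref_end + read_gap,
                       a$ref_start - read_gap)
  deviation <- abs(expected_b - edge_b)
  is_signal <- inverted | deviation > deviation_bp

  out <- tibble(
    read_id = a$read_id[is_signal],
    read_length = a$read_length[is_signal],
    kind = ifelse(inverted[is_signal], "inverted", "noninverted"),
    ref_edge_a = edge_a[is_signal],
    ref_edge_b = edge_b[is_signal],
    strand_pair = paste0(a$strand, b$strand)[is_signal],
    read_pos = ((a$read_end + b$read_start) / 2)[is_signal],
    mapq_a = a$mapq[is_signal],
    mapq_b = b$mapq[is_signal],
    seg_a = a$.row[is_signal],
    seg_b = b$.row[is_signal]
  )
  out %>%
    mutate(
      edge_lo = pmin(.data$ref_edge_a, .data$ref_edge_b),
      edge_hi = pmax(.data$ref_edge_a, .data$ref_edge_b),
      transition = ifelse(.data$ref_edge_a <= .data$ref_edge_b, "LH", "HL"),
      read_pos_fraction = .data$read_pos / .data$read_length
    ) %>%
    select("read_id", "read_length", "kind", "ref_edge_a", "ref_edge_b",
           "edge_lo", "edge_hi", "strand_pair", "transition", "read_pos",
           "read_pos_fraction", "mapq_a", "mapq_b", "seg_a", "seg_b")
}

empty_breakpoints <- function() {
  tibble(
    read_id = character(), read_length = integer(), kind = character(),
    ref_edge_a = numeric(), ref_edge_b = numeric(),
    edge_lo = numeric(), edge_hi = numeric(), strand_pair = character(),
    transition = character(), read_pos = numeric(),
    read_pos_fraction = numeric(), mapq_a = numeric(), mapq_b = numeric(),
    seg_a = integer(), seg_b = integer()
  )
}
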