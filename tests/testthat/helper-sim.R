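# Shared fixtures: all inputs are generated in code at test time.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# Four-structure colony: a 30 kbp primary tandem repeat plus one alternate
# of each excision class at 5% of mitochondrial content each.
cascade_specs <- function() {
  list(
    structure_spec(tibble(ref_start = 2000, ref_end = 32000, strand = "+"),
                   frequency = 0.85, name = "primary"),
    structure_spec(tibble(ref_start = 9000, ref_end = 15000, strand = "+"),
                   frequency = 0.05, name = "typeI"),
    structure_spec(tibble(ref_start = c(30500, 2000),
                          ref_end = c(32000, 3500),
                          strand = c("+", "+")),
                   frequency = 0.05, name = "typeII"),
    structure_spec(tibble(ref_start = 2000, ref_end = 8000, strand = "+"),
                   frequency = 0.05, name = "typeIII")
  )
}

# Tandem unit with two real inverted junctions whose reference-edge gaps
# exceed the artifact fold-gap criterion.
inverted_tandem_spec <- function() {
  structure_spec(tibble(ref_start = c(2000, 20000),
                        ref_end = c(14000, 23000),
                        strand = c("+", "-")),
                 frequency = 1, name = "inv_tandem")
}

# Four alignments sharing a common region [3000, 7100) with unequal
# extensions; satisfies the mixed-geometry constraint L1+L4 == L2+L3.
mixed_alignments <- function() {
  tibble(ref_start = c(1800, 1800, 3000, 3000),
         ref_end   = c(7700, 7100, 7700, 7100),
         strand    = "+")
}

default_model <- function() read_length_model(1000, 5000)

# Minimal hand-built breakpoint tibble for unit tests.
make_signals <- function(read_id, kind, edge_a, edge_b, strand_pair = NULL,
                         read_pos = NULL, read_length = 10000) {
  n <- length(edge_a)
  strand_pair <- strand_pair %||%
    ifelse(kind == "inverted", "+-", "++")
  tibble(
    read_id = read_id, read_length = read_length, kind = kind,
    ref_edge_a = edge_a, ref_edge_b = edge_b,
    edge_lo = pmin(edge_a, edge_b), edge_hi = pmax(edge_a, edge_b),
    strand_pair = strand_pair,
    transition = ifelse(edge_a <= edge_b, "LH", "HL"),
    read_pos = read_pos %||% seq(1000, by = 1000, length.out = n),
    read_pos_fraction = (read_pos %||% seq(1000, by = 1000, length.out = n)) /
      read_length,
    mapq_a = 60, mapq_b = 60, seg_a = seq_len(n), seg_b = seq_len(n) + 1L
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force DBSCAN oracle: density-connected components by transitive
# closure over core points; border points may legally attach to any
# adjacent core cluster.
brute_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  core <- rowSums(d <= eps) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & labels == 0L &
                      apply(d[, comp, drop = FALSE] <= eps, 1, any))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cl
  }
  list(core = core, labels = labels)
}

# Compare our DBSCAN labels to the oracle: core-point partitions must agree
# exactly; each border point must sit in a cluster holding a core point
# within eps; noise must match.
expect_dbscan_matches_oracle <- function(xy, eps, min_pts) {
  ours <- petiteseq:::dbscan_labels(xy, eps, min_pts)
  d <- as.matrix(dist(xy))
  oracle <- brute_dbscan(xy, eps, min_pts)
  # same noise set
  expect_equal(unname(ours == 0L),
               unname(!oracle$core &
                        !apply(d <= eps, 1, function(r) any(r & oracle$core))))
  # core partition identical (as set of sets)
  part <- function(lab, core) {
    unname(lapply(split(which(core), lab[core]), sort))
  }
  expect_setequal(part(ours, oracle$core), part(oracle$labels, oracle$core))
  # border points attach to a cluster with a core neighbour
  for (i in which(!oracle$core & ours != 0L)) {
    same <- which(ours == ours[i] & oracle$core)
    expect_true(any(d[i, same] <= eps))
  }
}
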