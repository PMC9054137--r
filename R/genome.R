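# Genome-feature statistics and excision null models: origin content of
# structures, GC sliding windows, breakpoint-to-origin displacements, exact
# repeat finding, and the three excision placement models (uniform random,
# between perfect repeats, origin-conditioned).

#' Replication-origin base-pair fraction of a structure
#'
#' The fraction of a repeat unit's base pairs covered by replication-origin
#' intervals (overlaps counted once). Structures with origin densities above
#' the wild-type genome's hold a replicative advantage; structures with
#' fraction 0 ("zero-ori") rely on surrogate GC-cluster elements.
#'
#' @param structure One-row structure tibble (with an `alignments` list
#'   column) or a plain alignments tibble (`ref_start`, `ref_end`).
#' @param origins Origin annotation tibble (`start`, `end`).
#' @return Fraction in `[0, 1]`.
#' @export
origin_content_fraction <- function(structure, origins) {
  aln <- if ("alignments" %in% names(structure)) {
    structure$alignments[[1]]
  } else structure
  period <- sum(aln$ref_end - aln$ref_start)
  if (period <= 0) return(0)
  ov <- 0
  ori <- merge_plain_intervals(origins$start, origins$end)
  for (i in seq_len(nrow(aln))) {
    ov <- ov + sum(pmax(0, pmin(aln$ref_end[i], ori$end) -
                          pmax(aln$ref_start[i], ori$start)))
  }
  ov / period
}

merge_plain_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Sliding-window GC content distribution
#'
#' Scores every window (step 1) of `window` bp by GC fraction. Windows
#' above 0.6 GC are the signature of the GC-cluster elements found in
#' replication origins.
#'
#' @param sequence Nucleotide string (length >= `window`).
#' @param window Window size, bp (default 10).
#' @return List: `gc` (per-window fractions), `cdf` (empirical CDF
#'   function), `frac_above` (fraction of windows with GC > 0.6).
#' @export
gc_sliding_cdf <- function(sequence, window = 10) {
  n <- nchar(sequence)
  if (n < window) abort("sequence shorter than window")
  chars <- strsplit(toupper(sequence), "")[[1]]
  is_gc <- as.integer(chars %in% c("G", "C"))
  cs <- c(0L, cumsum(is_gc))
  gc <- (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
  list(gc = gc, cdf = ecdf(gc), frac_above = mean(gc > 0.6))
}

#' Displacement of breakpoint edges from the nearest replication origin
#'
#' Distance 0 for an edge inside an origin interval, otherwise the gap to
#' the nearest origin boundary. Linear coordinates by default; `circular`
#' wraps distances around the genome.
#'
#' @param edges Numeric vector of reference edge positions.
#' @param origins Origin tibble (`start`, `end`, half-open).
#' @param genome_length Needed when `circular = TRUE`.
#' @param circular Wrap distances around a circular genome.
#' @return Numeric vector of displacements, bp.
#' @export
min_origin_displacement <- function(edges, origins, genome_length = NULL,
                                    circular = FALSE) {
  if (nrow(origins) == 0L) abort("no origins supplied")
  if (circular && is.null(genome_length)) {
    abort("circular distances need genome_length")
  }
  vapply(edges, function(p) {
    d <- pmax(origins$start - p, p - origins$end, 0)
    if (circular) {
      wrap <- pmin(
        (origins$start - p) %% genome_length,
        (p - origins$end) %% genome_length
      )
      inside <- p >= origins$start & p < origins$end
      d <- ifelse(inside, 0, pmin(d, wrap))
    }
    min(d)
  }, numeric(1))
}

#' Find perfect direct repeats in a genome
#'
#' Enumerates all pairs of occurrences of maximal exact same-strand repeats
#' of at least `min_len` bp: short repeated homology of this kind seeds the
#' illegitimate recombination events that excise Petite repeat units.
#' Each reported pair is maximal (extending either end breaks the match).
#'
#' @param genome Genome tibble or nucleotide string.
#' @param min_len Minimum repeat length, bp (default 11).
#' @return Tibble `pos1`, `pos2` (0-based starts, `pos1 < pos2`), `length`.
#' @export
find_perfect_repeats <- function(genome, min_len = 11) {
  seq <- if (is.character(genome)) genome else genome$sequence[[1]]
  n <- nchar(seq)
  if (n < 2 * min_len) {
    return(tibble(pos1 = integer(), pos2 = integer(), length = integer()))
  }
  k <- as.integer(min_len)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  groups <- split(starts, kmers)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  chars <- strsplit(seq, "")[[1]]
  out_p1 <- integer(0); out_p2 <- integer(0); out_len <- integer(0)
  for (g in groups) {
    for (ii in seq_len(length(g) - 1L)) {
      for (jj in (ii + 1L):length(g)) {
        i <- g[ii]; j <- g[jj]
        # left-maximal seed only, so each maximal pair is reported once
        if (i > 1L && j > 1L && chars[i - 1L] == chars[j - 1L]) next
        len <- k
        while (i + len <= n && j + len <= n &&
               chars[i + len] == chars[j + len]) {
          len <- len + 1L
        }
        out_p1 <- c(out_p1, i - 1L)   # back to 0-based
        out_p2 <- c(out_p2, j - 1L)
        out_len <- c(out_len, len)
      }
    }
  }
  distinct(tibble(pos1 = out_p1, pos2 = out_p2, length = out_len))
}

#' Simulate excision placement null models
#'
#' Three models for where excised fragments (and hence breakpoint edges)
#' fall on the reference:
#'
#' * `uniform`: fragment lengths drawn from `length_source`, starts uniform
#'   on the linear reference (fragments must fit; no wraparound).
#' * `perfect_repeat`: a pair of occurrences of a maximal exact direct
#'   repeat of at least `min_repeat_len` bp is drawn uniformly; the
#'   fragment is the interval between the two copies.
#' * `origin_conditioned`: as `uniform`, but each fragment is conditioned
#'   on overlapping a uniformly pre-selected replication origin (strong
#'   selection for origin-containing fragments).
#'
#' Both edges of every fragment are pooled into the displacement sample.
#'
#' @param genome Genome tibble.
#' @param origins Origin tibble.
#' @param model One of `"uniform"`, `"perfect_repeat"`,
#'   `"origin_conditioned"`.
#' @param n_fragments Number of fragments to draw.
#' @param length_source Empirical fragment-length vector (required for the
#'   uniform and origin-conditioned models).
#' @param min_repeat_len Minimum repeat length for the repeat model.
#' @param seed RNG seed.
#' @param repeats Optional precomputed [find_perfect_repeats()] table.
#' @return Tibble: `start`, `end`, `disp_start`, `disp_end`. Pool
#'   `c(disp_start, disp_end)` for the displacement CDF.
#' @export
simulate_excisions <- function(genome, origins,
                               model = c("uniform", "perfect_repeat",
                                         "origin_conditioned"),
                               n_fragments = 1000, length_source = NULL,
                               min_repeat_len = 11, seed = NULL,
                               repeats = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  G <- genome$length[[1]]
  if (model == "perfect_repeat") {
    if (is.null(repeats)) repeats <- find_perfect_repeats(genome, min_repeat_len)
    repeats <- repeats[repeats$length >= min_repeat_len, ]
    if (nrow(repeats) == 0L) abort("no qualifying perfect repeats found")
    idx <- sample.int(nrow(repeats), n_fragments, replace = TRUE)
    start <- repeats$pos1[idx]
    end <- repeats$pos2[idx]
  } else {
    if (is.null(length_source) || !length(length_source)) {
      abort("length_source required for this model")
    }
    len <- sample(length_source, n_fragments, replace = TRUE)
    len <- pmin(len, G - 1)
    if (model == "uniform") {
      start <- floor(runif(n_fragments, 0, G - len + 1))
    } else {
      oi <- sample.int(nrow(origins), n_fragments, replace = TRUE)
      # uniform start among placements overlapping the chosen origin:
      # the exact conditional of rejection-sampling uniform placements
      lo <- pmax(0, origins$start[oi] - len + 1)
      hi <- pmin(G - len, origins$end[oi] - 1)
      bad <- hi < lo
      if (any(bad)) { lo[bad] <- 0; hi[bad] <- G - len[bad] }
      start <- floor(lo + runif(n_fragments) * (hi - lo + 1))
    }
    end <- start + len
  }
  tibble(
    start = as.numeric(start), end = as.numeric(end),
    disp_start = min_origin_displacement(start, origins),
    disp_end = min_origin_displacement(end, origins)
  )
}
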