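# Synthetic data: toy references with planted origins/repeats, and simulated
# long-read alignment records from concatemer structures, including Nanopore
# inverted-duplication artifacts. The generator is the ground truth the test
# suite measures the pipeline against.

#' Describe one concatemer repeat structure to simulate
#'
#' A structure is an ordered list of reference alignments (intervals plus
#' orientation) forming one repeat unit. `tandem` units are repeated
#' verbatim, the rolling-circle product seen in most Petite colonies.
#' `mixed` units model the non-periodic structures in which four alignments
#' sharing a common region appear in varying orientations: the unit list is
#' interpreted as the four alignments, and each simulated period draws one of
#' the two partial units (largest+smallest inverted, or second-largest +
#' second-smallest inverted) that single crossovers interconvert.
#'
#' @param alignments Tibble (or data.frame) with columns `ref_start`,
#'   `ref_end` (0-based half-open) and `strand` (`"+"`/`"-"`).
#' @param frequency Target fraction of total mitochondrial base pairs.
#' @param arrangement `"tandem"` or `"mixed"`.
#' @param name Optional label carried into the ground-truth table.
#' @return A `structure_spec` list.
#' @export
structure_spec <- function(alignments, frequency,
                           arrangement = c("tandem", "mixed"),
                           name = NULL) {
  arrangement <- match.arg(arrangement)
  alignments <- as_tibble(alignments)
  stopifnot(all(c("ref_start", "ref_end", "strand") %in% names(alignments)),
            all(alignments$ref_start < alignments$ref_end),
            all(alignments$strand %in% c("+", "-")),
            frequency >= 0)
  if (arrangement == "mixed") {
    if (nrow(alignments) != 4L) {
      abort("mixed structures need exactly four alignments")
    }
    len <- alignments$ref_end - alignments$ref_start
    ord <- order(len, decreasing = TRUE)
    l <- len[ord]
    if (abs((l[1] + l[4]) - (l[2] + l[3])) > 1e-8) {
      abort(paste("mixed alignments must satisfy the shared-region geometry",
                  "(largest+smallest length == sum of the middle two)"))
    }
  }
  structure(list(alignments = alignments, frequency = frequency,
                 arrangement = arrangement,
                 name = name %||% arrangement),
            class = "structure_spec")
}

#' Shifted-exponential read-length model
#'
#' Read lengths are modelled as `mu + Exponential(beta)`: `mu` is the
#' location (shortest read, in bp) and `beta` the scale. This matches the
#' exponential fit used for the sampling-bias corrections.
#'
#' @param mu Location, bp (>= 0).
#' @param beta Scale, bp (> 0).
#' @return A `read_length_model` list.
#' @export
read_length_model <- function(mu, beta) {
  stopifnot(mu >= 0, beta > 0)
  structure(list(mu = mu, beta = beta), class = "read_length_model")
}

# The two partial units of a mixed structure, each unit a tibble of
# alignments with traversal orientation. Ranks by decreasing length:
# P = (1 '+', 4 '-'), Q = (2 '+', 3 '-').
mixed_units <- function(alignments) {
  len <- alignments$ref_end - alignments$ref_start
  ord <- order(len, decreasing = TRUE)
  a <- alignments[ord, ]
  list(
    dplyr::bind_rows(mutate(a[1, ], strand = "+"),
                     mutate(a[4, ], strand = "-")),
    dplyr::bind_rows(mutate(a[2, ], strand = "+"),
                     mutate(a[3, ], strand = "-"))
  )
}

#' Build a toy reference genome with planted origins and repeats
#'
#' Generates an AT-rich random background (as in yeast mtDNA), places
#' `n_origins` disjoint GC-cluster-rich origin blocks at evenly spaced
#' positions, and plants perfect direct repeats at recorded random loci.
#' Origin blocks alternate GC-rich cluster stretches with AT spacers so
#' every origin contains 10 bp windows above 0.6 GC.
#'
#' @param length Genome length, bp.
#' @param n_origins Number of origin blocks.
#' @param origin_length Length of each origin block, bp.
#' @param repeat_seeds List of `c(length, copies)` pairs; each seed motif is
#'   copied at `copies` random mutually non-overlapping loci anywhere on the
#'   genome (origins included: real mitochondrial origins are themselves
#'   repeat-rich homologous elements).
#' @param seed RNG seed (integer) for reproducibility.
#' @param gc_background Background GC fraction.
#' @return List with `genome` (tibble), `origins` (tibble) and `repeats`
#'   (tibble of planted occurrences: `motif`, `length`, `start`).
#' @export
build_toy_reference <- function(length, n_origins = 2L, origin_length = 1000L,
                                repeat_seeds = list(), seed = NULL,
                                gc_background = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  planted <- n_origins * origin_length +
    sum(vapply(repeat_seeds, function(s) s[1] * s[2], numeric(1)))
  if (planted >= length) abort("planted features exceed genome length")
  p_bg <- c(A = (1 - gc_background) / 2, C = gc_background / 2,
            G = gc_background / 2, T = (1 - gc_background) / 2)
  seq <- sample(names(p_bg), length, replace = TRUE, prob = p_bg)

  occupied <- rep(FALSE, length)
  origins <- tibble(name = character(), start = integer(), end = integer(),
                    strand = character())
  if (n_origins > 0L) {
    centers <- round((seq_len(n_origins) - 0.5) * length / n_origins)
    for (i in seq_len(n_origins)) {
      s <- max(0L, min(length - origin_length, centers[i] - origin_length %/% 2))
      block <- origin_block(origin_length)
      seq[(s + 1L):(s + origin_length)] <- block
      origins <- bind_rows(origins, tibble(
        name = paste0("ori", i), start = as.integer(s),
        end = as.integer(s + origin_length),
        strand = if (i %% 2L == 0L) "-" else "+"
      ))
    }
  }

  repeats <- tibble(motif = character(), length = integer(), start = integer())
  for (sd_pair in repeat_seeds) {
    len_r <- as.integer(sd_pair[1]); copies <- as.integer(sd_pair[2])
    motif <- paste0(sample(c("A", "C", "G", "T"), len_r, replace = TRUE),
                    collapse = "")
    placed <- 0L; tries <- 0L
    while (placed < copies && tries < 10000L) {
      tries <- tries + 1L
      s <- sample.int(length - len_r, 1L) - 1L
      span <- (s + 1L):(s + len_r)
      if (any(occupied[span])) next
      seq[span] <- strsplit(motif, "")[[1]]
      occupied[span] <- TRUE
      repeats <- bind_rows(repeats,
                           tibble(motif = motif, length = len_r,
                                  start = as.integer(s)))
      placed <- placed + 1L
    }
    if (placed < copies) abort("could not place repeat seeds (packing infeasible)")
  }

  list(genome = reference_genome("toy_mt", paste0(seq, collapse = "")),
       origins = origins, repeats = repeats)
}

# GC-cluster-like origin block: 25 bp GC-rich stretches separated by 15 bp
# AT spacers, so sliding 10 bp windows inside clusters exceed 0.6 GC.
origin_block <- function(n) {
  out <- character(0)
  while (sum(nchar(out)) < n) {
    cluster <- paste0(sample(c("G", "C", "A", "T"), 25, replace = TRUE,
                             prob = c(0.425, 0.425, 0.075, 0.075)),
                      collapse = "")
    spacer <- paste0(sample(c("A", "T"), 15, replace = TRUE), collapse = "")
    out <- c(out, cluster, spacer)
  }
  strsplit(substr(paste0(out, collapse = ""), 1L, n), "")[[1]]
}

#' Simulate long-read alignment records from concatemer structures
#'
#' Each read picks one structure with probability proportional to its target
#' base-pair frequency, draws a length from the shifted-exponential model,
#' and samples a uniformly random phase of an arbitrarily long concatemer of
#' that structure. The read is emitted as the ordered alignment segments a
#' mapper would report: one collinear segment per traversed (part of an)
#' alignment, with junction-adjacent reference endpoints optionally jittered
#' by Gaussian noise.
#'
#' With probability `artifact_rate` a read is replaced by its
#' inverted-duplication artifact: the read is extended by a strand-flipped
#' mirror of its own suffix so the spurious inversion sits at a relative
#' position drawn from `Beta(artifact_beta_a, artifact_beta_b)` (draws below
#' 0.5 give a full duplication), the reference edges at the fold are offset
#' by under 1 kbp, and the mirrored half is flagged degraded (reduced mapq).
#'
#' @param specs List of [structure_spec()] objects; frequencies must sum to
#'   a positive value (they are renormalised).
#' @param model [read_length_model()].
#' @param n_reads Number of reads.
#' @param artifact_rate Fraction of reads replaced by artifacts.
#' @param noise Breakpoint jitter SD, bp (0 disables).
#' @param seed RNG seed.
#' @param artifact_beta_a,artifact_beta_b Artifact fold-position Beta
#'   parameters.
#' @param mapq,degraded_mapq Mapping quality assigned to clean and to
#'   mirrored (degraded) segments.
#' @return List with `alignments` (segment tibble as from
#'   [read_alignments()]) and `truth` (per-read tibble: `read_id`,
#'   `structure`, `phase`, `read_length`, `artifact`, `fold_frac`).
#' @export
simulate_reads <- function(specs, model, n_reads, artifact_rate = 0,
                           noise = 0, seed = NULL,
                           artifact_beta_a = 8, artifact_beta_b = 6,
                           mapq = 60L, degraded_mapq = 40L) {
  if (inherits(specs, "structure_spec")) specs <- list(specs)
  stopifnot(n_reads >= 1, artifact_rate >= 0, artifact_rate <= 1)
  freqs <- vapply(specs, function(s) s$frequency, numeric(1))
  if (sum(freqs) <= 0) abort("all structure frequencies are zero")
  freqs <- freqs / sum(freqs)
  if (!is.null(seed)) set.seed(seed)

  spec_idx <- sample.int(length(specs), n_reads, replace = TRUE, prob = freqs)
  lens <- round(model$mu + rexp(n_reads, rate = 1 / model$beta))
  lens <- pmax(lens, 50)
  is_artifact <- runif(n_reads) < artifact_rate

  seg_list <- vector("list", n_reads)
  t_phase <- t_fold <- numeric(n_reads)
  t_struct <- character(n_reads)
  for (i in seq_len(n_reads)) {
    sp <- specs[[spec_idx[i]]]
    rid <- sprintf("read%06d", i)
    walk <- concatemer_walk(sp, lens[i])
    segs <- walk$segments
    if (noise > 0) segs <- jitter_junctions(segs, noise)
    fold_frac <- NA_real_
    if (is_artifact[i]) {
      art <- apply_artifact(segs, lens[i], artifact_beta_a, artifact_beta_b,
                            degraded_mapq)
      segs <- art$segments
      fold_frac <- art$fold_frac
      lens[i] <- art$read_length
    }
    segs$read_id <- rid
    segs$read_length <- lens[i]
    seg_list[[i]] <- segs
    t_phase[i] <- walk$phase; t_fold[i] <- fold_frac
    t_struct[i] <- sp$name
  }
  truth <- tibble(read_id = sprintf("read%06d", seq_len(n_reads)),
                  structure = t_struct, phase = t_phase,
                  read_length = lens, artifact = is_artifact,
                  fold_frac = t_fold)
  segs <- bind_rows(seg_list)
  segs$mapq[is.na(segs$mapq)] <- mapq
  segs <- segs %>%
    mutate(across(c("read_start", "read_end", "ref_start", "ref_end"),
                  ~ as.integer(round(.x))),
           ref_name = "toy_mt", mapq = as.integer(.data$mapq),
           mapq_unavailable = FALSE) %>%
    filter(.data$ref_end > .data$ref_start,
           .data$read_end > .data$read_start) %>%
    select("read_id", "read_length", "read_start", "read_end", "strand",
           "ref_name", "ref_start", "ref_end", "mapq", "mapq_unavailable",
           "degraded") %>%
    arrange(.data$read_id, .data$read_start)
  list(alignments = segs, truth = truth)
}

# Walk a window of `len` bp over an infinite concatemer of the spec at a
# uniformly random phase; returns the emitted segments in read order.
concatemer_walk <- function(sp, len) {
  tandem_unit <- sp$alignments
  units <- if (sp$arrangement == "mixed") mixed_units(sp$alignments) else NULL
  draw_unit <- function() {
    if (is.null(units)) tandem_unit else units[[sample.int(2L, 1L)]]
  }
  unit <- draw_unit()
  unit_lens <- unit$ref_end - unit$ref_start
  period <- sum(unit_lens)
  phase <- runif(1, 0, period)

  v_rs <- v_re <- v_fs <- v_fe <- numeric(0)
  v_st <- character(0)
  rc <- 0            # read coordinate consumed so far
  pos <- phase       # position within current unit
  ai <- 1L
  while (pos >= unit_lens[ai]) { pos <- pos - unit_lens[ai]; ai <- ai + 1L }
  while (rc < len) {
    a_len <- unit_lens[ai]
    take <- min(a_len - pos, len - rc)
    s <- unit$ref_start[ai]; e <- unit$ref_end[ai]
    if (unit$strand[ai] == "+") {
      ref_s <- s + pos; ref_e <- s + pos + take
    } else {
      ref_s <- e - pos - take; ref_e <- e - pos
    }
    v_rs <- c(v_rs, rc); v_re <- c(v_re, rc + take)
    v_fs <- c(v_fs, ref_s); v_fe <- c(v_fe, ref_e)
    v_st <- c(v_st, unit$strand[ai])
    rc <- rc + take
    pos <- pos + take
    if (pos >= a_len) {
      pos <- 0
      ai <- ai + 1L
      if (ai > nrow(unit)) {
        unit <- draw_unit()
        unit_lens <- unit$ref_end - unit$ref_start
        ai <- 1L
      }
    }
  }
  list(segments = tibble(read_start = v_rs, read_end = v_re, strand = v_st,
                         ref_start = v_fs, ref_end = v_fe,
                         mapq = NA_real_, degraded = FALSE),
       phase = phase)
}

# Jitter junction-facing reference endpoints (not read-terminal endpoints)
# by symmetric Gaussian noise, emulating mapper imprecision at alignment
# termini; shifts are truncated to half the segment length so segments keep
# positive length and stay within one unit.
jitter_junctions <- function(segs, noise) {
  n <- nrow(segs)
  if (n == 0L) return(segs)
  for (i in seq_len(n)) {
    len_i <- segs$ref_end[i] - segs$ref_start[i]
    cap <- max(0, len_i / 2 - 1)
    jig <- function() max(-cap, min(cap, rnorm(1, 0, noise)))
    left_is_junction <- i > 1L
    right_is_junction <- i < n
    # read-forward left/right map to ref ends depending on strand
    if (segs$strand[i] == "+") {
      if (left_is_junction) segs$ref_start[i] <- segs$ref_start[i] + jig()
      if (right_is_junction) segs$ref_end[i] <- segs$ref_end[i] + jig()
    } else {
      if (left_is_junction) segs$ref_end[i] <- segs$ref_end[i] + jig()
      if (right_is_junction) segs$ref_start[i] <- segs$ref_start[i] + jig()
    }
  }
  segs
}

# Replace a read by its inverted-duplication artifact: append a
# strand-flipped mirror of the read suffix of length m = x(1-p)/p, p drawn
# from the fold-position Beta (clamped to >= 0.5), with a small reference
# offset at the fold and degraded mapq in the mirrored half.
apply_artifact <- function(segs, x, beta_a, beta_b, degraded_mapq) {
  p <- max(rbeta(1, beta_a, beta_b), 0.5)
  m <- min(round(x * (1 - p) / p), x)
  m <- max(m, 50)
  cut <- x - m
  mirror <- segs[segs$read_end > cut, ]
  clip_left <- pmax(cut - mirror$read_start, 0)
  mirror$read_start <- mirror$read_start + clip_left
  keep <- mirror$read_end > mirror$read_start
  mirror <- mirror[keep, ]
  clip_left <- clip_left[keep]
  plus <- mirror$strand == "+"
  mirror$ref_start[plus] <- mirror$ref_start[plus] + clip_left[plus]
  mirror$ref_end[!plus] <- mirror$ref_end[!plus] - clip_left[!plus]

  # degraded second half: each mirrored segment is displaced in reference
  # coordinates by its own small offset (length-preserving, clamped below
  # 1 kbp), so the adjacent edges at the fold end up separated by a small
  # (< 1 kbp) gap and every mirrored junction is slightly off its template
  mirrored <- mirror
  mirrored$strand <- ifelse(mirror$strand == "+", "-", "+")
  rs <- 2 * x - mirror$read_end
  re <- 2 * x - mirror$read_start
  mirrored$read_start <- rs
  mirrored$read_end <- re
  n_m <- nrow(mirrored)
  offset <- pmax(pmin(rnorm(n_m, 0, 250), 999), -999)
  offset <- pmax(offset, -mirror$ref_start)   # stay on the reference
  mirrored$ref_start <- mirror$ref_start + offset
  mirrored$ref_end <- mirror$ref_end + offset
  mirrored$mapq <- degraded_mapq
  mirrored$degraded <- TRUE
  mirrored <- mirrored[order(mirrored$read_start), ]

  out <- bind_rows(segs, mirrored)
  list(segments = out, fold_frac = x / (x + m), read_length = x + m)
}
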