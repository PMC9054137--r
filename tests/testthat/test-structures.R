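# Helpers to build encoded-read rows by hand.
enc_row <- function(clusters, transitions, pairs, segments = NULL) {
  tibble(
    read_id = "r1", read_length = 10000, n_signals = length(clusters),
    labels = list(clusters),
    numeric_enc = list(paste0(clusters, transitions)),
    orient_enc = list(paste0(clusters, pairs)),
    read_positions = list(seq(1000, by = 1000, length.out = length(clusters))),
    segments = list(segments),
    end_refs = list(c(0, 0))
  )
}

test_that("tandem repeat detection finds the shortest repeating unit", {
  segs <- tibble(ref_start = rep(2000, 4), ref_end = rep(8000, 4),
                 strand = "+", interior = c(FALSE, TRUE, TRUE, FALSE))
  r <- enc_row(c(2, 2, 2), rep("LH", 3), rep("++", 3), segs)
  u <- detect_tandem_repeats(r)
  expect_equal(u$unit[[1]], "2LH")
  expect_equal(u$n_periods, 3)
  expect_equal(u$period_bp, 6000)
  # period-2 unit
  r2 <- enc_row(c(2, 3, 2, 3), c("LH", "HL", "LH", "HL"),
                c("++", "++", "++", "++"),
                tibble(ref_start = c(0, 1000, 4000, 1000, 4000),
                       ref_end = c(900, 3000, 9000, 3000, 9000),
                       strand = "+",
                       interior = c(FALSE, TRUE, TRUE, TRUE, FALSE)))
  u2 <- detect_tandem_repeats(r2)
  expect_equal(length(u2$unit[[1]]), 2L)
  expect_equal(u2$n_periods, 2)
  # 1.5 periods is below the tandem minimum
  r3 <- enc_row(c(2, 3, 2), c("LH", "HL", "LH"), c("++", "++", "++"))
  expect_null(detect_tandem_repeats(r3))
  # both encodings must repeat: orientation flip breaks the period
  r4 <- enc_row(c(2, 2, 2), rep("LH", 3), c("++", "--", "++"), segs)
  expect_null(detect_tandem_repeats(r4))
})

test_that("tandem detection is rotation-invariant", {
  spec <- structure_spec(tibble(ref_start = c(1000, 6000),
                                ref_end = c(4000, 10000),
                                strand = c("+", "+")), frequency = 1)
  sim <- simulate_reads(spec, read_length_model(16000, 8000), 40, seed = 6)
  aln <- filter_alignments(sim$alignments)
  bp <- extract_breakpoints(aln)
  cl <- cluster_all_breakpoints(bp)
  enc <- encode_reads(cl$breakpoints, aln)
  units <- purrr::map_chr(seq_len(nrow(enc)), function(i) {
    u <- detect_tandem_repeats(enc[i, ])
    if (is.null(u)) NA_character_ else paste(u$unit[[1]], collapse = "|")
  })
  units <- units[!is.na(units)]
  expect_gt(length(units), 10)
  expect_equal(length(unique(units)), 1L)  # same canonical unit, any phase
})

test_that("partial repeats capture the mixed-structure pattern", {
  # A, B', A with matching A copies
  segs <- tibble(ref_start = c(2000, 5000, 2000),
                 ref_end = c(4500, 6500, 4500),
                 strand = c("+", "-", "+"),
                 interior = c(TRUE, TRUE, TRUE))
  r <- enc_row(c(1, 2), c("LH", "HL"), c("+-", "-+"), segs)
  u <- detect_partial_repeats(r)
  expect_equal(u$role, "mixed-partial")
  expect_equal(u$n_periods, 1.5)
  expect_equal(nrow(u$alignments[[1]]), 2L)
  # A, B, A all same orientation: the tandem detector's case, not ours
  segs2 <- mutate(segs, strand = "+")
  r2 <- enc_row(c(1, 2), c("LH", "HL"), c("++", "++"), segs2)
  expect_null(detect_partial_repeats(r2))
  # A, B', C: no repetition
  segs3 <- tibble(ref_start = c(2000, 5000, 8000),
                  ref_end = c(4500, 6500, 9500),
                  strand = c("+", "-", "+"),
                  interior = TRUE)
  r3 <- enc_row(c(1, 2), c("LH", "HL"), c("+-", "-+"), segs3)
  expect_null(detect_partial_repeats(r3))
})

test_that("transition matrix counts adjacent label pairs", {
  enc <- bind_rows(
    enc_row(c(2, 3, 2, 3), rep("LH", 4), rep("++", 4)),
    enc_row(c(5), "LH", "++")
  )
  T_ <- build_transition_matrix(enc)
  expect_equal(T_["2", "3"], 2L)
  expect_equal(T_["3", "2"], 1L)
  expect_equal(sum(T_), 3L)
  # no multi-signal reads: zero matrix
  T0 <- build_transition_matrix(enc_row(c(7), "LH", "++"))
  expect_equal(sum(T0), 0L)
})

test_that("transition matrix is balanced for periodic sampling", {
  spec <- structure_spec(tibble(ref_start = c(1000, 6000),
                                ref_end = c(4000, 10000),
                                strand = c("+", "+")), frequency = 1)
  sim <- simulate_reads(spec, default_model(), 800, seed = 61)
  aln <- filter_alignments(sim$alignments)
  cl <- cluster_all_breakpoints(extract_breakpoints(aln))
  T_ <- build_transition_matrix(encode_reads(cl$breakpoints, aln))
  offdiag <- c(T_[1, 2], T_[2, 1])
  expect_gt(min(offdiag), 0)
  expect_lt(abs(offdiag[1] - offdiag[2]), 3 * sqrt(sum(offdiag)))
})

test_that("transition merging follows the fractional-difference criterion", {
  T_ <- matrix(0, 2, 2, dimnames = list(c("2", "3"), c("2", "3")))
  T_["2", "3"] <- 100; T_["3", "2"] <- 120
  m <- merge_transitions(T_)
  # 100 vs 120: max |c - 110| / 110 = 0.0909 < 0.34 -> merged, valid repeat
  expect_equal(nrow(m), 1L)
  expect_equal(m$count, 110)
  expect_true(m$is_repeat)
  expect_setequal(m$clusters[[1]], c(2L, 3L))

  T2 <- T_; T2["3", "2"] <- 300
  m2 <- merge_transitions(T2)
  # 100 vs 300: fractional difference 0.5 >= 0.34 -> kept apart
  expect_equal(nrow(m2), 2L)
  # singleton i->j lists have 2 breakpoints but 1 transition: not repeats
  expect_false(any(m2$is_repeat))

  # transitions with no shared breakpoint never merge
  T3 <- matrix(0, 4, 4, dimnames = list(as.character(1:4), as.character(1:4)))
  T3["1", "2"] <- 100; T3["3", "4"] <- 100
  m3 <- merge_transitions(T3)
  expect_equal(nrow(m3), 2L)
})

test_that("primary selection prefers span, then support, then position", {
  st <- tibble(
    structure_id = 1:2, role = NA_character_,
    clusters = list(1L, 2L),
    alignments = list(tibble(ref_start = 0, ref_end = 30000, strand = "+"),
                      tibble(ref_start = 40000, ref_end = 45000, strand = "+")),
    period_bp = c(30000, 5000), span_bp = c(30000, 5000),
    count = c(10, 500), n_reads = c(10L, 500L)
  )
  expect_equal(select_primary(st)$structure_id, 1L)  # span dominates count
  st$span_bp <- c(10000, 10000)
  expect_equal(select_primary(st)$structure_id, 2L)  # tie -> higher support
  expect_null(select_primary(st[0, ]))
  expect_equal(select_primary(st[1, ])$structure_id, 1L)
})

test_that("excision classes follow shared-edge counting", {
  clusters <- tibble(
    cluster_id = 1:4, kind = "noninverted",
    n_signals = 10L, n_reads = 10L,
    centroid_a = c(2000, 9000, 3500, 2000),
    centroid_b = c(32000, 15000, 30500, 8000),
    sd_a = c(5, 5, 5, 5), sd_b = c(5, 5, 5, 5)
  )
  mk_st <- function(id, cl, aln) {
    tibble(structure_id = id, role = "alternate", clusters = list(cl),
           alignments = list(aln), span_bp = max(aln$ref_end) - min(aln$ref_start),
           period_bp = sum(aln$ref_end - aln$ref_start), count = 10,
           n_reads = 10L)
  }
  primary <- mk_st(1L, 1L, tibble(ref_start = 2000, ref_end = 32000, strand = "+"))
  type1 <- mk_st(2L, 2L, tibble(ref_start = 9000, ref_end = 15000, strand = "+"))
  type2 <- mk_st(3L, c(1L, 3L), tibble(ref_start = c(30500, 2000),
                                       ref_end = c(32000, 3500), strand = "+"))
  type3 <- mk_st(4L, 4L, tibble(ref_start = 2000, ref_end = 8000, strand = "+"))
  expect_equal(classify_excision(type1, primary, clusters), "I")
  expect_equal(classify_excision(type2, primary, clusters), "II")
  expect_equal(classify_excision(type3, primary, clusters), "III")
  # a two-alignment structure sharing one edge fits no class
  odd <- mk_st(5L, 4L, tibble(ref_start = c(2000, 9000),
                              ref_end = c(3000, 15000), strand = "+"))
  expect_warning(cls <- classify_excision(odd, primary, clusters),
                 "no excision class")
  expect_equal(cls, "unclassified")
})

test_that("edge distances are normalised by primary alignment length", {
  clusters <- tibble(cluster_id = 1:3, kind = "noninverted", n_signals = 5L,
                     n_reads = 5L,
                     centroid_a = c(2000, 2000, 17000),
                     centroid_b = c(32000, 8000, 20000),
                     sd_a = 0, sd_b = 0)
  st <- tibble(
    structure_id = 1:3,
    role = c("primary", "alternate", "alternate"),
    excision_class = c(NA, "III", "I"),
    clusters = list(1L, 2L, 3L),
    alignments = list(tibble(ref_start = 2000, ref_end = 32000, strand = "+"),
                      tibble(ref_start = 2000, ref_end = 8000, strand = "+"),
                      tibble(ref_start = 17000, ref_end = 20000, strand = "+")),
    period_bp = c(30000, 6000, 3000), span_bp = c(30000, 6000, 3000),
    count = 1, n_reads = 1L
  )
  ed <- edge_distance_stats(st, clusters)
  d3 <- ed$fractional_distance[ed$structure_id == 2]
  expect_equal(sort(d3), c(0, 6000 / 30000))      # shared edge and 8000
  d1 <- ed$fractional_distance[ed$structure_id == 3]
  expect_equal(sort(d1), c(12000, 15000) / 30000) # interior edges
  summ <- edge_distance_stats(st, clusters, summarise = TRUE)
  expect_equal(nrow(summ), 2L)
})
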