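test_that("read-length fit is the shifted-exponential MLE", {
  lens <- c(rep(1000, 5), rep(4000, 5))
  fit <- fit_read_lengths(lens)
  expect_equal(fit$mu, 1000)
  expect_equal(fit$beta, 1500)
  # location equivariance
  fit2 <- fit_read_lengths(lens + 700)
  expect_equal(fit2$mu, 1700)
  expect_equal(fit2$beta, 1500)
  # MLE consistency at n = 1e4
  set.seed(8)
  x <- 5000 + rexp(10000, 1 / 3000)
  fit3 <- fit_read_lengths(x)
  expect_lt(abs(fit3$beta - 3000), 3 * 3000 / sqrt(10000))
  expect_lt(abs(fit3$mu - 5000), 10)
  # degenerate input
  expect_warning(fd <- fit_read_lengths(rep(2000, 12)), "degenerate")
  expect_gt(fd$beta, 0)
  expect_error(fit_read_lengths(1:5), "at least 10")
})

test_that("mixed visibility matches its closed form", {
  fit <- read_length_model(1000, 5000)
  # four equal lengths at L = mu: (1 - 1/4) * e^0
  expect_equal(mixed_visibility(1000, rep(1000, 4), fit), 0.75)
  # direct evaluation: L = 6000, sum = 20000 -> 0.7 * e^-1
  expect_equal(mixed_visibility(6000, c(6000, 6000, 6000, 2000), fit),
               0.7 * exp(-1), tolerance = 1e-12)
  # below mu the exponential clamps at 1
  expect_equal(mixed_visibility(500, c(500, 500, 500, 500), fit), 0.75)
})

test_that("mixed frequencies normalise bias-corrected counts", {
  fit <- read_length_model(1000, 5000)
  eq <- mixed_frequencies(rep(10, 4), rep(2000, 4), fit)
  expect_equal(eq$frequency, rep(0.25, 4))
  expect_equal(sum(eq$frequency), 1)
  zero <- mixed_frequencies(c(0, 10, 10, 10), rep(2000, 4), fit)
  expect_equal(zero$frequency[1], 0)
  expect_error(mixed_frequencies(c(0, 0), c(1, 1), fit))
})

test_that("bias correction is necessary and sufficient on mixed reads", {
  spec <- structure_spec(mixed_alignments(), frequency = 1,
                         arrangement = "mixed")
  sim <- simulate_reads(spec, read_length_model(1000, 2500), 4000, seed = 11)
  aln <- filter_alignments(sim$alignments)
  cnt <- count_mixed_alignments(aln, mixed_alignments())
  fit <- fit_read_lengths(dplyr::distinct(aln, read_id, read_length)$read_length)
  freq <- mixed_frequencies(cnt$count, cnt$length, fit)
  se3 <- 3 * sqrt(0.25 * 0.75 / sum(cnt$count))
  expect_lt(max(abs(freq$frequency - 0.25)), se3)        # corrected: equal
  expect_gt(max(abs(freq$raw_frequency - 0.25)), se3)    # raw: biased
})

test_that("structure visibility matches numerical integration", {
  fit <- read_length_model(1000, 5000)
  # boundary: Lk = mu = u -> term2 vanishes, Q = 1
  expect_equal(structure_visibility(1000, fit, u = 1000), 1)
  # closed form vs quadrature
  for (Lk in c(2000, 6000, 20000, 60000)) {
    f <- function(x) exp(-(x - 1000) / 5000) / 5000
    num <- stats::integrate(f, Lk, Inf, rel.tol = 1e-12)$value +
      stats::integrate(function(x) x / Lk * f(x), 1000, Lk,
                       rel.tol = 1e-12)$value
    expect_lt(abs(structure_visibility(Lk, fit) - num) / num, 1e-6)
  }
  # u above Lk drops the second term
  expect_equal(structure_visibility(2000, fit, u = 3000),
               exp(-1000 / 5000))
  # monotone decreasing in Lk beyond mu
  Ls <- seq(1000, 50000, by = 500)
  Qs <- vapply(Ls, structure_visibility, numeric(1), fit = fit)
  expect_true(all(diff(Qs) < 0))
  # continuous at L = mu
  expect_lt(abs(structure_visibility(1000 + 1e-6, fit) -
                  structure_visibility(1000 - 1e-6, fit)), 1e-5)
})

test_that("reads are assigned by label overlap under footprint containment", {
  structures <- tibble(
    structure_id = 1:2, role = c("alternate", "primary"),
    clusters = list(2L, c(2L, 5L)),
    alignments = list(tibble(ref_start = 1000, ref_end = 9000, strand = "+"),
                      tibble(ref_start = 1000, ref_end = 20000, strand = "+")),
    period_bp = c(8000, 19000), span_bp = c(8000, 19000),
    count = c(5, 50), n_reads = c(5L, 50L)
  )
  enc <- tibble(
    read_id = c("tie", "alien", "outside"),
    read_length = 5000, n_signals = c(3L, 1L, 1L),
    labels = list(c(2L, 2L, 2L), 7L, 2L),
    numeric_enc = list(c("2LH", "2LH", "2LH"), "7LH", "2LH"),
    orient_enc = list(c("2++", "2++", "2++"), "7++", "2++"),
    read_positions = list(c(1, 2, 3), 1, 1),
    segments = list(tibble(ref_start = 2000, ref_end = 8000, strand = "+",
                           interior = FALSE),
                    tibble(ref_start = 2000, ref_end = 8000, strand = "+",
                           interior = FALSE),
                    tibble(ref_start = 25000, ref_end = 30000, strand = "+",
                           interior = FALSE)),
    end_refs = list(c(2000, 8000), c(2000, 8000), c(25000, 30000))
  )
  asg <- assign_reads_to_structures(enc, structures)
  # equal overlap on one label type: tie -> larger span wins
  expect_equal(asg$structure_id[asg$read_id == "tie"], 2L)
  # label absent from all structures -> unassigned
  expect_true(is.na(asg$structure_id[asg$read_id == "alien"]))
  # content outside every footprint -> unassigned despite label overlap
  expect_true(is.na(asg$structure_id[asg$read_id == "outside"]))
})

test_that("structure frequencies recover generator proportions", {
  specs <- list(
    structure_spec(tibble(ref_start = 2000, ref_end = 32000, strand = "+"),
                   frequency = 0.95, name = "primary"),
    structure_spec(tibble(ref_start = 9000, ref_end = 15000, strand = "+"),
                   frequency = 0.05, name = "alt")
  )
  sim <- simulate_reads(specs, default_model(), 3000, seed = 19)
  res <- run_structure_pipeline(sim$alignments)
  expect_equal(nrow(res$frequencies), 2L)
  f <- res$frequencies
  expect_equal(sum(f$frequency), 1)
  prim <- f$frequency[f$role == "primary"]
  expect_lt(abs(prim - 0.95), 3 * sqrt(0.95 * 0.05 / 3000) + 0.01)
  # a single structure gets frequency one
  one <- structure_frequencies(
    tibble(read_id = "r1", structure_id = 1L),
    tibble(read_id = "r1", read_length = 5000, n_signals = 1L,
           labels = list(1L), numeric_enc = list("1LH"),
           orient_enc = list("1++"), read_positions = list(1),
           segments = list(tibble(ref_start = 0, ref_end = 100,
                                  strand = "+", interior = FALSE)),
           end_refs = list(c(0, 100))),
    tibble(structure_id = 1L, role = "primary", clusters = list(1L),
           alignments = list(tibble(ref_start = 0, ref_end = 5000,
                                    strand = "+")),
           period_bp = 5000, span_bp = 5000, count = 1, n_reads = 1L),
    read_length_model(1000, 5000))
  expect_equal(one$frequency, 1)
})

test_that("alternate bp fraction counts qualifying reads", {
  primary <- tibble(structure_id = 1L, role = "primary", clusters = list(1L),
                    alignments = list(tibble(ref_start = 0, ref_end = 30000,
                                             strand = "+")),
                    period_bp = 30000, span_bp = 30000, count = 1,
                    n_reads = 1L)
  clusters <- tibble(cluster_id = 1L, kind = "noninverted", n_signals = 5L,
                     n_reads = 5L, centroid_a = 0, centroid_b = 30000,
                     sd_a = 0, sd_b = 0)
  aln <- tibble(read_id = sprintf("r%d", 1:10), read_length = 1000L,
                read_start = 0L, read_end = 1000L, strand = "+",
                ref_name = "m", ref_start = 0L, ref_end = 1000L,
                mapq = 60L, mapq_unavailable = FALSE)
  # two of ten equal-length reads carry an internal non-primary breakpoint
  bp <- make_signals(c("r1", "r2"), "noninverted",
                     edge_a = c(10000, 12000), edge_b = c(15000, 20000))
  expect_equal(alternate_bp_fraction(bp, aln, primary, clusters), 0.2)
  # no non-primary breakpoints -> 0
  bp0 <- make_signals("r1", "noninverted", 0, 30000)
  expect_equal(alternate_bp_fraction(bp0, aln, primary, clusters), 0)
  # all reads qualify -> 1
  bp1 <- make_signals(sprintf("r%d", 1:10), "noninverted",
                      edge_a = rep(10000, 10), edge_b = rep(15000, 10))
  expect_equal(alternate_bp_fraction(bp1, aln, primary, clusters), 1)
  # artifact-flagged reads are excluded from the numerator
  expect_equal(alternate_bp_fraction(bp, aln, primary, clusters,
                                     artifact_read_ids = "r1"), 0.1)
  expect_error(alternate_bp_fraction(bp, aln[0, ], primary, clusters),
               "base pairs")
})
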