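# Inverted-duplication artifact filtering. Nanopore chemistry frequently
# re-reads the complementary strand of a template, producing a read followed
# by a (degraded) strand-flipped mirror of its own suffix: a spurious,
# near-central inversion whose two reference edges sit close together.

#' Flag inverted signals consistent with the artifact position model
#'
#' A signal is an artifact *candidate* when (a) its within-read position is
#' plausibly drawn from the artifact fold-position distribution -- by
#' default, its two-sided tail probability under `Beta(beta_a, beta_b)`
#' exceeds `likelihood_threshold` -- and (b) the distance between its two
#' reference edges is below `max_fold_gap` (90% of real artifacts fall under
#' 1 kbp). Non-inverted signals are never candidates.
#'
#' @param breakpoints Breakpoint tibble ([extract_breakpoints()]).
#' @param beta_a,beta_b Artifact fold-position Beta parameters (defaults 8,
#'   6: nearly centered, skewed late).
#' @param likelihood_threshold Positional plausibility threshold (default
#'   0.01).
#' @param max_fold_gap Maximum reference-edge distance, bp (default 1000).
#' @param position_test `"tail"` (two-sided tail probability, default) or
#'   `"density"` (Beta density above the threshold).
#' @return Input with an added logical `artifact_candidate` column.
#' @export
flag_artifact_candidates <- function(breakpoints, beta_a = 8, beta_b = 6,
                                     likelihood_threshold = 0.01,
                                     max_fold_gap = 1000,
                                     position_test = c("tail", "density")) {
  position_test <- match.arg(position_test)
  x <- breakpoints$read_pos_fraction
  plausible <- if (position_test == "tail") {
    2 * pmin(pbeta(x, beta_a, beta_b), 1 - pbeta(x, beta_a, beta_b)) >
      likelihood_threshold
  } else {
    stats::dbeta(x, beta_a, beta_b) > likelihood_threshold
  }
  breakpoints %>%
    mutate(artifact_candidate = .data$kind == "inverted" & plausible &
             abs(.data$ref_edge_a - .data$ref_edge_b) < max_fold_gap)
}

#' Resolve artifact candidates into final artifact calls
#'
#' A candidate is called an artifact when it is the *only*
#' artifact-consistent inverted signal in its read: genuine inverted
#' junctions in concatemers recur within reads (or fail the positional /
#' fold-gap criteria), whereas the strand-switch fold happens once. Called
#' artifacts are removed from downstream clustering, but the read and its
#' fold position are kept for the majority-voting cluster filter, which
#' exploits the fact that the mirrored half duplicates every real junction
#' it covers.
#'
#' @param breakpoints Output of [flag_artifact_candidates()].
#' @param count What to count per read when testing "only one signal":
#'   `"candidates"` (artifact-consistent inverted signals, default) or
#'   `"all_inverted"` (every inverted signal).
#' @return List with `breakpoints` (non-artifact signals, `artifact` column
#'   all `FALSE`), `artifacts` (the removed signals) and `folds` (per-read
#'   fold bookkeeping: `read_id`, `fold_read_pos`, `read_length`).
#' @export
resolve_artifacts <- function(breakpoints,
                              count = c("candidates", "all_inverted")) {
  count <- match.arg(count)
  if (!"artifact_candidate" %in% names(breakpoints)) {
    abort("run flag_artifact_candidates() first")
  }
  counted <- if (count == "candidates") {
    breakpoints$artifact_candidate
  } else {
    breakpoints$kind == "inverted"
  }
  per_read <- tapply(counted, breakpoints$read_id, sum)
  n_counted <- as.vector(per_read[breakpoints$read_id])
  is_artifact <- breakpoints$artifact_candidate & n_counted == 1L
  artifacts <- breakpoints[is_artifact, ]
  keep <- breakpoints[!is_artifact, ]
  keep$artifact <- FALSE
  folds <- artifacts %>%
    transmute(read_id = .data$read_id, fold_read_pos = .data$read_pos,
              read_length = .data$read_length)
  list(breakpoints = keep, artifacts = artifacts, folds = folds)
}
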