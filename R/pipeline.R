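# End-to-end driver: alignment records in, structures and frequencies out.

#' Run the full structural-inference pipeline on one sample
#'
#' Chains the whole analysis: alignment filtering, breakpoint extraction,
#' inverted-duplication artifact removal, breakpoint clustering with
#' read-support/vote filtering, repeat-structure reconstruction, and
#' read-length-bias-corrected structure frequencies.
#'
#' @param alignments Alignment tibble ([read_alignments()] or
#'   [simulate_reads()]`$alignments`).
#' @param min_mapq,min_len Alignment filter gates ([filter_alignments()]).
#' @param deviation_bp Breakpoint deviation threshold
#'   ([extract_breakpoints()]).
#' @param artifact_beta_a,artifact_beta_b,artifact_likelihood,artifact_max_gap
#'   Artifact model parameters ([flag_artifact_candidates()]).
#' @param min_pts,eps_noninv,min_read_support Clustering parameters
#'   ([cluster_all_breakpoints()]).
#' @param merge_threshold Transition merging threshold
#'   ([merge_transitions()]).
#' @param freq_lower_bound Lower integration bound `u` for
#'   [structure_visibility()] (default: fitted `mu`).
#' @return List: `alignments` (filtered), `breakpoints` (clustered
#'   signals), `clusters`, `folds`, `structures`, `frequencies`,
#'   `read_length_fit`, `assignments`.
#' @export
run_structure_pipeline <- function(alignments,
                                   min_mapq = 20, min_len = 300,
                                   deviation_bp = 30,
                                   artifact_beta_a = 8, artifact_beta_b = 6,
                                   artifact_likelihood = 0.01,
                                   artifact_max_gap = 1000,
                                   min_pts = 3, eps_noninv = 1000,
                                   min_read_support = 3,
                                   merge_threshold = 0.34,
                                   freq_lower_bound = NULL) {
  aln <- filter_alignments(alignments, min_mapq = min_mapq,
                           min_len = min_len)
  bp <- extract_breakpoints(aln, deviation_bp = deviation_bp)
  bp <- flag_artifact_candidates(bp, beta_a = artifact_beta_a,
                                 beta_b = artifact_beta_b,
                                 likelihood_threshold = artifact_likelihood,
                                 max_fold_gap = artifact_max_gap)
  res <- resolve_artifacts(bp)
  clustered <- cluster_all_breakpoints(res$breakpoints, folds = res$folds,
                                       min_pts = min_pts,
                                       eps_noninv = eps_noninv,
                                       min_read_support = min_read_support)
  structures <- reconstruct_structures(clustered$breakpoints,
                                       clustered$clusters, aln,
                                       folds = res$folds,
                                       merge_threshold = merge_threshold)
  read_lengths <- aln %>% distinct(.data$read_id, .data$read_length)
  fit <- NULL; freqs <- NULL; assignments <- NULL
  if (nrow(read_lengths) >= 10L && nrow(structures) > 0L) {
    fit <- fit_read_lengths(read_lengths$read_length)
    enc <- encode_reads(clustered$breakpoints, aln, folds = res$folds)
    assignments <- assign_reads_to_structures(enc, structures)
    freqs <- structure_frequencies(assignments, enc, structures, fit,
                                   u = freq_lower_bound)
  }
  list(alignments = aln, breakpoints = clustered$breakpoints,
       clusters = clustered$clusters, folds = res$folds,
       structures = structures, frequencies = freqs,
       read_length_fit = fit, assignments = assignments)
}
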