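# ggplot2 views of the main result types.

#' Plot breakpoint clusters on the reference plane
#'
#' Scatter of cluster centroids in the (low edge, high edge) reference
#' plane -- each marker one inferred junction -- sized by read support and
#' shaped by kind.
#'
#' @param clusters Cluster tibble ([cluster_breakpoints()] or
#'   [cluster_all_breakpoints()]).
#' @param retained_only Show only vote-retained clusters (default TRUE when
#'   the column is present).
#' @return A ggplot object.
#' @export
plot_breakpoint_clusters <- function(clusters, retained_only = TRUE) {
  if (retained_only && "retained" %in% names(clusters)) {
    clusters <- filter(clusters, .data$retained)
  }
  ggplot2::ggplot(clusters,
                  ggplot2::aes(x = .data$centroid_a, y = .data$centroid_b,
                               size = .data$n_reads, shape = .data$kind)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "reference position, low edge (bp)",
                  y = "reference position, high edge (bp)",
                  size = "reads", shape = "kind")
}

#' Plot reconstructed structures along the reference
#'
#' One horizontal segment per alignment, one row per structure, coloured by
#' role (primary/alternate) and annotated with the excision class.
#'
#' @param structures Structure tibble ([reconstruct_structures()]).
#' @return A ggplot object.
#' @export
plot_structures <- function(structures) {
  df <- structures %>%
    mutate(label = ifelse(is.na(.data$excision_class), .data$role,
                          paste0(.data$role, " (", .data$excision_class, ")"))) %>%
    tidyr::unnest("alignments")
  ggplot2::ggplot(df, ggplot2::aes(y = factor(.data$structure_id))) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ref_start, xend = .data$ref_end,
                   yend = factor(.data$structure_id),
                   colour = .data$label),
      linewidth = 3
    ) +
    ggplot2::labs(x = "reference position (bp)", y = "structure",
                  colour = NULL)
}

#' Plot breakpoint-to-origin displacement CDFs
#'
#' Empirical cumulative distributions of edge displacements for one or more
#' excision models or observed data sets.
#'
#' @param displacements Named list of numeric displacement vectors.
#' @return A ggplot object.
#' @export
plot_displacement_cdf <- function(displacements) {
  df <- purrr::imap_dfr(displacements, function(d, nm) {
    tibble(model = nm, displacement = sort(d),
           F = seq_along(d) / length(d))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement, y = .data$F,
                                   colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "displacement to nearest origin (bp)",
                  y = "cumulative fraction of breakpoint edges",
                  colour = NULL)
}

#' Plot the read-length fit
#'
#' Histogram of read lengths with the fitted shifted-exponential density.
#'
#' @param read_lengths Numeric vector.
#' @param fit [fit_read_lengths()] result (refitted when `NULL`).
#' @return A ggplot object.
#' @export
plot_read_length_fit <- function(read_lengths, fit = NULL) {
  fit <- fit %||% fit_read_lengths(read_lengths)
  grid <- seq(fit$mu, max(read_lengths), length.out = 200)
  dens <- tibble(x = grid,
                 y = exp(-(grid - fit$mu) / fit$beta) / fit$beta)
  ggplot2::ggplot(tibble(x = read_lengths), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70") +
    ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$y),
                       colour = "firebrick") +
    ggplot2::labs(x = "read length (bp)", y = "density")
}
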