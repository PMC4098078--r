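#' Heatmap of a connectivity matrix
#'
#' @param z Seeds x seeds Fisher-Z matrix (e.g. from
#'   [connectivity_matrix()]).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_connectivity_matrix <- function(z, title = NULL) {
  check_matrix_na_ok(z)
  seeds <- rownames(z) %||% paste0("seed", seq_len(nrow(z)))
  df <- tidyr::expand_grid(a = factor(seeds, seeds), b = factor(seeds, seeds))
  df$z <- as.vector(t(z))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::scale_y_discrete(limits = rev(seeds)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Fisher Z", title = title) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

check_matrix_na_ok <- function(z) {
  if (!is.matrix(z) || !is.numeric(z) || nrow(z) != ncol(z)) {
    stop_restfc("Expected a square numeric matrix.")
  }
  invisible(z)
}

#' Plot behavior-connectivity correlations
#'
#' Spearman rho per edge and score, highlighting flagged pairs.
#'
#' @param behavior Tibble from [spearman_edge_behavior()] or the `behavior`
#'   element of [run_pipeline()] (optionally with `scope`/`score` columns).
#' @return A ggplot object.
#' @export
plot_behavior_correlations <- function(behavior) {
  df <- tibble::as_tibble(behavior)
  if (!all(c("edge", "rho", "flagged") %in% names(df))) {
    stop_restfc("`behavior` needs columns edge, rho, flagged.")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$edge,
                                        colour = .data$flagged)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Spearman rho", y = NULL, colour = "flagged") +
    ggplot2::theme_minimal(base_size = 9)
  if (all(c("scope", "score") %in% names(df))) {
    p <- p + ggplot2::facet_grid(ggplot2::vars(.data$scope),
                                 ggplot2::vars(.data$score))
  }
  p
}
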