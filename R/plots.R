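#' Diagnostic plot for a Bliss fit
#'
#' Observed versus fitted combination `W` values; a tight diagonal indicates
#' the independence model explains the combination data well, and points far
#' above the diagonal are synergy candidates.
#'
#' @param object A `bliss_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bliss_fit <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$fitted, y = .data$w_obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      x = expression(hat(W)[i] + hat(W)[j]~"(fitted)"),
      y = expression(W[ij]~"(observed)"),
      title = sprintf("Bliss fit, assay (%s, %s)",
                      object$cell_line, object$dose_level),
      subtitle = sprintf("R² = %.3f over %d pair equations",
                         object$r_squared, object$m)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of absolute (lower triangle) and specificity (upper) scores
#'
#' @param T_mat,Sc_mat Score matrices with a shared drug order.
#' @return A ggplot: tiles below the diagonal show the cell-line count in
#'   which each pair synergizes, tiles above show the specificity score.
#' @export
plot_synergy_heatmap <- function(T_mat, Sc_mat) {
  drugs <- rownames(T_mat)
  idx <- which(upper.tri(T_mat), arr.ind = TRUE)
  df <- dplyr::bind_rows(
    tibble::tibble(x = idx[, 2], y = idx[, 1], value = T_mat[idx],
                   panel = "absolute"),
    tibble::tibble(x = idx[, 1], y = idx[, 2],
                   value = Sc_mat[idx], panel = "specificity")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_continuous(breaks = seq_along(drugs), labels = drugs,
                                expand = c(0, 0)) +
    ggplot2::scale_y_reverse(breaks = seq_along(drugs), labels = drugs,
                             expand = c(0, 0)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "score",
                  title = "Synergy scores: absolute (lower) / specificity (upper)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Distribution of absolute synergy scores against a randomization null
#'
#' @param T_mat Observed score matrix.
#' @param null_combined A permuted cube (long tibble from
#'   [permute_within_cell_line()]) to contrast against, or `NULL` to plot
#'   the observed distribution alone.
#' @return A ggplot of the per-pair score histograms.
#' @export
plot_score_distribution <- function(T_mat, null_combined = NULL) {
  obs <- tibble::tibble(score = T_mat[upper.tri(T_mat)], which = "observed")
  df <- obs
  if (!is.null(null_combined)) {
    Tn <- absolute_synergy_scores(null_combined, drugs = rownames(T_mat))
    df <- dplyr::bind_rows(
      obs, tibble::tibble(score = Tn[upper.tri(Tn)], which = "permuted")
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$which)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "absolute synergy score (cell lines with synergy)",
                  y = "drug pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
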