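#' Plot an FDR curve
#'
#' q-value against score, one panel per self/heteromeric group, with the
#' running decoy composition shown as colour.
#'
#' @param object An `xl_fdr_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xl_fdr_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$q_value)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "score (decreasing)", y = "q-value",
                  title = "Decoy-based FDR curve") +
    ggplot2::theme_minimal()
}

#' Plot accepted counts of an FDR result
#'
#' Accepted matches per group and decoy class at the chosen threshold.
#'
#' @param object An `xl_fdr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xl_fdr_result <- function(object, ...) {
  acc <- threshold_curve(object$curve, object$alpha)
  df <- dplyr::count(as_tibble(acc), .data$group, .data$decoy_class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n,
                                   fill = .data$decoy_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "accepted matches",
                  fill = "class",
                  title = sprintf("Accepted at %s-level FDR %.2g",
                                  object$level, object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot elution profiles of selected proteins
#'
#' @param profiles Wide elution profile tibble.
#' @param accessions Proteins to show.
#' @param normalize Normalise each profile to its maximum (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_elution_profiles <- function(profiles, accessions, normalize = TRUE) {
  df <- purrr::map_dfr(accessions, function(a) {
    v <- profile_vector(profiles, a)
    if (normalize && max(v) > 0) v <- normalize_profile(v)
    tibble(accession = a, fraction = seq_along(v), abundance = v)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$abundance,
                                   colour = .data$accession)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SEC fraction",
                  y = if (normalize) "relative abundance" else "iBAQ",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
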