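#' Tidy an FDR curve
#'
#' @param x An `xl_fdr_curve`.
#' @param ... Unused.
#' @return A tibble with one row per match: key, score, group, decoy class,
#'   cumulative counts, `fdr` and `q_value`.
#' @export
tidy.xl_fdr_curve <- function(x, ...) {
  as_tibble(x)[, c("group", "key", "score", "decoy_class", "is_self",
                   "TT", "TD", "DD", "fdr", "q_value")]
}

#' Tidy / summarise an FDR result
#'
#' `tidy()` returns the accepted target-target matches; `glance()` a
#' one-row summary.
#'
#' @param x An `xl_fdr_result` from [apply_fdr()] or [merge_datasets()].
#' @param ... Unused.
#' @export
tidy.xl_fdr_result <- function(x, ...) {
  as_tibble(x$accepted)
}

#' @rdname tidy.xl_fdr_result
#' @export
glance.xl_fdr_result <- function(x, ...) {
  acc <- x$accepted
  tibble(level = x$level, alpha = x$alpha, grouped = x$grouped,
         cascade = x$cascade,
         n_accepted = nrow(acc),
         n_accepted_het = sum(!acc$is_self),
         n_accepted_self = sum(acc$is_self))
}

#' Tidy an error estimate
#'
#' @param x An `xl_error_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the control name, counts, raw fraction, K+R
#'   factor and corrected error.
#' @export
tidy.xl_error_estimate <- function(x, ...) {
  tibble(control = x$control, n_false_control = x$n_false_control,
         n_plausible = x$n_plausible, raw_fraction = x$raw_fraction,
         kr_factor = x$kr_factor, corrected_error = x$corrected_error)
}

#' @rdname tidy.xl_error_estimate
#' @export
glance.xl_error_estimate <- function(x, ...) tidy(x)
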