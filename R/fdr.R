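#' Pointwise decoy-based FDR
#'
#' The crosslink-specific decoy estimate of the false discovery rate among
#' target-target matches above a score cutoff:
#' \deqn{FDR = (TD - DD) / TT}
#' Decoy-decoy counts are subtracted because a TD match can arise from one
#' random peptide paired with a true one, double-counting pure random
#' matches. The estimate is clamped to \[0, 1\]; with no targets it is 0
#' when `TD - DD <= 0` and 1 otherwise.
#'
#' @param TT,TD,DD Non-negative cumulative match counts per class.
#' @return Numeric vector of FDR estimates in \[0, 1\].
#' @examples
#' fdr_point(95, 10, 5) # 5/95
#' @export
fdr_point <- function(TT, TD, DD) {
  if (any(c(TT, TD, DD) < 0)) abort("counts must be non-negative")
  raw <- ifelse(TT == 0, ifelse(TD - DD <= 0, 0, 1), (TD - DD) / TT)
  pmin(pmax(raw, 0), 1)
}

#' Build a score-ordered FDR curve
#'
#' Sorts matches by descending score (ties: decoys before targets, a
#' conservative over-count), accumulates TT/TD/DD prefix counts, applies
#' [fdr_point()] at every prefix and monotonises into q-values by a running
#' minimum from the low-score end, so acceptance sets are nested in the
#' threshold. Self and heteromeric matches occupy random spaces of very
#' different size, so by default they form separate groups with separate
#' curves.
#'
#' @param matches Aggregated match tibble at a single level.
#' @param group_self_separately Estimate self and heteromeric groups
#'   separately (default `TRUE`); otherwise one combined group.
#' @return An `xl_fdr_curve`: the match tibble with `group`, cumulative
#'   `TT`, `TD`, `DD`, `fdr` and `q_value` columns, ordered within group by
#'   the acceptance order.
#' @export
build_fdr_curve <- function(matches, group_self_separately = TRUE) {
  lv <- unique(matches$level)
  if (length(lv) > 1) abort("input mixes identification levels")
  x <- matches
  x$group <- if (group_self_separately) {
    if_else(x$is_self, "self", "heteromeric")
  } else "combined"
  decoy_rank <- c(DD = 0L, TD = 1L, TT = 2L)
  x <- x |>
    group_by(.data$group) |>
    arrange(desc(.data$score), decoy_rank[.data$decoy_class], .data$key,
            .by_group = TRUE) |>
    mutate(
      TT = cumsum(.data$decoy_class == "TT"),
      TD = cumsum(.data$decoy_class == "TD"),
      DD = cumsum(.data$decoy_class == "DD"),
      fdr = fdr_point(.data$TT, .data$TD, .data$DD),
      q_value = rev(cummin(rev(.data$fdr)))
    ) |>
    ungroup()
  structure(x, class = c("xl_fdr_curve", class(x)),
            level = lv, grouped = group_self_separately)
}

threshold_curve <- function(curve, alpha) {
  dplyr::filter(curve, .data$q_value <= alpha)
}

# per-group score cutoff and class tallies among accepted matches
curve_cutoffs <- function(curve, alpha) {
  acc <- threshold_curve(curve, alpha)
  groups <- unique(curve$group)
  purrr::map_dfr(groups, function(g) {
    a <- acc[acc$group == g, ]
    tibble(group = g,
           score_cutoff = if (nrow(a) > 0) min(a$score) else Inf,
           n_accepted = sum(a$decoy_class == "TT"),
           TT = sum(a$decoy_class == "TT"),
           TD = sum(a$decoy_class == "TD"),
           DD = sum(a$decoy_class == "DD"))
  })
}

#' Apply FDR control at a chosen identification level
#'
#' Starting from unique CSM-level matches, controls the decoy-based FDR at
#' `level`. With `cascade = TRUE` each lower level is thresholded at the
#' same `alpha` on its own curve (same grouping) and only the survivors —
#' including decoy matches, which must survive to stay countable — are
#' merged upward before the target level is thresholded. Matches are
#' accepted when `q_value <= alpha`.
#'
#' @param csm_matches Aggregated match tibble at level `"csm"` (from
#'   [as_matches()]), or matches already at `level` when `cascade = FALSE`.
#' @param level Target level, default `"ppi"`.
#' @param alpha Nominal FDR threshold in (0, 1).
#' @param group_self_separately Separate self/heteromeric estimation.
#' @param cascade Threshold every lower level at `alpha` first.
#' @return An `xl_fdr_result` list: `accepted` (target-target matches with
#'   q-values), `curve` (the final [build_fdr_curve()] output over all
#'   classes), `cutoffs` (per-group score cutoffs and tallies), `level`,
#'   `alpha`, `grouped`, `cascade`.
#' @export
apply_fdr <- function(csm_matches, level = "ppi", alpha = 0.05,
                      group_self_separately = TRUE, cascade = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "xlinkfdr_config_error")
  }
  levels <- match_levels()
  target_i <- match(level, levels)
  if (is.na(target_i)) abort(paste0("unknown level: ", level))
  x <- csm_matches
  cur_i <- match(unique(x$level), levels)
  if (length(cur_i) != 1) abort("input mixes identification levels")
  if (cascade && cur_i < target_i) {
    for (i in cur_i:(target_i - 1)) {
      cv <- build_fdr_curve(x, group_self_separately)
      surv <- threshold_curve(cv, alpha)
      surv <- as_tibble(surv)[, setdiff(names(surv),
                                        c("group", "TT", "TD", "DD",
                                          "fdr", "q_value"))]
      x <- merge_to_level(surv, levels[i + 1])
    }
  } else if (cur_i < target_i) {
    x <- merge_to_level(x, level)
  }
  curve <- build_fdr_curve(x, group_self_separately)
  accepted <- threshold_curve(curve, alpha)
  structure(
    list(accepted = accepted[accepted$decoy_class == "TT", ],
         curve = curve,
         cutoffs = curve_cutoffs(curve, alpha),
         level = level, alpha = alpha,
         grouped = group_self_separately, cascade = cascade),
    class = "xl_fdr_result")
}

#' Local-FDR score normalisation
#'
#' Score scales differ between datasets (e.g. different crosslinker
#' chemistries), so before merging datasets each match score is replaced by
#' `1 - local FDR`, a normalised score in \[0, 1\]. The local FDR at a match
#' is [fdr_point()] evaluated on a window of the `window` nearest matches by
#' score rank within the match's group, then monotonised to be
#' non-decreasing as the score decreases.
#'
#' @param matches Aggregated match tibble at one level.
#' @param window Odd window size of at least 5 ranks (default 101). Groups
#'   smaller than the window use the whole group.
#' @param group_self_separately Separate self/heteromeric windows.
#' @return `matches` with `local_fdr` and `normalized_score` columns.
#' @export
normalize_scores <- function(matches, window = 101L,
                             group_self_separately = TRUE) {
  if (window < 5 || window %% 2 == 0) {
    abort("window must be an odd integer >= 5", class = "xlinkfdr_config_error")
  }
  curve <- build_fdr_curve(matches, group_self_separately)
  out <- curve |>
    group_by(.data$group) |>
    mutate(local_fdr = local_fdr_window(.data$decoy_class, window),
           normalized_score = 1 - cummax(.data$local_fdr)) |>
    ungroup()
  class(out) <- setdiff(class(out), "xl_fdr_curve")
  out
}

# sliding rank window, shrunk to the group when the group is smaller
local_fdr_window <- function(decoy_class, window) {
  n <- length(decoy_class)
  if (n == 0) return(numeric(0))
  w <- min(window, n)
  half <- (w - 1L) %/% 2L
  ctt <- cumsum(c(0L, decoy_class == "TT"))
  ctd <- cumsum(c(0L, decoy_class == "TD"))
  cdd <- cumsum(c(0L, decoy_class == "DD"))
  i <- seq_len(n)
  lo <- pmax(1L, pmin(i - half, n - w + 1L))
  hi <- lo + w - 1L
  fdr_point(ctt[hi + 1L] - ctt[lo], ctd[hi + 1L] - ctd[lo],
            cdd[hi + 1L] - cdd[lo])
}

#' Merge two datasets at a common FDR threshold
#'
#' Concatenates two tables of matches (typically protein pairs from two
#' crosslinkers) whose scores were normalised with [normalize_scores()],
#' combines records sharing a key across the two datasets by root-sum-square
#' of their normalised scores, rebuilds the FDR curve and thresholds at
#' `alpha`.
#'
#' @param results_a,results_b Aggregated match tibbles at the same level
#'   with a `normalized_score` column.
#' @param alpha Nominal FDR threshold (default 0.01).
#' @param group_self_separately Separate self/heteromeric estimation.
#' @return An `xl_fdr_result` over the merged table.
#' @export
merge_datasets <- function(results_a, results_b, alpha = 0.01,
                           group_self_separately = TRUE) {
  lv <- unique(c(results_a$level, results_b$level))
  if (length(lv) > 1) abort("datasets are at different identification levels")
  for (x in list(results_a, results_b)) {
    if (!"normalized_score" %in% names(x)) {
      abort("normalize_scores() must be applied before merging datasets")
    }
  }
  keep <- c("level", "key", "normalized_score", "decoy_class", "is_self",
            "n_csm", "protein_1", "protein_2")
  both <- bind_rows(results_a[, keep], results_b[, keep]) |>
    group_by(.data$key, .data$decoy_class, .data$is_self) |>
    summarise(level = first(.data$level),
              score = sqrt(sum(.data$normalized_score^2)),
              n_csm = sum(.data$n_csm),
              protein_1 = first(.data$protein_1),
              protein_2 = first(.data$protein_2),
              .groups = "drop")
  curve <- build_fdr_curve(both, group_self_separately)
  accepted <- threshold_curve(curve, alpha)
  structure(
    list(accepted = accepted[accepted$decoy_class == "TT", ],
         curve = curve,
         cutoffs = curve_cutoffs(curve, alpha),
         level = lv, alpha = alpha,
         grouped = group_self_separately, cascade = FALSE),
    class = "xl_fdr_result")
}

#' @export
print.xl_fdr_result <- function(x, ...) {
  cat(sprintf("<xl_fdr_result> level=%s alpha=%g grouped=%s cascade=%s\n",
              x$level, x$alpha, x$grouped, x$cascade))
  cat(sprintf("  accepted target-target matches: %d\n", nrow(x$accepted)))
  print(x$cutoffs)
  invisible(x)
}
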