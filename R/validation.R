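new_error_estimate <- function(control, n_false_control, n_plausible,
                               kr_factor) {
  raw <- if (n_false_control + n_plausible == 0) 0 else
    n_false_control / (n_plausible + n_false_control)
  structure(
    list(control = control,
         n_false_control = n_false_control,
         n_plausible = n_plausible,
         raw_fraction = raw,
         kr_factor = kr_factor,
         corrected_error = raw * kr_factor),
    class = "xl_error_estimate")
}

#' @export
print.xl_error_estimate <- function(x, ...) {
  cat(sprintf(
    "<xl_error_estimate> %s: %d false / %d plausible, raw %.4f x KR %.4f = %.4f\n",
    x$control, x$n_false_control, x$n_plausible, x$raw_fraction,
    x$kr_factor, x$corrected_error))
  invisible(x)
}

#' Search-space normalisation factor from K+R content
#'
#' False matches distribute over the *whole* search space but a control
#' (entrapment or non-crosslinkable partition) only observes those falling
#' into its share. The observed false fraction is scaled by
#' `(KR_main + KR_control) / KR_control`, using total lysine + arginine
#' content as a proxy for the number of tryptic peptides each partition
#' contributes. Equal K+R content gives exactly 2.
#'
#' @param kr_main Total K+R of the partition whose error is estimated
#'   (e.g. the foreground proteome).
#' @param kr_control Total K+R of the control partition; must be positive.
#' @return The normalisation factor (always `>= 1`).
#' @examples
#' kr_factor(9, 100) # 1.09
#' @export
kr_factor <- function(kr_main, kr_control) {
  if (any(kr_control <= 0)) {
    abort("control partition has no K/R residues",
          class = "xlinkfdr_config_error")
  }
  (kr_main + kr_control) / kr_control
}

#' Construct an entrapment database
#'
#' For each foreground protein (processed in descending K+R order), selects
#' the unused candidate with the closest K+R count (ties: closest length,
#' then lexicographically smallest accession), without replacement. The
#' selected foreign proteins are flagged `is_entrapment`; any accepted PPI
#' touching them is a known false positive.
#'
#' @param foreground Protein tibble of the foreground (real) proteome.
#' @param candidates Protein tibble of foreign candidate proteins; must be
#'   at least as many as the foreground.
#' @return Protein tibble of selected entrapment proteins.
#' @export
build_entrapment_db <- function(foreground, candidates) {
  if (nrow(candidates) < nrow(foreground)) {
    abort("fewer candidates than foreground proteins",
          class = "xlinkfdr_config_error")
  }
  cand <- candidates |>
    arrange(.data$kr_count, nchar(.data$sequence), .data$accession)
  used <- rep(FALSE, nrow(cand))
  pick <- integer(nrow(foreground))
  fg_order <- order(-foreground$kr_count)
  for (j in fg_order) {
    free <- which(!used)
    d_kr <- abs(cand$kr_count[free] - foreground$kr_count[j])
    best <- free[d_kr == min(d_kr)]
    if (length(best) > 1) {
      d_len <- abs(nchar(cand$sequence[best]) - nchar(foreground$sequence[j]))
      best <- best[d_len == min(d_len)]
      best <- best[order(cand$accession[best])][1]
    }
    used[best[1]] <- TRUE
    pick[j] <- best[1]
  }
  out <- cand[pick, ]
  out$is_entrapment <- TRUE
  out
}

#' Entrapment-based PPI error estimate
#'
#' Counts accepted target PPIs touching at least one entrapment protein and
#' corrects the observed fraction by the K+R search-space factor computed
#' over the foreground versus entrapment partitions of the database:
#' \deqn{Error = n_{ent} / (n_{fg} + n_{ent}) \cdot
#'       (KR_{fg} + KR_{ent}) / KR_{ent}}
#'
#' @param accepted_ppis Accepted PPI-level match tibble (target-target) with
#'   `protein_1` / `protein_2` columns.
#' @param proteome Protein tibble with `is_entrapment` flags (decoys
#'   ignored).
#' @return An `xl_error_estimate`.
#' @export
entrapment_error <- function(accepted_ppis, proteome) {
  targets <- proteome[!proteome$is_decoy, ]
  accs <- unique(c(accepted_ppis$protein_1, accepted_ppis$protein_2))
  unknown <- setdiff(accs, targets$base_accession)
  if (length(unknown) > 0) {
    abort(paste0("accession(s) not in proteome: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  ent <- targets$base_accession[targets$is_entrapment]
  touches <- accepted_ppis$protein_1 %in% ent | accepted_ppis$protein_2 %in% ent
  n_ent <- sum(touches)
  n_fg <- sum(!touches)
  kf <- if (n_ent == 0 && sum(targets$is_entrapment) == 0) 1 else
    kr_factor(sum(targets$kr_count[!targets$is_entrapment]),
              sum(targets$kr_count[targets$is_entrapment]))
  new_error_estimate("entrapment", n_ent, n_fg, kf)
}

#' Best lower iBAQ of a protein pair
#'
#' For two elution profiles over the same fractions, keeps the lower of the
#' two iBAQ values in every fraction and returns the maximum over fractions:
#' the best abundance at which the pair was ever seen together, hence the
#' best estimate of the chance to observe the pair crosslinked.
#'
#' @param a,b Numeric abundance vectors (iBAQ per fraction), equal length.
#' @return A single number (0 when the pair never co-occurs).
#' @examples
#' best_lower_ibaq(c(0, 8, 2), c(5, 4, 9)) # 4
#' @export
best_lower_ibaq <- function(a, b) {
  if (length(a) != length(b)) abort("profiles differ in fraction count")
  max(pmin(a, b))
}

#' Abundance threshold from loosely filtered pairs
#'
#' The detection-limit heuristic: take the distribution of
#' [best_lower_ibaq()] over protein pairs identified at a loose FDR and
#' return its lower 5th percentile (nearest-rank).
#'
#' @param pairs Tibble with `protein_1`, `protein_2` columns.
#' @param profiles Wide elution profile tibble.
#' @param percentile Lower tail probability (default 0.05).
#' @return The iBAQ threshold.
#' @export
ibaq_threshold <- function(pairs, profiles, percentile = 0.05) {
  if (nrow(pairs) == 0) abort("no pairs supplied")
  vals <- purrr::map2_dbl(pairs$protein_1, pairs$protein_2, function(p1, p2) {
    best_lower_ibaq(profile_vector(profiles, p1), profile_vector(profiles, p2))
  })
  sort(vals)[max(1L, ceiling(percentile * length(vals)))]
}

#' Classify a protein pair as plausible or non-crosslinkable
#'
#' A pair is plausible when both proteins are found together in at least one
#' SEC fraction with individual iBAQ values above the threshold; otherwise
#' the proteins never co-occurred at detectable abundance and could not have
#' been crosslinked, so an identification of the pair is a false positive.
#'
#' @param pairs Tibble with `protein_1`, `protein_2` columns.
#' @param profiles Wide elution profile tibble (absent proteins count as
#'   all-zero).
#' @param threshold iBAQ threshold, e.g. from [ibaq_threshold()].
#' @return Logical vector: `TRUE` for plausible pairs.
#' @export
classify_plausible <- function(pairs, profiles, threshold) {
  purrr::map2_lgl(pairs$protein_1, pairs$protein_2, function(p1, p2) {
    a <- profile_vector(profiles, p1)
    b <- profile_vector(profiles, p2)
    any(a > threshold & b > threshold)
  })
}

#' Non-crosslinkable PPI error estimate
#'
#' The experimentally grounded error control: accepted PPIs classified
#' non-crosslinkable are known false, and the observed false fraction is
#' scaled by the K+R factor of the plausible versus false interaction sets
#' (each distinct protein counted once per set it appears in):
#' \deqn{Error = n_{false} / (n_{plausible} + n_{false}) \cdot
#'       (KR_{plausible} + KR_{false}) / KR_{false}}
#'
#' @param accepted_ppis Accepted PPI-level match tibble (target-target).
#' @param plausible Logical vector parallel to `accepted_ppis`, e.g. from
#'   [classify_plausible()].
#' @param proteome Protein tibble resolving `kr_count` by `base_accession`.
#' @return An `xl_error_estimate`.
#' @export
noncrosslinkable_error <- function(accepted_ppis, plausible, proteome) {
  if (length(plausible) != nrow(accepted_ppis) || anyNA(plausible)) {
    abort("every accepted PPI must be classified")
  }
  kr_of <- function(accs) {
    i <- match(unique(accs), proteome$base_accession)
    if (anyNA(i)) abort("accession(s) not in proteome")
    sum(proteome$kr_count[i])
  }
  n_false <- sum(!plausible)
  n_plaus <- sum(plausible)
  kf <- if (n_false == 0) 1 else {
    kr_false <- kr_of(c(accepted_ppis$protein_1[!plausible],
                        accepted_ppis$protein_2[!plausible]))
    kr_plaus <- if (n_plaus == 0) 0 else
      kr_of(c(accepted_ppis$protein_1[plausible],
              accepted_ppis$protein_2[plausible]))
    kr_factor(kr_plaus, kr_false)
  }
  new_error_estimate("non-crosslinkable", n_false, n_plaus, kf)
}

#' Wrong-crosslinker PPI error estimate
#'
#' Matches assigned to a fictional crosslinker (true mass shifted by
#' -28.031 Da) are known false. Because adding the wrong-mass crosslinker
#' doubles the search space, the observed fraction is scaled by 2. A PPI
#' matched by both the correct and the wrong crosslinker counts once on each
#' side.
#'
#' @param accepted Match tibble with a `crosslinker_id` column.
#' @param true_id,wrong_id The two crosslinker identifiers.
#' @return An `xl_error_estimate`.
#' @export
wrong_crosslinker_error <- function(accepted, true_id, wrong_id) {
  ids <- unique(accepted$crosslinker_id)
  unknown <- setdiff(ids, c(true_id, wrong_id))
  if (length(unknown) > 0) {
    abort(paste0("unknown crosslinker id(s): ", paste(unknown, collapse = ", ")))
  }
  n_wrong <- sum(accepted$crosslinker_id == wrong_id)
  n_true <- sum(accepted$crosslinker_id == true_id)
  new_error_estimate("wrong-crosslinker", n_wrong, n_true, 2)
}
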