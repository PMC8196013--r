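#' Prefilter crosslink-spectrum matches
#'
#' Applies the standard pre-FDR quality filters to a CSM table. A match is
#' retained only if
#' * both peptides have at least `min_fragments` matched fragments,
#' * both unmodified peptides are at least `min_peptide_length` residues,
#' * `delta_score >= delta_ratio * score`,
#' * (if `drop_ambiguous`) each peptide maps to exactly one protein after
#'   decoy-prefix stripping (a peptide shared only by a target and its own
#'   decoy is not ambiguous), and
#' * (if `drop_noncovalent`) the spectrum was not flagged as a gas-phase
#'   associated (non-covalent) peptide pair.
#'
#' A CSM failing several rules is counted once under the first failing rule
#' in the order fragments, length, delta, ambiguity, noncovalent; the
#' per-rule counts are attached as the `"rejections"` attribute and readable
#' with [rejection_counts()].
#'
#' @param csms A CSM tibble.
#' @param min_fragments Minimum matched fragments per peptide (default 3).
#' @param delta_ratio Required delta score as a fraction of the match score
#'   (default 0.15). Rows with `NA` delta (column absent upstream) skip this
#'   rule.
#' @param min_peptide_length Minimum unmodified peptide length (default 6).
#' @param drop_ambiguous Drop matches with multi-protein peptides.
#' @param drop_noncovalent Drop spectra flagged as non-covalent.
#' @param decoy_prefix Accession prefix stripped before the ambiguity test.
#' @return The retained CSM tibble, with attribute `rejections` (named
#'   integer vector).
#' @examples
#' x <- csm_tibble("s1", "PEPTIDEK", 3, "P1", "ELVISKR", 2, "P2",
#'                 matched_fragments_a = 3, matched_fragments_b = 3,
#'                 score = 10, delta_score = 2)
#' filter_csms(x)
#' @export
filter_csms <- function(csms, min_fragments = 3L, delta_ratio = 0.15,
                        min_peptide_length = 6L, drop_ambiguous = TRUE,
                        drop_noncovalent = TRUE, decoy_prefix = "REV_") {
  if (min_fragments < 0 || delta_ratio < 0 || min_peptide_length < 0) {
    abort("filter thresholds must be non-negative",
          class = "xlinkfdr_config_error")
  }
  fail_frag <- csms$matched_fragments_a < min_fragments |
    csms$matched_fragments_b < min_fragments
  fail_len <- peptide_length(csms$sequence_a) < min_peptide_length |
    peptide_length(csms$sequence_b) < min_peptide_length
  fail_delta <- !is.na(csms$delta_score) &
    csms$delta_score < delta_ratio * csms$score
  n_prot <- function(p, prefix) {
    purrr::map_int(strsplit(p, ";", fixed = TRUE),
                   ~ length(unique(strip_decoy_prefix(.x, prefix))))
  }
  fail_amb <- if (drop_ambiguous) {
    n_prot(csms$proteins_a, decoy_prefix) != 1L |
      n_prot(csms$proteins_b, decoy_prefix) != 1L
  } else rep(FALSE, nrow(csms))
  fail_nc <- if (drop_noncovalent) csms$noncovalent_flag else rep(FALSE, nrow(csms))

  # first-failing rule, in the documented order
  rule <- rep(NA_character_, nrow(csms))
  for (r in c("noncovalent", "ambiguity", "delta", "length", "fragments")) {
    f <- switch(r, fragments = fail_frag, length = fail_len, delta = fail_delta,
                ambiguity = fail_amb, noncovalent = fail_nc)
    rule[f] <- r
  }
  keep <- is.na(rule)
  rejections <- setNames(
    purrr::map_int(c("fragments", "length", "delta", "ambiguity", "noncovalent"),
                   ~ sum(rule == .x, na.rm = TRUE)),
    c("fragments", "length", "delta", "ambiguity", "noncovalent"))
  out <- csms[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' @rdname filter_csms
#' @param x A tibble returned by [filter_csms()].
#' @export
rejection_counts <- function(x) {
  attr(x, "rejections") %||%
    abort("no rejection counts: was this produced by filter_csms()?")
}
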