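match_levels <- function() c("csm", "peptide_pair", "residue_pair", "ppi")

#' Canonicalise the two sides of each CSM
#'
#' A crosslink has no direction: a link from peptide A to peptide B is the
#' same observation as B to A. Canonicalisation orders the two peptides of
#' every match under a total order (sequence string, then link position,
#' then accession list) so that equal matches get equal keys. Idempotent and
#' deterministic.
#'
#' @param csms A CSM tibble.
#' @return The CSM tibble with sides `a`/`b` possibly swapped per row.
#' @export
canonicalize_csms <- function(csms) {
  swap <- csms$sequence_a > csms$sequence_b |
    (csms$sequence_a == csms$sequence_b & csms$link_pos_a > csms$link_pos_b) |
    (csms$sequence_a == csms$sequence_b & csms$link_pos_a == csms$link_pos_b &
       csms$proteins_a > csms$proteins_b)
  side_cols <- c("sequence", "link_pos", "proteins", "positions", "is_decoy",
                 "matched_fragments")
  out <- csms
  for (col in side_cols) {
    a <- paste0(col, "_a"); b <- paste0(col, "_b")
    tmp <- out[[a]][swap]
    out[[a]][swap] <- out[[b]][swap]
    out[[b]][swap] <- tmp
  }
  out
}

#' Collapse spectrum-redundant CSMs to unique CSMs
#'
#' Repeated spectra of the same crosslinked peptide pair (same modified
#' sequences, link positions and, by default, precursor charge) are one
#' piece of evidence, not several; using redundant CSMs distorts every
#' downstream FDR. The highest-scoring record per key is kept (ties broken
#' by lowest spectrum id).
#'
#' @param csms A CSM tibble.
#' @param include_charge Include precursor charge in the unique-CSM key
#'   (default `TRUE`).
#' @return Unique CSM tibble, canonicalised.
#' @export
deduplicate_csms <- function(csms, include_charge = TRUE) {
  x <- canonicalize_csms(csms)
  key <- paste(x$sequence_a, x$link_pos_a, x$sequence_b, x$link_pos_b,
               if (include_charge) x$precursor_charge else "", sep = "\r")
  ord <- order(key, -x$score, x$spectrum_id)
  x <- x[ord, , drop = FALSE]
  x[!duplicated(key[ord]), , drop = FALSE]
}

#' Decoy class of a match
#'
#' @param is_decoy_a,is_decoy_b Logical decoy flags of the two sides.
#' @return Character vector in `{"TT","TD","DD"}`.
#' @export
decoy_class <- function(is_decoy_a, is_decoy_b) {
  dplyr::case_when(
    !is_decoy_a & !is_decoy_b ~ "TT",
    is_decoy_a & is_decoy_b ~ "DD",
    .default = "TD"
  )
}

#' Self versus heteromeric classification
#'
#' A match is a self link when both peptides map to the same protein
#' sequence after stripping the decoy prefix, so a target peptide crosslinked
#' to its own protein's decoy still counts as self. Requires unambiguous
#' (single-protein) assignments; ambiguous matches should have been removed
#' by [filter_csms()].
#'
#' @param proteins_a,proteins_b Semicolon-separated accession strings.
#' @param decoy_prefix Accession prefix marking decoys.
#' @return Logical vector: `TRUE` for self links.
#' @export
classify_self <- function(proteins_a, proteins_b, decoy_prefix = "REV_") {
  one_base <- function(p) {
    bases <- purrr::map(strsplit(p, ";", fixed = TRUE),
                        ~ unique(strip_decoy_prefix(.x, decoy_prefix)))
    n <- lengths(bases)
    if (any(n != 1L)) {
      abort("ambiguous protein assignment; run filter_csms() first")
    }
    purrr::map_chr(bases, 1)
  }
  one_base(proteins_a) == one_base(proteins_b)
}

#' Lift unique CSMs to aggregated matches
#'
#' Converts a canonicalised, deduplicated CSM tibble into the aggregated
#' match representation shared by all identification levels: one row per
#' match carrying its key, score, decoy class, self flag, CSM support count,
#' and the higher-level keys (peptide pair, residue pair, protein pair) it
#' will merge into. Residue positions in the protein are
#' `protein_position + link_position - 1` (1-based); when a peptide maps to
#' several positions in its single protein, the first listed position is
#' used.
#'
#' @param csms Unique CSM tibble from [deduplicate_csms()].
#' @param decoy_prefix Accession prefix marking decoys.
#' @param include_charge Include precursor charge in the CSM key.
#' @return An aggregated match tibble at level `"csm"`.
#' @export
as_matches <- function(csms, decoy_prefix = "REV_", include_charge = TRUE) {
  first_tok <- function(x) purrr::map_chr(strsplit(x, ";", fixed = TRUE), 1)
  base_a <- strip_decoy_prefix(first_tok(csms$proteins_a), decoy_prefix)
  base_b <- strip_decoy_prefix(first_tok(csms$proteins_b), decoy_prefix)
  site_a <- as.integer(first_tok(csms$positions_a)) + csms$link_pos_a - 1L
  site_b <- as.integer(first_tok(csms$positions_b)) + csms$link_pos_b - 1L
  pep_a <- paste0(csms$sequence_a, "|", csms$link_pos_a)
  pep_b <- paste0(csms$sequence_b, "|", csms$link_pos_b)
  res_a <- paste0(base_a, ":", site_a)
  res_b <- paste0(base_b, ":", site_b)
  res_swap <- res_a > res_b
  acc_swap <- base_a > base_b
  tibble(
    level = "csm",
    key = paste(pep_a, pep_b,
                if (include_charge) csms$precursor_charge else "",
                sep = "::"),
    score = csms$score,
    decoy_class = decoy_class(csms$is_decoy_a, csms$is_decoy_b),
    is_self = classify_self(csms$proteins_a, csms$proteins_b, decoy_prefix),
    n_csm = 1L,
    support = as.list(csms$spectrum_id),
    pep_key = paste(pep_a, pep_b, sep = "--"),
    res_key = paste(ifelse(res_swap, res_b, res_a),
                    ifelse(res_swap, res_a, res_b), sep = "--"),
    ppi_key = paste(ifelse(acc_swap, base_b, base_a),
                    ifelse(acc_swap, base_a, base_b), sep = "--"),
    protein_1 = ifelse(acc_swap, base_b, base_a),
    protein_2 = ifelse(acc_swap, base_a, base_b),
    crosslinker_id = csms$crosslinker_id
  )
}

#' Merge matches upward one or more identification levels
#'
#' Groups matches by the key of the target level — restricted to identical
#' decoy class and self flag, so that decoy protein pairs survive as their
#' own records and stay countable — and aggregates scores as the
#' root-sum-square of the member scores:
#' \deqn{Score_{higher} = \sqrt{\sum Score_{lower}^2}}
#' Root-sum-square composes, so merging CSMs straight to protein pairs
#' equals merging through peptide pairs and residue pairs.
#'
#' @param matches Aggregated match tibble, all at one level.
#' @param to_level Target level: `"peptide_pair"`, `"residue_pair"` or
#'   `"ppi"`.
#' @return Aggregated match tibble at `to_level`; at `"ppi"` level an
#'   `n_residue_pairs` column counts the distinct residue pairs supporting
#'   each protein pair.
#' @export
merge_to_level <- function(matches, to_level) {
  lv <- unique(matches$level)
  if (length(lv) > 1) abort("input mixes identification levels")
  levels <- match_levels()
  if (!to_level %in% levels) abort(paste0("unknown level: ", to_level))
  if (nrow(matches) > 0 && match(to_level, levels) <= match(lv, levels)) {
    abort(paste0("cannot merge ", lv, " to ", to_level))
  }
  key_col <- switch(to_level, peptide_pair = "pep_key",
                    residue_pair = "res_key", ppi = "ppi_key")
  out <- matches |>
    group_by(new_key = .data[[key_col]], .data$decoy_class, .data$is_self) |>
    summarise(
      score = sqrt(sum(.data$score^2)),
      n_csm = sum(.data$n_csm),
      support = list(unlist(.data$key)),
      n_residue_pairs = dplyr::n_distinct(.data$res_key),
      pep_key = first(.data$pep_key),
      res_key = first(.data$res_key),
      ppi_key = first(.data$ppi_key),
      protein_1 = first(.data$protein_1),
      protein_2 = first(.data$protein_2),
      crosslinker_id = first(.data$crosslinker_id),
      .groups = "drop"
    ) |>
    rename(key = "new_key") |>
    mutate(level = to_level) |>
    arrange(desc(.data$score), .data$key)
  if (to_level != "ppi") out$n_residue_pairs <- NULL
  out[, c("level", "key", "score", "decoy_class", "is_self", "n_csm",
          "support",
          intersect("n_residue_pairs", names(out)),
          "pep_key", "res_key", "ppi_key", "protein_1", "protein_2",
          "crosslinker_id")]
}
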