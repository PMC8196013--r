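#' Canonical CSM column names
#'
#' Crosslink search engines name their output columns differently; every
#' reader in the package goes through a column map from the logical field
#' names used internally to the column names found in the file. The default
#' map is the identity on the canonical names below. Fields `a`/`b` refer to
#' the two crosslinked peptides of a match.
#'
#' @return Named character vector `logical field -> file column`.
#' @export
csm_columns <- function() {
  cols <- c(
    "spectrum_id",
    "sequence_a", "link_pos_a", "proteins_a", "positions_a",
    "is_decoy_a", "matched_fragments_a",
    "sequence_b", "link_pos_b", "proteins_b", "positions_b",
    "is_decoy_b", "matched_fragments_b",
    "precursor_charge", "score", "delta_score",
    "crosslinker_id", "noncovalent_flag"
  )
  setNames(cols, cols)
}

csm_required_fields <- function() {
  c("spectrum_id", "sequence_a", "link_pos_a", "proteins_a",
    "matched_fragments_a", "sequence_b", "link_pos_b", "proteins_b",
    "matched_fragments_b", "precursor_charge", "score")
}

csm_integer_fields <- function() {
  c("link_pos_a", "link_pos_b", "matched_fragments_a", "matched_fragments_b",
    "precursor_charge")
}

#' Build a CSM table in code
#'
#' Convenience constructor for crosslink-spectrum-match (CSM) tables with
#' sensible defaults for the optional fields; used heavily by tests and the
#' simulator. Protein assignments are semicolon-separated accession strings
#' (one peptide can match several proteins until ambiguity filtering).
#'
#' @param spectrum_id,sequence_a,sequence_b,link_pos_a,link_pos_b Core match
#'   fields; link positions are 1-based within the unmodified peptide.
#' @param proteins_a,proteins_b Semicolon-separated accessions per peptide.
#' @param positions_a,positions_b Semicolon-separated 1-based peptide start
#'   positions in the protein, parallel to the accession lists (default 1).
#' @param is_decoy_a,is_decoy_b Logical decoy flags; default derived from
#'   `decoy_prefix` on the first accession.
#' @param matched_fragments_a,matched_fragments_b Matched fragment counts.
#' @param precursor_charge,score,delta_score,crosslinker_id,noncovalent_flag
#'   Remaining per-match fields.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @return A CSM tibble with the canonical columns of [csm_columns()].
#' @export
csm_tibble <- function(spectrum_id, sequence_a, link_pos_a, proteins_a,
                       sequence_b, link_pos_b, proteins_b,
                       positions_a = "1", positions_b = "1",
                       is_decoy_a = NULL, is_decoy_b = NULL,
                       matched_fragments_a = 10L, matched_fragments_b = 10L,
                       precursor_charge = 3L, score = 10, delta_score = NULL,
                       crosslinker_id = "XL", noncovalent_flag = FALSE,
                       decoy_prefix = "REV_") {
  x <- tibble(
    spectrum_id = as.character(spectrum_id),
    sequence_a = as.character(sequence_a),
    link_pos_a = as.integer(link_pos_a),
    proteins_a = as.character(proteins_a),
    positions_a = as.character(positions_a),
    matched_fragments_a = as.integer(matched_fragments_a),
    sequence_b = as.character(sequence_b),
    link_pos_b = as.integer(link_pos_b),
    proteins_b = as.character(proteins_b),
    positions_b = as.character(positions_b),
    matched_fragments_b = as.integer(matched_fragments_b),
    precursor_charge = as.integer(precursor_charge),
    score = as.numeric(score),
    crosslinker_id = as.character(crosslinker_id),
    noncovalent_flag = as.logical(noncovalent_flag)
  )
  x$delta_score <- if (is.null(delta_score)) x$score * 0.5 else as.numeric(delta_score)
  x$is_decoy_a <- if (is.null(is_decoy_a)) {
    first_accession_is_decoy(x$proteins_a, decoy_prefix)
  } else as.logical(is_decoy_a)
  x$is_decoy_b <- if (is.null(is_decoy_b)) {
    first_accession_is_decoy(x$proteins_b, decoy_prefix)
  } else as.logical(is_decoy_b)
  validate_csms(x[, names(csm_columns())])
}

first_accession_is_decoy <- function(proteins, decoy_prefix) {
  startsWith(purrr::map_chr(strsplit(proteins, ";", fixed = TRUE), 1), decoy_prefix)
}

# Enforce the CSM invariants: 0 <= delta <= score (clamped), link positions
# inside the unmodified peptide.
validate_csms <- function(x) {
  x$delta_score <- pmin(pmax(x$delta_score, 0), pmax(x$score, 0))
  bad_a <- x$link_pos_a < 1L | x$link_pos_a > peptide_length(x$sequence_a)
  bad_b <- x$link_pos_b < 1L | x$link_pos_b > peptide_length(x$sequence_b)
  if (any(bad_a | bad_b, na.rm = TRUE)) {
    abort(paste0("link position outside peptide for spectrum ",
                 x$spectrum_id[which(bad_a | bad_b)[1]]))
  }
  as_tibble(x)
}

#' Read a CSM table from TSV
#'
#' Parses a tab-separated table of crosslink-spectrum matches produced by any
#' search engine, renaming columns through `column_map`. Decoy status may be
#' carried as an explicit logical column, derived from the accession prefix,
#' or both; when both are present and disagree the file is rejected. A
#' missing `delta_score` column disables the delta-score prefilter with a
#' warning rather than failing.
#'
#' @param path File path of a UTF-8, tab-separated table with header.
#' @param column_map Named character vector mapping logical fields (names of
#'   [csm_columns()]) to the file's column names.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @return A CSM tibble (see [csm_tibble()]).
#' @export
read_csm_table <- function(path, column_map = csm_columns(),
                           decoy_prefix = "REV_") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  required <- csm_required_fields()
  missing_req <- required[!column_map[required] %in% names(raw)]
  if (length(missing_req) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(column_map[missing_req], collapse = ", ")),
          class = "xlinkfdr_config_error")
  }
  out <- tibble(.rows = nrow(raw))
  for (field in names(csm_columns())) {
    col <- column_map[[field]] %||% field
    out[[field]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  # line numbers in error messages count the header as line 1
  parse_num <- function(field, as_int = FALSE) {
    v <- out[[field]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf("cannot parse %s value '%s' on line %d",
                    field, v[bad[1]], bad[1] + 1L),
            class = "xlinkfdr_parse_error")
    }
    if (as_int) as.integer(parsed) else parsed
  }
  for (f in csm_integer_fields()) out[[f]] <- parse_num(f, as_int = TRUE)
  out$score <- parse_num("score")
  if (all(is.na(out$delta_score))) {
    warn("no delta_score column: the delta-score prefilter is disabled")
    out$delta_score <- NA_real_
  } else {
    out$delta_score <- parse_num("delta_score")
  }
  na_req <- required[purrr::map_lgl(required, ~ anyNA(out[[.x]]))]
  if (length(na_req) > 0) {
    field <- na_req[1]
    abort(sprintf("missing %s value on line %d", field,
                  which(is.na(out[[field]]))[1] + 1L),
          class = "xlinkfdr_parse_error")
  }
  out$positions_a[is.na(out$positions_a)] <- "1"
  out$positions_b[is.na(out$positions_b)] <- "1"
  out$crosslinker_id[is.na(out$crosslinker_id)] <- ""
  out$noncovalent_flag <- !is.na(out$noncovalent_flag) &
    tolower(out$noncovalent_flag) %in% c("true", "t", "1", "yes")
  for (side in c("a", "b")) {
    flag_col <- paste0("is_decoy_", side)
    derived <- first_accession_is_decoy(out[[paste0("proteins_", side)]],
                                        decoy_prefix)
    if (all(is.na(out[[flag_col]]))) {
      out[[flag_col]] <- derived
    } else {
      explicit <- tolower(out[[flag_col]]) %in% c("true", "t", "1", "yes")
      # a prefix-bearing accession flagged non-decoy is a contradiction;
      # the converse (flag TRUE, no prefix) is a legitimate engine style
      clash <- which(derived & !explicit)
      if (length(clash) > 0) {
        abort(sprintf(
          "decoy flag and accession prefix disagree on line %d (peptide %s)",
          clash[1] + 1L, side), class = "xlinkfdr_parse_error")
      }
      out[[flag_col]] <- explicit
    }
  }
  validate_csms(out)
}

#' Write a CSM table to TSV
#'
#' Inverse of [read_csm_table()] under default column names: writing and
#' re-reading round-trips all canonical columns.
#'
#' @param csms A CSM tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csm_table <- function(csms, path) {
  readr::write_tsv(csms[, names(csm_columns())], path, progress = FALSE)
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' @param path FASTA file path.
#' @param decoy_prefix Accession prefix marking decoy entries.
#' @param entrapment_accessions Character vector of accessions to flag as
#'   entrapment (foreign) proteins.
#' @return A protein tibble (see [protein_table()]).
#' @export
read_protein_fasta <- function(path, decoy_prefix = "REV_",
                               entrapment_accessions = character()) {
  seqs <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(seqs))
  pt <- protein_table(acc, as.character(seqs), decoy_prefix = decoy_prefix)
  pt$is_entrapment <- pt$accession %in% entrapment_accessions |
    pt$base_accession %in% entrapment_accessions
  pt
}

#' Write a protein database to FASTA
#'
#' @param proteins A protein tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$accession))
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Read / write protein elution profiles
#'
#' Elution profiles are stored as a wide table: one row per protein, an
#' `accession` column, then one numeric column per SEC fraction (iBAQ scale;
#' 0 where the protein was not identified in a fraction).
#'
#' @param path TSV file path.
#' @return A wide tibble of profiles.
#' @export
read_elution_profiles <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    accession = "c", .default = "d"), progress = FALSE)
  if (!"accession" %in% names(x)) {
    abort("profiles table must have an 'accession' column",
          class = "xlinkfdr_config_error")
  }
  x
}

#' @rdname read_elution_profiles
#' @param profiles A wide profile tibble.
#' @export
write_elution_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path, progress = FALSE)
  invisible(path)
}

# Abundance vector for one protein; absent proteins elute nowhere (all 0).
profile_vector <- function(profiles, accession) {
  mat <- as.matrix(profiles[, setdiff(names(profiles), "accession")])
  i <- match(accession, profiles$accession)
  if (is.na(i)) rep(0, ncol(mat)) else as.numeric(mat[i, ])
}

#' Write an aggregated results table
#'
#' Writes matches of a single identification level with their q-values as a
#' TSV, ordered by descending score then key so output is stable.
#'
#' @param matches An aggregated match tibble (one level) with a `q_value`
#'   column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(matches, path) {
  lv <- unique(matches$level)
  if (length(lv) > 1) {
    abort("matches mix identification levels; write one level at a time")
  }
  cols <- intersect(
    c("level", "key", "protein_1", "protein_2", "score", "q_value",
      "decoy_class", "is_self", "n_csm", "n_residue_pairs"),
    names(matches))
  out <- matches |>
    arrange(desc(.data$score), .data$key) |>
    select(all_of(cols))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
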