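#' Construct a protein table
#'
#' The protein table is the package's representation of a search database:
#' one row per sequence entry, carrying decoy and entrapment flags, the
#' accession with any decoy prefix stripped (`base_accession`) and the
#' lysine + arginine residue count (`kr_count`) used by the search-space
#' normalisation factors of the error controls.
#'
#' @param accession Character vector of unique accessions.
#' @param sequence Character vector of amino-acid sequences (upper case).
#' @param is_decoy Logical; defaults to detecting `decoy_prefix`.
#' @param is_entrapment Logical flag for entrapment (foreign) entries.
#' @param decoy_prefix Accession prefix marking decoys (default `"REV_"`).
#' @return A tibble with columns `accession`, `sequence`, `is_decoy`,
#'   `is_entrapment`, `base_accession`, `kr_count`.
#' @examples
#' protein_table(c("P1", "REV_P1"), c("ACKR", "RKCA"))
#' @export
protein_table <- function(accession, sequence,
                          is_decoy = NULL, is_entrapment = FALSE,
                          decoy_prefix = "REV_") {
  if (anyDuplicated(accession)) {
    abort(paste0("duplicate accession(s): ",
                 paste(unique(accession[duplicated(accession)]), collapse = ", ")))
  }
  if (any(!nzchar(sequence))) abort("empty protein sequence")
  if (is.null(is_decoy)) is_decoy <- startsWith(accession, decoy_prefix)
  tibble(
    accession = as.character(accession),
    sequence = toupper(sequence),
    is_decoy = is_decoy,
    is_entrapment = rep_len(is_entrapment, length(accession)),
    base_accession = strip_decoy_prefix(accession, decoy_prefix),
    kr_count = kr_count(sequence)
  )
}

#' Count lysine and arginine residues
#'
#' K + R content approximates the number of tryptic peptides a protein can
#' contribute and therefore its share of the random search space; ratios of
#' K+R totals are the normalisation factors of the entrapment and
#' non-crosslinkable error estimates.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Integer vector of K + R counts.
#' @export
kr_count <- function(sequence) {
  stringr::str_count(toupper(sequence), "[KR]")
}

#' @rdname protein_table
#' @param x Character vector of accessions.
#' @export
strip_decoy_prefix <- function(x, decoy_prefix = "REV_") {
  sub(paste0("^", escape_regex(decoy_prefix)), "", x)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Unmodified peptide sequence: modifications are opaque non-upper-case
# annotations (e.g. "Mox", "Ccm", "K[+138.07]") and are never interpreted.
strip_mods <- function(x) gsub("[^A-Z]", "", gsub("\\[[^]]*\\]", "", x))

peptide_length <- function(x) nchar(strip_mods(x))
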