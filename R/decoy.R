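#' Generate a decoy protein
#'
#' Decoy sequences model random matching: the target sequence is reversed,
#' then, scanning the reversed sequence left to right, every
#' enzyme-specific residue (K or R for trypsin) at position 2 or later is
#' swapped with its preceding residue; a leading enzyme residue stays in
#' place. The swap keeps the tryptic cleavage structure (and hence the
#' peptide-mass distribution) of the decoy close to the target while the
#' amino-acid composition, length and K+R count are preserved exactly.
#'
#' @param proteins A protein tibble of targets.
#' @param enzyme_residues Residues defining cleavage sites (default `K`, `R`).
#' @param decoy_prefix Prefix prepended to the decoy accession.
#' @return A protein tibble of decoys (same row count).
#' @examples
#' make_decoy(protein_table("P1", "ACKDEFR"))$sequence # "RFEKDCA"
#' @export
make_decoy <- function(proteins, enzyme_residues = c("K", "R"),
                       decoy_prefix = "REV_") {
  if (any(!nzchar(proteins$sequence))) abort("empty protein sequence")
  rev_seq <- purrr::map_chr(strsplit(proteins$sequence, ""), function(chars) {
    r <- rev(chars)
    n <- length(r)
    if (n >= 2) {
      for (i in 2:n) {
        if (r[i] %in% enzyme_residues) {
          tmp <- r[i - 1]
          r[i - 1] <- r[i]
          r[i] <- tmp
        }
      }
    }
    paste(r, collapse = "")
  })
  protein_table(paste0(decoy_prefix, proteins$accession), rev_seq,
                is_decoy = TRUE, is_entrapment = proteins$is_entrapment,
                decoy_prefix = decoy_prefix)
}

#' Append decoys to a target database
#'
#' One decoy per target, including entrapment entries; the result has twice
#' as many records as the input.
#'
#' @inheritParams make_decoy
#' @return Protein tibble of targets followed by their decoys.
#' @export
make_decoy_db <- function(proteins, enzyme_residues = c("K", "R"),
                          decoy_prefix = "REV_") {
  if (any(proteins$is_decoy)) {
    abort("input already contains decoys", class = "xlinkfdr_config_error")
  }
  bind_rows(proteins, make_decoy(proteins, enzyme_residues, decoy_prefix))
}
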