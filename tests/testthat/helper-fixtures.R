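# fixtures built in code: small random CSM tables and bare match tibbles,
# independent of the simulator so they can serve as oracles for it

random_sequence <- function(n, len = 12) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "K", "L", "R", "S", "V"),
                 len, replace = TRUE), collapse = "")
  }, character(1))
}

# CSMs over a small protein universe; decoy sides use the REV_ prefix
random_csms <- function(n, seed = 42, n_proteins = 8, decoy_rate = 0.3) {
  set.seed(seed)
  accs <- paste0("P", seq_len(n_proteins))
  pick <- function() {
    a <- sample(accs, n, replace = TRUE)
    dec <- runif(n) < decoy_rate
    ifelse(dec, paste0("REV_", a), a)
  }
  prot_a <- pick(); prot_b <- pick()
  csm_tibble(
    spectrum_id = sprintf("s%04d", seq_len(n)),
    sequence_a = random_sequence(n), link_pos_a = sample(1:10, n, TRUE),
    proteins_a = prot_a,
    sequence_b = random_sequence(n), link_pos_b = sample(1:10, n, TRUE),
    proteins_b = prot_b,
    positions_a = as.character(sample(1:200, n, TRUE)),
    positions_b = as.character(sample(1:200, n, TRUE)),
    matched_fragments_a = sample(3:12, n, TRUE),
    matched_fragments_b = sample(3:12, n, TRUE),
    precursor_charge = sample(3:5, n, TRUE),
    score = round(runif(n, 1, 20), 3),
    delta_score = NULL
  )
}

# bare csm-level match tibble for FDR-curve tests, one unique key per row
toy_matches <- function(scores, classes, self = FALSE, level = "csm") {
  n <- length(scores)
  self <- rep_len(self, n)
  acc1 <- ifelse(self, "A", "A")
  acc2 <- ifelse(self, "A", "B")
  tibble::tibble(
    level = level,
    key = sprintf("k%04d", seq_len(n)),
    score = scores,
    decoy_class = classes,
    is_self = self,
    n_csm = 1L,
    support = as.list(sprintf("s%04d", seq_len(n))),
    pep_key = sprintf("pep%04d", seq_len(n)),
    res_key = sprintf("res%04d", seq_len(n)),
    ppi_key = paste0(acc1, "--", acc2),
    protein_1 = acc1, protein_2 = acc2,
    crosslinker_id = "XL"
  )
}

# brute-force q-values: recompute the FDR at every prefix independently
brute_force_q <- function(scores, classes) {
  decoy_rank <- c(DD = 0, TD = 1, TT = 2)
  ord <- order(-scores, decoy_rank[classes])
  s <- scores[ord]; cl <- classes[ord]
  n <- length(s)
  fdr <- vapply(seq_len(n), function(i) {
    TT <- sum(cl[1:i] == "TT"); TD <- sum(cl[1:i] == "TD")
    DD <- sum(cl[1:i] == "DD")
    raw <- if (TT == 0) { if (TD - DD <= 0) 0 else 1 } else (TD - DD) / TT
    min(max(raw, 0), 1)
  }, numeric(1))
  q <- vapply(seq_len(n), function(i) min(fdr[i:n]), numeric(1))
  list(order = ord, fdr = fdr, q = q)
}
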