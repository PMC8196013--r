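#' Configuration of the synthetic crosslink benchmark
#'
#' Defines a ground-truth scenario: a proteome with log-normal abundances
#' spanning several orders of magnitude, a set of true protein-protein
#' interactions whose members coelute, true CSMs drawn on those
#' interactions (and on self links) with abundance-dependent sampling, and
#' false CSMs drawn from the random search space, where a heteromeric false
#' match is `het_random_weight` times more likely than a self one and each
#' peptide is independently a decoy with probability 1/2 — so the expected
#' TD - DD count equals the number of false target-target matches, the
#' premise that makes decoy-based FDR estimates testable against the truth.
#'
#' @param n_proteins Number of target proteins (>= 10).
#' @param n_fractions Number of SEC fractions for elution profiles.
#' @param abundance_sigma Standard deviation of log10 abundance (1.0 spans
#'   roughly six orders of magnitude over a proteome).
#' @param n_true_ppis Number of true heteromeric interactions.
#' @param n_true_csms,n_false_csms True / false CSM draws.
#' @param self_fraction_true Fraction of true CSMs that are self links.
#' @param het_random_weight Relative random-space weight of heteromeric
#'   versus self false matches (default 10: a false match is ten times more
#'   likely to be heteromeric).
#' @param score_true,score_false Length-2 numeric `(mean, sd)` of the match
#'   score distributions; the true mean must exceed the false mean.
#' @param entrapment_fraction Fraction of targets flagged as entrapment
#'   (excluded from true interactions by construction).
#' @param crosslinker_id Label stored on every simulated CSM.
#' @param seed Integer seed; all randomness flows from it.
#' @return An `xl_sim_config` list.
#' @export
sim_config <- function(n_proteins = 500L, n_fractions = 44L,
                       abundance_sigma = 1.0, n_true_ppis = 300L,
                       n_true_csms = 5000L, n_false_csms = 5000L,
                       self_fraction_true = 0.7, het_random_weight = 10,
                       score_true = c(7, 1.5), score_false = c(3.5, 1.5),
                       entrapment_fraction = 0, crosslinker_id = "XL",
                       seed = 1L) {
  if (n_proteins < 10) abort("n_proteins must be at least 10",
                             class = "xlinkfdr_config_error")
  if (any(c(n_true_ppis, n_true_csms, n_false_csms) < 0)) {
    abort("counts must be non-negative", class = "xlinkfdr_config_error")
  }
  if (self_fraction_true < 0 || self_fraction_true > 1 ||
      entrapment_fraction < 0 || entrapment_fraction > 1) {
    abort("fractions must lie in [0, 1]", class = "xlinkfdr_config_error")
  }
  if (score_true[1] <= score_false[1]) {
    abort("true score mean must exceed false score mean",
          class = "xlinkfdr_config_error")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_fractions = as.integer(n_fractions),
         abundance_sigma = abundance_sigma,
         n_true_ppis = as.integer(n_true_ppis),
         n_true_csms = as.integer(n_true_csms),
         n_false_csms = as.integer(n_false_csms),
         self_fraction_true = self_fraction_true,
         het_random_weight = het_random_weight,
         score_true = score_true, score_false = score_false,
         entrapment_fraction = entrapment_fraction,
         crosslinker_id = crosslinker_id,
         seed = as.integer(seed)),
    class = "xl_sim_config")
}

# residue frequencies of an average bacterial proteome; K + R ~ 11 %
aa_frequencies <- function() {
  c(A = 0.089, R = 0.055, N = 0.040, D = 0.054, C = 0.012, E = 0.058,
    Q = 0.044, G = 0.074, H = 0.022, I = 0.060, L = 0.095, K = 0.058,
    M = 0.026, F = 0.039, P = 0.042, S = 0.055, T = 0.054, W = 0.014,
    Y = 0.028, V = 0.081)
}

#' Simulate a proteome with elution profiles
#'
#' Generates random protein sequences at realistic K/R density, log-normal
#' abundances, a set of true heteromeric interactions among non-entrapment
#' proteins (abundance-weighted, since detectable complexes are made of
#' detectable proteins), elution profiles in which interaction partners
#' share a peak fraction, and an appended decoy database.
#'
#' @param config An [sim_config()] object.
#' @return A list: `proteins` (targets + decoys), `profiles` (wide tibble,
#'   one column per fraction), `true_ppis` (tibble of true protein pairs
#'   with canonical keys), `config`.
#' @export
simulate_proteome <- function(config) {
  set.seed(config$seed)
  n <- config$n_proteins
  freq <- aa_frequencies()
  lens <- sample(100:400, n, replace = TRUE)
  seqs <- purrr::map_chr(lens, ~ paste(
    sample(names(freq), .x, replace = TRUE, prob = freq), collapse = ""))
  acc <- sprintf("SP%04d", seq_len(n))
  n_ent <- round(config$entrapment_fraction * n)
  is_ent <- c(rep(FALSE, n - n_ent), rep(TRUE, n_ent))
  targets <- protein_table(acc, seqs, is_decoy = FALSE, is_entrapment = is_ent)
  abundance <- 10^rnorm(n, 6.5, config$abundance_sigma)

  # true PPIs among non-entrapment proteins, abundance weighted
  eligible <- which(!is_ent)
  w <- abundance[eligible]
  pairs <- matrix(integer(0), ncol = 2)
  seen <- character(0)
  while (nrow(pairs) < config$n_true_ppis) {
    need <- config$n_true_ppis - nrow(pairs)
    i <- eligible[sample.int(length(eligible), need, replace = TRUE, prob = w)]
    j <- eligible[sample.int(length(eligible), need, replace = TRUE, prob = w)]
    ok <- i != j
    cand <- cbind(pmin(i[ok], j[ok]), pmax(i[ok], j[ok]))
    key <- paste(cand[, 1], cand[, 2])
    fresh <- !key %in% seen & !duplicated(key)
    pairs <- rbind(pairs, cand[fresh, , drop = FALSE])
    seen <- c(seen, key[fresh])
  }
  true_ppis <- tibble(
    protein_1 = pmin(acc[pairs[, 1]], acc[pairs[, 2]]),
    protein_2 = pmax(acc[pairs[, 1]], acc[pairs[, 2]]),
    ppi_key = paste(.data$protein_1, .data$protein_2, sep = "--")
  )

  # interaction components share an elution peak
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) comp[a] <- b
  }
  root <- vapply(seq_len(n), find, integer(1))
  nf <- config$n_fractions
  peak_of_root <- setNames(sample(4:(nf - 3), length(unique(root)),
                                  replace = TRUE), unique(root))
  peak <- peak_of_root[as.character(root)]
  width <- runif(n, 1.5, 3.0)
  fr <- seq_len(nf)
  prof <- t(vapply(seq_len(n), function(i) {
    v <- abundance[i] * exp(-(fr - peak[i])^2 / (2 * width[i]^2)) *
      exp(rnorm(nf, 0, 0.3))
    v[v < 1e4] <- 0  # below detection limit
    v
  }, numeric(nf)))
  profiles <- as_tibble(setNames(as.data.frame(prof), paste0("f", fr)))
  profiles <- dplyr::bind_cols(tibble(accession = acc), profiles)

  proteins <- make_decoy_db(targets)
  proteins$abundance <- abundance[match(proteins$base_accession, acc)]
  list(proteins = proteins, profiles = profiles, true_ppis = true_ppis,
       abundance = setNames(abundance, acc), config = config)
}

# tryptic digestion intervals (start, end) with peptide length >= min_len
digest_intervals <- function(sequence, min_len = 6L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  ends <- sort(unique(c(which(chars %in% c("K", "R")), n)))
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- (ends - starts + 1L) >= min_len
  if (!any(keep)) return(cbind(start = 1L, end = n))
  cbind(start = starts[keep], end = ends[keep])
}

# one random link site (interval weighted by length) per protein row index
sample_peptides <- function(proteins, idx) {
  cache <- attr(proteins, "digest_cache")
  n <- length(idx)
  pep <- character(n); start <- integer(n); link <- integer(n)
  for (k in seq_len(n)) {
    iv <- cache[[idx[k]]]
    j <- if (nrow(iv) == 1) 1L else
      sample.int(nrow(iv), 1, prob = iv[, 2] - iv[, 1] + 1)
    s <- iv[j, 1]; e <- iv[j, 2]
    pos <- s + sample.int(e - s + 1L, 1) - 1L
    pep[k] <- substr(proteins$sequence[idx[k]], s, e)
    start[k] <- s
    link[k] <- pos - s + 1L
  }
  tibble(accession = proteins$accession[idx], peptide = pep,
         start = start, link = link)
}

with_digest_cache <- function(proteins) {
  attr(proteins, "digest_cache") <- purrr::map(proteins$sequence,
                                               digest_intervals)
  proteins
}

#' Simulate crosslink search output with known ground truth
#'
#' Draws true CSMs on the proteome's true interactions and self links
#' (abundance-weighted, repeated draws giving true PPIs multi-CSM support)
#' and false CSMs from the K/R-weighted random space with independent
#' per-peptide decoy labels. Peptides are genuine tryptic peptides of the
#' (target or decoy) sequences, so the output behaves like search-engine
#' output under deduplication, prefiltering and aggregation. Entrapment
#' proteins participate only in false matches.
#'
#' @param config An [sim_config()] object.
#' @param proteome Output of [simulate_proteome()] for the same config.
#' @return A list: `csms` (CSM tibble), `truth` (per-spectrum tibble with
#'   `is_true`), `true_ppi_keys` (character keys of true protein pairs).
#' @export
simulate_search_output <- function(config, proteome) {
  set.seed(config$seed + 1L)
  proteins <- with_digest_cache(proteome$proteins)
  targets <- proteins[!proteins$is_decoy, ]
  attr(targets, "digest_cache") <-
    attr(proteins, "digest_cache")[which(!proteins$is_decoy)]
  abundance <- proteome$abundance

  n_self_true <- round(config$self_fraction_true * config$n_true_csms)
  n_het_true <- config$n_true_csms - n_self_true

  # pre-defined true residue pairs: a few per interaction / self protein
  het_sites <- NULL
  if (config$n_true_ppis > 0 && n_het_true > 0) {
    idx1 <- match(proteome$true_ppis$protein_1, targets$accession)
    idx2 <- match(proteome$true_ppis$protein_2, targets$accession)
    n_sites <- 1L + rpois(length(idx1), 1.5)
    ppi_id <- rep(seq_along(idx1), n_sites)
    side1 <- sample_peptides(targets, idx1[ppi_id])
    side2 <- sample_peptides(targets, idx2[ppi_id])
    het_sites <- list(ppi_id = ppi_id, side1 = side1, side2 = side2,
                      weight = sqrt(abundance[targets$accession[idx1]] *
                                      abundance[targets$accession[idx2]]))
  }
  ent_free <- which(!targets$is_entrapment)
  self_prot <- sample(ent_free, min(length(ent_free), 250),
                      prob = abundance[targets$accession[ent_free]])
  n_self_sites <- 1L + rpois(length(self_prot), 2)
  self_id <- rep(seq_along(self_prot), n_self_sites)
  self_side1 <- sample_peptides(targets, self_prot[self_id])
  self_side2 <- sample_peptides(targets, self_prot[self_id])

  het_pick <- if (!is.null(het_sites)) {
    sample.int(length(het_sites$ppi_id), n_het_true, replace = TRUE,
               prob = het_sites$weight[het_sites$ppi_id])
  } else integer(0)
  self_weight <- abundance[targets$accession[self_prot]]
  self_pick <- if (length(self_id) > 0 && n_self_true > 0) {
    sample.int(length(self_id), n_self_true, replace = TRUE,
               prob = self_weight[self_id])
  } else integer(0)

  true_rows <- bind_rows(
    if (length(het_pick) > 0) tibble(
      acc_a = het_sites$side1$accession[het_pick],
      pep_a = het_sites$side1$peptide[het_pick],
      start_a = het_sites$side1$start[het_pick],
      link_a = het_sites$side1$link[het_pick],
      acc_b = het_sites$side2$accession[het_pick],
      pep_b = het_sites$side2$peptide[het_pick],
      start_b = het_sites$side2$start[het_pick],
      link_b = het_sites$side2$link[het_pick]),
    if (length(self_pick) > 0) tibble(
      acc_a = self_side1$accession[self_pick],
      pep_a = self_side1$peptide[self_pick],
      start_a = self_side1$start[self_pick],
      link_a = self_side1$link[self_pick],
      acc_b = self_side2$accession[self_pick],
      pep_b = self_side2$peptide[self_pick],
      start_b = self_side2$start[self_pick],
      link_b = self_side2$link[self_pick])
  )
  n_true <- if (is.null(true_rows)) 0L else nrow(true_rows)

  # false matches: K/R-weighted random protein picks, decoys with prob 1/2
  n_false <- config$n_false_csms
  false_rows <- NULL
  if (n_false > 0) {
    p_het <- config$het_random_weight / (config$het_random_weight + 1)
    is_het <- runif(n_false) < p_het
    kr_w <- targets$kr_count
    i1 <- sample.int(nrow(targets), n_false, replace = TRUE, prob = kr_w)
    i2 <- ifelse(is_het,
                 sample.int(nrow(targets), n_false, replace = TRUE, prob = kr_w),
                 i1)
    redraw <- which(is_het & i1 == i2)
    while (length(redraw) > 0) {
      i2[redraw] <- sample.int(nrow(targets), length(redraw), replace = TRUE,
                               prob = kr_w)
      redraw <- redraw[i1[redraw] == i2[redraw]]
    }
    dec1 <- runif(n_false) < 0.5
    dec2 <- runif(n_false) < 0.5
    # decoy peptides come from the decoy partner sequence
    row_of <- function(ti, dec) ifelse(dec, nrow(targets) + ti, ti)
    # proteins table = targets then decoys in the same order
    all_prot <- proteins
    side_a <- sample_peptides(all_prot, row_of(i1, dec1))
    side_b <- sample_peptides(all_prot, row_of(i2, dec2))
    false_rows <- tibble(
      acc_a = side_a$accession, pep_a = side_a$peptide,
      start_a = side_a$start, link_a = side_a$link,
      acc_b = side_b$accession, pep_b = side_b$peptide,
      start_b = side_b$start, link_b = side_b$link)
  }

  rows <- bind_rows(true_rows, false_rows)
  n_all <- nrow(rows)
  is_true <- c(rep(TRUE, n_true), rep(FALSE, n_all - n_true))
  score_mu <- ifelse(is_true, config$score_true[1], config$score_false[1])
  score_sd <- ifelse(is_true, config$score_true[2], config$score_false[2])
  score <- pmax(rnorm(n_all, score_mu, score_sd), 0.01)
  csms <- csm_tibble(
    spectrum_id = sprintf("sp%06d", seq_len(n_all)),
    sequence_a = rows$pep_a, link_pos_a = rows$link_a, proteins_a = rows$acc_a,
    sequence_b = rows$pep_b, link_pos_b = rows$link_b, proteins_b = rows$acc_b,
    positions_a = as.character(rows$start_a),
    positions_b = as.character(rows$start_b),
    matched_fragments_a = 3L + rpois(n_all, ifelse(is_true, 5, 3)),
    matched_fragments_b = 3L + rpois(n_all, ifelse(is_true, 5, 3)),
    precursor_charge = sample(3:5, n_all, replace = TRUE),
    score = score,
    delta_score = score * runif(n_all, 0.2, 0.8),
    crosslinker_id = config$crosslinker_id
  )
  truth <- tibble(spectrum_id = csms$spectrum_id, is_true = is_true)
  list(csms = csms, truth = truth,
       true_ppi_keys = proteome$true_ppis$ppi_key)
}

#' Run one simulated benchmark scenario end to end
#'
#' Convenience wrapper: simulate, prefilter, deduplicate, apply grouped
#' cascaded FDR at the requested level, and measure the realized
#' (ground-truth) false fraction among accepted heteromeric target PPIs.
#'
#' @param config An [sim_config()] object.
#' @param alpha Nominal FDR threshold.
#' @param level Target identification level (default `"ppi"`).
#' @param group_self_separately,cascade Passed to [apply_fdr()].
#' @return A list: `result` (`xl_fdr_result`), `accepted_het` (accepted
#'   heteromeric target PPIs with a `truth_false` flag), `n_accepted`,
#'   `n_false`, `false_fraction`, `proteome`, `search`.
#' @export
run_benchmark <- function(config, alpha = 0.05, level = "ppi",
                          group_self_separately = TRUE, cascade = TRUE) {
  proteome <- simulate_proteome(config)
  search <- simulate_search_output(config, proteome)
  filtered <- filter_csms(search$csms)
  matches <- as_matches(deduplicate_csms(filtered))
  res <- apply_fdr(matches, level = level, alpha = alpha,
                   group_self_separately = group_self_separately,
                   cascade = cascade)
  acc <- res$accepted
  if (level != "ppi") acc <- merge_to_level(as_tibble(acc)[, names(matches)], "ppi")
  het <- acc[!acc$is_self & acc$decoy_class == "TT", ]
  het$truth_false <- !het$ppi_key %in% search$true_ppi_keys
  list(result = res, accepted_het = het,
       n_accepted = nrow(het), n_false = sum(het$truth_false),
       false_fraction = if (nrow(het) == 0) 0 else mean(het$truth_false),
       proteome = proteome, search = search)
}
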