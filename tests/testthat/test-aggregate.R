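test_that("canonicalisation orders sides, is idempotent and symmetric", {
  x <- csm_tibble(c("s1", "s2"),
                  sequence_a = c("ZZZPEP", "AAAPEP"),
                  link_pos_a = c(1, 5),
                  proteins_a = c("P2", "P1"),
                  sequence_b = c("AAAPEP", "AAAPEP"),
                  link_pos_b = c(3, 2),
                  proteins_b = c("P1", "P1"))
  y <- canonicalize_csms(x)
  expect_equal(y$sequence_a, c("AAAPEP", "AAAPEP"))
  expect_equal(y$sequence_b[1], "ZZZPEP")
  # same-sequence pair ordered by link position
  expect_equal(c(y$link_pos_a[2], y$link_pos_b[2]), c(2L, 5L))
  expect_equal(canonicalize_csms(y), y)
  # swapping the input sides changes nothing after canonicalisation
  sw <- x
  for (col in c("sequence", "link_pos", "proteins", "positions", "is_decoy",
                "matched_fragments")) {
    a <- paste0(col, "_a"); b <- paste0(col, "_b")
    tmp <- sw[[a]]; sw[[a]] <- sw[[b]]; sw[[b]] <- tmp
  }
  expect_equal(canonicalize_csms(sw)$sequence_a, y$sequence_a)
  expect_equal(canonicalize_csms(sw)$link_pos_b, y$link_pos_b)
})

test_that("deduplication keeps the best score per key and matches a group-by oracle", {
  base <- csm_tibble(c("s1", "s2"), "AAAPEPK", 3, "P1", "CCCPEPK", 2, "P2",
                     score = c(8, 10))
  one <- deduplicate_csms(base)
  expect_equal(nrow(one), 1)
  expect_equal(one$score, 10)
  # charge differences keep records apart
  two <- dplyr::mutate(base, precursor_charge = c(3L, 4L))
  expect_equal(nrow(deduplicate_csms(two)), 2)
  expect_equal(nrow(deduplicate_csms(two, include_charge = FALSE)), 1)

  # 100 redundant CSMs over 10 keys: brute-force max per key
  set.seed(9)
  keys <- random_csms(10, seed = 9)
  dup <- keys[sample(1:10, 100, replace = TRUE), ]
  dup$spectrum_id <- sprintf("r%03d", 1:100)
  dup$score <- round(runif(100, 1, 30), 3)
  got <- deduplicate_csms(dup)
  expect_equal(nrow(got), 10)
  oracle_key <- paste(pmin(dup$sequence_a, dup$sequence_b),
                      pmax(dup$sequence_a, dup$sequence_b),
                      dup$precursor_charge)
  oracle <- tapply(dup$score, oracle_key, max)
  got_key <- paste(pmin(got$sequence_a, got$sequence_b),
                   pmax(got$sequence_a, got$sequence_b),
                   got$precursor_charge)
  expect_equal(sort(got$score),
               sort(as.numeric(oracle[unique(oracle_key)])))
  expect_setequal(got_key, names(oracle))
})

test_that("decoy class and self classification follow the flags", {
  expect_equal(decoy_class(c(FALSE, FALSE, TRUE, TRUE),
                           c(FALSE, TRUE, FALSE, TRUE)),
               c("TT", "TD", "TD", "DD"))
  expect_equal(classify_self(c("P1", "P1", "P1"), c("P1", "P2", "REV_P1")),
               c(TRUE, FALSE, TRUE))
  expect_error(classify_self("P1;P2", "P3"), "ambiguous")
})

test_that("merging aggregates scores by root sum of squares", {
  m <- toy_matches(c(3, 4), c("TT", "TT"))
  m$ppi_key <- "A--B"
  out <- merge_to_level(m, "ppi")
  expect_equal(out$score, 5)
  expect_equal(out$n_csm, 2L)
  single <- merge_to_level(toy_matches(7.3, "TT"), "ppi")
  expect_equal(single$score, 7.3)
  expect_error(merge_to_level(dplyr::bind_rows(m, single), "ppi"), "mix")
})

test_that("merging 30 residue pairs into PPIs matches a brute-force oracle", {
  set.seed(30)
  m <- toy_matches(round(runif(30, 1, 10), 3), rep("TT", 30),
                   level = "residue_pair")
  ppis <- sprintf("A--B%s", sample(1:7, 30, replace = TRUE))
  m$ppi_key <- ppis
  m$protein_1 <- "A"
  m$protein_2 <- sub("A--", "", ppis)
  out <- merge_to_level(m, "ppi")
  expect_equal(nrow(out), length(unique(ppis)))
  oracle <- tapply(m$score, ppis, function(s) sqrt(sum(s^2)))
  expect_equal(out$score[match(names(oracle), out$key)], as.numeric(oracle))
})

test_that("decoy-involving protein pairs stay separate records", {
  m <- toy_matches(c(5, 6, 7), c("TT", "TD", "DD"))
  m$ppi_key <- "A--B"
  out <- merge_to_level(m, "ppi")
  expect_equal(nrow(out), 3)
  expect_setequal(out$decoy_class, c("TT", "TD", "DD"))
})

test_that("merging is permutation invariant and chain-consistent", {
  csms <- random_csms(80, seed = 31)
  m <- as_matches(deduplicate_csms(csms))
  direct <- merge_to_level(m, "ppi")
  chained <- m |>
    merge_to_level("peptide_pair") |>
    merge_to_level("residue_pair") |>
    merge_to_level("ppi")
  expect_equal(chained$key, direct$key)
  expect_equal(chained$score, direct$score, tolerance = 1e-12)
  expect_equal(chained$n_csm, direct$n_csm)
  expect_equal(sum(direct$n_csm), nrow(m))

  shuffled <- merge_to_level(m[sample(nrow(m)), ], "ppi")
  expect_equal(shuffled$key, direct$key)
  expect_equal(shuffled$score, direct$score)

  # adding support strictly increases the aggregate score
  extra <- m[1, ]
  extra$key <- "extra-key"
  extra$score <- 2.5
  grown <- merge_to_level(dplyr::bind_rows(m, extra), "ppi")
  k <- grown$key == direct$key[match(extra$ppi_key, direct$ppi_key)]
  target <- dplyr::filter(grown, .data$key == extra$ppi_key,
                          .data$decoy_class == extra$decoy_class,
                          .data$is_self == extra$is_self)
  before <- dplyr::filter(direct, .data$key == extra$ppi_key,
                          .data$decoy_class == extra$decoy_class,
                          .data$is_self == extra$is_self)
  expect_gt(target$score, before$score)
})

test_that("residue keys use protein coordinates so missed cleavages collapse", {
  # same residue reached from two peptides with different start positions
  x <- csm_tibble(c("s1", "s2"),
                  sequence_a = c("KAAAPEP", "AAAPEP"),
                  link_pos_a = c(5, 4),
                  proteins_a = "P1",
                  positions_a = c("10", "11"),
                  sequence_b = "CCCPEPK", link_pos_b = 2, proteins_b = "P2",
                  positions_b = "5")
  m <- as_matches(deduplicate_csms(x))
  expect_equal(nrow(m), 2)          # distinct peptide pairs
  expect_equal(dplyr::n_distinct(m$res_key), 1)  # same residue pair (P1:14)
  rp <- merge_to_level(m, "residue_pair")
  expect_equal(nrow(rp), 1)
})
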