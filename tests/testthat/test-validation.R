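test_that("K+R search-space factor matches its closed form", {
  expect_equal(kr_factor(100, 100), 2)
  expect_equal(kr_factor(0, 50), 1)
  expect_equal(kr_factor(9, 100), 1.09)
  expect_true(all(kr_factor(c(0, 5, 500), 10) >= 1))
  expect_error(kr_factor(10, 0), class = "xlinkfdr_config_error")
})

test_that("entrapment sampling picks nearest K+R candidates without replacement", {
  fg <- protein_table(c("F1", "F2"),
                      c(strrep("KA", 10), strrep("KA", 5)))  # kr 10, 5
  cand <- protein_table(c("C04", "C09", "C11"),
                        c(strrep("KG", 4), strrep("KG", 9), strrep("KG", 11)))
  picked <- build_entrapment_db(fg, cand)
  # exhaustive oracle over all 1-to-1 assignments in greedy order:
  # F1 (kr 10) sees distances {6,1,1} -> tie 9 vs 11, equal |len diff|? no:
  # lengths 18 vs 22 against 20 -> both 2, lexicographic picks C09;
  # F2 (kr 5) then takes C04.
  expect_setequal(picked$accession, c("C09", "C04"))
  expect_true(all(picked$is_entrapment))
  expect_error(build_entrapment_db(fg, cand[1, ]),
               class = "xlinkfdr_config_error")
  # exact K+R matches reproduce the foreground K+R total
  cand2 <- protein_table(c("D1", "D2"), c(strrep("RA", 10), strrep("RA", 5)))
  picked2 <- build_entrapment_db(fg, cand2)
  expect_equal(sum(picked2$kr_count), sum(fg$kr_count))
})

test_that("entrapment error applies the documented arithmetic", {
  fg_acc <- sprintf("F%02d", 1:20)
  ent_acc <- sprintf("E%02d", 1:20)
  proteome <- protein_table(c(fg_acc, ent_acc),
                            rep(strrep("KAGA", 10), 40),
                            is_decoy = FALSE,
                            is_entrapment = rep(c(FALSE, TRUE), each = 20))
  ppis <- tibble::tibble(
    protein_1 = c(fg_acc[rep(1:10, 9)], ent_acc[1:10]),
    protein_2 = c(fg_acc[rep(11:20, 9)], fg_acc[1:10]))
  est <- entrapment_error(ppis, proteome)
  expect_equal(est$n_false_control, 10)
  expect_equal(est$raw_fraction, 0.1)
  expect_equal(est$kr_factor, 2)       # equal K+R partitions
  expect_equal(est$corrected_error, 0.2)
  # no entrapment hits -> exactly zero regardless of the factor
  clean <- ppis[1:90, ]
  expect_equal(entrapment_error(clean, proteome)$corrected_error, 0)
  expect_error(entrapment_error(tibble::tibble(protein_1 = "X", protein_2 = "F01"),
                                proteome), "not in proteome")
})

test_that("best lower iBAQ takes the max over fraction-wise minima", {
  expect_equal(best_lower_ibaq(c(0, 8, 2), c(5, 4, 9)), 4)
  expect_equal(best_lower_ibaq(c(7, 0), c(0, 7)), 0)
  expect_error(best_lower_ibaq(1:3, 1:4), "fraction")
  set.seed(55)
  a <- runif(44, 0, 1e7); b <- runif(44, 0, 1e7)
  oracle <- -Inf
  for (i in 1:44) oracle <- max(oracle, min(a[i], b[i]))
  expect_equal(best_lower_ibaq(a, b), oracle)
})

test_that("iBAQ threshold is the nearest-rank lower percentile", {
  profiles <- tibble::tibble(accession = sprintf("P%02d", 1:21))
  # give protein pair k a best-lower value of k via two fractions
  mat <- matrix(0, 21, 2)
  pairs <- tibble::tibble(protein_1 = sprintf("P%02d", 1:20),
                          protein_2 = rep("P21", 20))
  profiles <- dplyr::bind_cols(profiles,
                               tibble::tibble(f1 = c(1:20, 1e9),
                                              f2 = rep(0, 21)))
  expect_equal(ibaq_threshold(pairs, profiles), 1)
  same <- tibble::tibble(protein_1 = rep("P05", 25), protein_2 = "P21")
  expect_equal(ibaq_threshold(same, profiles), 5)
  expect_error(ibaq_threshold(pairs[0, ], profiles), "pairs")
  # sort-and-index oracle on a large random instance
  set.seed(56)
  n <- 400
  prof2 <- tibble::tibble(accession = sprintf("Q%03d", 1:(n + 1)))
  prof2$f1 <- c(runif(n, 0, 1e7), 1e9)
  prof2$f2 <- 0
  pairs2 <- tibble::tibble(protein_1 = sprintf("Q%03d", 1:n),
                           protein_2 = sprintf("Q%03d", n + 1))
  vals <- sort(pmin(prof2$f1[1:n], 1e9))
  expect_equal(ibaq_threshold(pairs2, prof2), vals[ceiling(0.05 * n)])
})

test_that("plausibility equals best-lower-iBAQ above threshold", {
  profiles <- tibble::tibble(accession = c("A", "B", "C"),
                             f1 = c(5e6, 6e6, 0), f2 = c(0, 1e7, 2e6))
  pairs <- tibble::tibble(protein_1 = c("A", "A", "A"),
                          protein_2 = c("B", "C", "Z"))
  pl <- classify_plausible(pairs, profiles, 4.3e6)
  expect_equal(pl, c(TRUE, FALSE, FALSE))
  # equivalence with best_lower_ibaq on random profiles
  set.seed(57)
  accs <- sprintf("R%02d", 1:12)
  prof <- dplyr::bind_cols(tibble::tibble(accession = accs),
                           as.data.frame(matrix(runif(12 * 10, 0, 10), 12)))
  names(prof)[-1] <- paste0("f", 1:10)
  rp <- tibble::tibble(protein_1 = sample(accs, 30, TRUE),
                       protein_2 = sample(accs, 30, TRUE))
  for (thr in c(1, 3, 7)) {
    got <- classify_plausible(rp, prof, thr)
    oracle <- purrr::map2_lgl(rp$protein_1, rp$protein_2, function(p, q) {
      best_lower_ibaq(xlinkfdr:::profile_vector(prof, p),
                      xlinkfdr:::profile_vector(prof, q)) > thr
    })
    expect_equal(got, oracle)
  }
  # monotone non-increasing in the threshold
  n1 <- sum(classify_plausible(rp, prof, 1))
  n2 <- sum(classify_plausible(rp, prof, 5))
  expect_gte(n1, n2)
})

test_that("non-crosslinkable error combines counts with the K+R factor", {
  accs <- sprintf("N%03d", 1:40)
  proteome <- protein_table(accs, rep(strrep("KAAG", 25), 40))
  ppis <- tibble::tibble(protein_1 = accs[1:20], protein_2 = accs[21:40])
  plausible <- rep(c(TRUE, FALSE), c(18, 2))
  est <- noncrosslinkable_error(ppis, plausible, proteome)
  expect_equal(est$raw_fraction, 2 / 20)
  # 36 distinct plausible proteins vs 4 false proteins, equal kr each
  expect_equal(est$kr_factor, (36 + 4) / 4)
  expect_equal(est$corrected_error, 0.1 * 10)
  expect_equal(noncrosslinkable_error(ppis, rep(TRUE, 20),
                                      proteome)$corrected_error, 0)
  expect_error(noncrosslinkable_error(ppis, plausible[-1], proteome),
               "classified")
})

test_that("wrong-crosslinker error doubles the observed fraction", {
  acc <- tibble::tibble(crosslinker_id = rep(c("BS3", "BS3wrong"), c(95, 5)))
  est <- wrong_crosslinker_error(acc, "BS3", "BS3wrong")
  expect_equal(est$raw_fraction, 0.05)
  expect_equal(est$corrected_error, 0.10)
  none <- tibble::tibble(crosslinker_id = rep("BS3", 10))
  expect_equal(wrong_crosslinker_error(none, "BS3", "BS3wrong")$corrected_error, 0)
  bad <- tibble::tibble(crosslinker_id = "DSSO")
  expect_error(wrong_crosslinker_error(bad, "BS3", "BS3wrong"), "unknown")
})

test_that("tidy methods expose error estimates as one-row tibbles", {
  est <- wrong_crosslinker_error(
    tibble::tibble(crosslinker_id = rep(c("a", "b"), c(9, 1))), "a", "b")
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$corrected_error, est$corrected_error)
  expect_equal(glance(est), td)
})
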