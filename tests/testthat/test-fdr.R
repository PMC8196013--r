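test_that("pointwise FDR follows the decoy formula with clamping", {
  expect_equal(fdr_point(95, 10, 5), 5 / 95)
  expect_equal(fdr_point(100, 0, 0), 0)
  expect_equal(fdr_point(50, 2, 4), 0)   # TD < DD clamps to zero
  expect_equal(fdr_point(0, 3, 0), 1)
  expect_equal(fdr_point(0, 0, 3), 0)
  expect_error(fdr_point(-1, 0, 0), "non-negative")
})

test_that("curve prefixes accumulate the documented counts", {
  m <- toy_matches(10:5, c("TT", "TT", "TD", "TT", "DD", "TT"))
  cv <- build_fdr_curve(m, group_self_separately = FALSE)
  last <- cv[nrow(cv), ]
  expect_equal(c(last$TT, last$TD, last$DD), c(4L, 1L, 1L))
  expect_equal(last$fdr, 0)
})

test_that("all-decoy input yields q = 1 everywhere", {
  m <- toy_matches(c(9, 7, 5), c("TD", "TD", "TD"))
  cv <- build_fdr_curve(m, group_self_separately = FALSE)
  expect_true(all(cv$q_value == 1))
})

test_that("q-values equal an O(n^2) brute-force prefix recomputation", {
  set.seed(77)
  for (n in c(50, 500)) {
    scores <- round(runif(n, 0, 30), 1)  # duplicate scores exercise ties
    classes <- sample(c("TT", "TD", "DD"), n, TRUE, prob = c(0.7, 0.2, 0.1))
    m <- toy_matches(scores, classes)
    cv <- build_fdr_curve(m, group_self_separately = FALSE)
    oracle <- brute_force_q(scores, classes)
    expect_equal(cv$q_value, oracle$q)
    expect_true(all(diff(cv$q_value) >= 0))  # non-decreasing as score drops
  }
})

test_that("self and heteromeric groups are estimated separately", {
  # decoy-rich heteromeric space interleaved with a large clean self space:
  # combined estimation dilutes the heteromeric decoy density and lets
  # extra heteromeric matches through
  het <- toy_matches(
    c(seq(10, 1, length.out = 100), seq(9.9, 1, length.out = 30)),
    c(rep("TT", 100), rep("TD", 30)), self = FALSE)
  self <- toy_matches(c(seq(10, 1, length.out = 600), rep(0.5, 3)),
                      c(rep("TT", 600), rep("TD", 3)), self = TRUE)
  self$key <- paste0("self-", self$key)
  m <- dplyr::bind_rows(het, self)
  grouped <- apply_fdr(m, level = "csm", alpha = 0.05,
                       group_self_separately = TRUE, cascade = FALSE)
  combined <- apply_fdr(m, level = "csm", alpha = 0.05,
                        group_self_separately = FALSE, cascade = FALSE)
  n_het_grouped <- sum(!grouped$accepted$is_self)
  n_het_combined <- sum(!combined$accepted$is_self)
  expect_lt(n_het_grouped, n_het_combined)
  expect_error(apply_fdr(m, alpha = 1.5), class = "xlinkfdr_config_error")
})

test_that("acceptance at alpha matches brute-force q-values", {
  set.seed(79)
  m <- toy_matches(round(runif(40, 0, 10), 2),
                   sample(c("TT", "TD", "DD"), 40, TRUE,
                          prob = c(0.6, 0.3, 0.1)))
  res <- apply_fdr(m, level = "csm", alpha = 0.3, cascade = FALSE,
                   group_self_separately = FALSE)
  oracle <- brute_force_q(m$score, m$decoy_class)
  accepted_keys <- m$key[oracle$order][oracle$q <= 0.3 &
                                         m$decoy_class[oracle$order] == "TT"]
  expect_setequal(res$accepted$key, accepted_keys)
})

test_that("near-1 alpha accepts every target with q < 1", {
  m <- toy_matches(c(9, 8, 2, 1), c("TT", "TT", "TT", "TD"))
  res <- apply_fdr(m, level = "csm", alpha = 1 - 1e-9, cascade = FALSE,
                   group_self_separately = FALSE)
  cv <- build_fdr_curve(m, group_self_separately = FALSE)
  expect_equal(nrow(res$accepted), sum(cv$q_value < 1 & cv$decoy_class == "TT"))
})

test_that("local-FDR normalisation maps score runs to [0, 1] as documented", {
  # pure high-score target run, pure decoy tail
  m <- toy_matches(c(100:51, 50:1),
                   c(rep("TT", 50), rep("TD", 50)))
  norm <- normalize_scores(m, window = 21, group_self_separately = FALSE)
  norm <- norm[order(-norm$score), ]
  expect_equal(norm$normalized_score[1:10], rep(1, 10))  # no decoys in window
  expect_equal(norm$normalized_score[91:100], rep(0, 10))
  expect_true(all(norm$normalized_score >= 0 & norm$normalized_score <= 1))
  expect_true(all(diff(norm$normalized_score) <= 0))
  # direct window arithmetic: TT=40, TD=8, DD=2 -> local fdr 0.15
  expect_equal(xlinkfdr:::fdr_point(40, 8, 2), 0.15)
  expect_error(normalize_scores(m, window = 10),
               class = "xlinkfdr_config_error")
})

test_that("windows shrink for groups smaller than the window", {
  m <- toy_matches(c(9, 7, 3), c("TT", "TT", "TD"))
  norm <- normalize_scores(m, window = 101, group_self_separately = FALSE)
  expect_equal(nrow(norm), 3)
  expect_true(all(is.finite(norm$normalized_score)))
})

test_that("merging a dataset with itself reproduces its own acceptance set", {
  set.seed(80)
  csms <- random_csms(150, seed = 80)
  m <- merge_to_level(as_matches(deduplicate_csms(csms)), "ppi")
  norm <- normalize_scores(m, window = 11)
  single <- dplyr::mutate(norm, score = .data$normalized_score)
  res_single <- apply_fdr(single, level = "ppi", alpha = 0.5, cascade = FALSE)
  res_merged <- merge_datasets(norm, norm, alpha = 0.5)
  expect_setequal(res_merged$accepted$key, res_single$accepted$key)
})

test_that("disjoint datasets concatenate to the brute-force curve", {
  a <- toy_matches(c(9, 6, 3), c("TT", "TT", "TD"))
  b <- toy_matches(c(8, 5, 2), c("TT", "TD", "TT"))
  b$key <- paste0("b-", b$key)
  a$normalized_score <- c(0.9, 0.6, 0.3)
  b$normalized_score <- c(0.8, 0.5, 0.2)
  res <- merge_datasets(a, b, alpha = 0.99)
  oracle <- brute_force_q(c(a$normalized_score, b$normalized_score),
                          c(a$decoy_class, b$decoy_class))
  expect_equal(res$curve$q_value, oracle$q)
  expect_error(merge_datasets(a, dplyr::mutate(b, level = "ppi"), 0.5),
               "levels")
})
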