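#' Normalise an elution profile to its maximum
#'
#' @param x Numeric abundance vector over fractions; must have a positive
#'   maximum.
#' @return The vector divided by its maximum, values in \[0, 1\].
#' @export
normalize_profile <- function(x) {
  m <- max(x)
  if (!is.finite(m) || m <= 0) {
    abort("profile not quantified (all zero)", class = "xlinkfdr_data_error")
  }
  x / m
}

#' Correlate two elution profiles around their peaks
#'
#' Detects elution peaks of each (normalised) profile, forms the window of
#' fractions within `half_width` of any peak of either protein (clipped to
#' the valid range), and computes the Pearson correlation over that window
#' when it spans at least `min_window` fractions. Pairs whose window is too
#' small or has zero variance on either side get an undefined correlation
#' and are never called similar.
#'
#' @param a,b Normalised profiles (see [normalize_profile()]), equal length.
#' @param min_window Minimum window size in fractions (default 7).
#' @param r_threshold Correlation above which profiles are called similar
#'   (default 0.5).
#' @param half_width Fractions kept on each side of a peak (default 3).
#' @return A list: `r` (Pearson correlation or `NA`), `similar` (logical),
#'   `window` (integer fraction indices).
#' @export
correlate_pair <- function(a, b, min_window = 7L, r_threshold = 0.5,
                           half_width = 3L) {
  if (length(a) != length(b)) abort("profiles differ in fraction count")
  peaks <- sort(unique(c(profile_peaks(a), profile_peaks(b))))
  window <- sort(unique(unlist(lapply(
    peaks, function(p) max(1L, p - half_width):min(length(a), p + half_width)))))
  r <- NA_real_
  if (length(window) >= min_window &&
      stats::sd(a[window]) > 0 && stats::sd(b[window]) > 0) {
    r <- cor(a[window], b[window])
  }
  list(r = r, similar = isTRUE(r > r_threshold), window = window)
}

# strict local maxima; a plateau counts once at its leftmost fraction
profile_peaks <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  run_start <- which(c(TRUE, x[-1] != x[-n]))          # starts of equal runs
  run_val <- x[run_start]
  run_end <- c(run_start[-1] - 1L, n)
  k <- length(run_start)
  left <- c(-Inf, run_val[-k])
  right <- c(run_val[-1], -Inf)
  run_start[run_val > left & run_val > right & run_val > 0]
}

#' Coelution support among accepted PPIs
#'
#' Proportion of accepted protein pairs whose elution profiles are similar
#' (Pearson correlation above `r_threshold` in the peak window); pairs with
#' a missing profile are not similar. Also reports the stricter `r > 0.8`
#' tier.
#'
#' @param accepted_ppis Tibble with `protein_1`, `protein_2` columns.
#' @param profiles Wide elution profile tibble (raw iBAQ; normalisation is
#'   applied internally).
#' @param r_threshold Similarity threshold (default 0.5).
#' @param min_window,half_width Window parameters of [correlate_pair()].
#' @return A one-row tibble: `n_ppis`, `n_similar`, `support_fraction`,
#'   `n_high`, `high_fraction` (the `r > 0.8` tier).
#' @export
coelution_support <- function(accepted_ppis, profiles, r_threshold = 0.5,
                              min_window = 7L, half_width = 3L) {
  rs <- purrr::map2_dbl(accepted_ppis$protein_1, accepted_ppis$protein_2,
                        function(p1, p2) {
    a <- profile_vector(profiles, p1)
    b <- profile_vector(profiles, p2)
    if (max(a) <= 0 || max(b) <= 0) return(NA_real_)
    correlate_pair(normalize_profile(a), normalize_profile(b),
                   min_window = min_window, half_width = half_width,
                   r_threshold = r_threshold)$r
  })
  tibble(
    n_ppis = nrow(accepted_ppis),
    n_similar = sum(rs > r_threshold, na.rm = TRUE),
    support_fraction = if (nrow(accepted_ppis) == 0) 0 else
      sum(rs > r_threshold, na.rm = TRUE) / nrow(accepted_ppis),
    n_high = sum(rs > 0.8, na.rm = TRUE),
    high_fraction = if (nrow(accepted_ppis) == 0) 0 else
      sum(rs > 0.8, na.rm = TRUE) / nrow(accepted_ppis)
  )
}

#' Average elution profile of a protein complex
#'
#' @param members List of raw abundance vectors of equal length (one per
#'   complex component).
#' @return Element-wise mean abundance vector.
#' @export
complex_profile <- function(members) {
  if (length(members) == 0) abort("no complex members")
  lens <- lengths(members)
  if (length(unique(lens)) != 1) abort("profiles differ in fraction count")
  Reduce(`+`, members) / length(members)
}
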