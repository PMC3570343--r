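#' Exact hypergeometric point probability
#'
#' P(X = k) when n items are drawn without replacement from a population of
#' N containing M marked items, computed from log binomial coefficients so
#' populations of 10^3-10^4 do not overflow.
#'
#' @param k marked items in the sample.
#' @param n sample size.
#' @param M marked items in the population.
#' @param N population size.
#' @return the point probability.
#' @export
hypergeom_point <- function(k, n, M, N) {
  check_hg(k, n, M, N)
  if (k > M || (n - k) > (N - M)) return(0)
  exp(lchoose(M, k) + lchoose(N - M, n - k) - lchoose(N, n))
}

check_hg <- function(k, n, M, N) {
  v <- c(k = k, n = n, M = M, N = N)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    stop("k, n, M, N must be non-negative integers")
  if (k > n || n > N || M > N)
    stop("need 0 <= k <= n <= N and 0 <= M <= N")
  invisible(TRUE)
}

#' One-sided cumulative hypergeometric tail
#'
#' Under-representation is judged by the lower tail P(X <= k), over-
#' representation by the upper tail P(X >= k). Summation is exact, term by
#' term in log space over the feasible range of k.
#'
#' @inheritParams hypergeom_point
#' @param direction `"under"` (lower tail) or `"over"` (upper tail).
#' @return the tail probability.
#' @export
hypergeom_tail <- function(k, n, M, N, direction = c("under", "over")) {
  direction <- match.arg(direction)
  check_hg(k, n, M, N)
  lo <- max(0, n - (N - M))
  hi <- min(n, M)
  ks <- if (direction == "under") lo:min(k, hi) else max(k, lo):hi
  if (direction == "under" && k < lo) return(0)
  if (direction == "over" && k > hi) return(0)
  lg <- lchoose(M, ks) + lchoose(N - M, n - ks) - lchoose(N, n)
  mx <- max(lg)
  min(1, exp(mx) * sum(exp(lg - mx)))
}

#' Taxonomic-group enrichment test for one supergroup
#'
#' For each Venn category containing the sample supergroup's letter, pairs
#' it with the corresponding category lacking that letter (ABEV vs ABE, BEV
#' vs BE, AV vs A, ...). With k the size of the with-letter category, M the
#' size of the without-letter category, n the supergroup's total FSF
#' repertoire and N the total retained FSFs, the direction is "over" when
#' k/n > M/N and the P-value is the matching one-sided hypergeometric tail.
#'
#' @param groups a group assignment from [assign_groups()].
#' @param sample_supergroup supergroup letter defining the sample (e.g. "V").
#' @param alpha significance level for the `significant` flag.
#' @return data frame with columns comparison, k, n, M, N, direction, p,
#'   significant (one row per category pair; pairs whose background category
#'   is empty are kept with M = 0 and a warning).
#' @export
enrichment_table <- function(groups, sample_supergroup, alpha = 0.05) {
  stopifnot(sample_supergroup %in% SUPERGROUPS)
  tally <- groups$tally
  N <- sum(tally)
  letter <- sample_supergroup
  with_letter <- names(tally)[grepl(letter, names(tally))]
  n <- sum(tally[with_letter])
  rows <- lapply(setdiff(with_letter, letter), function(cat_with) {
    cat_without <- gsub(letter, "", cat_with)
    k <- as.integer(tally[cat_with])
    M <- if (cat_without %in% names(tally)) as.integer(tally[cat_without]) else 0L
    if (M == 0)
      warning("empty background category ", cat_without, " for ", cat_with)
    direction <- if (k / n > M / N) "over" else "under"
    p <- hypergeom_tail(k, n, M, N, direction)
    data.frame(comparison = paste0(cat_with, "_", cat_without),
               k = k, n = n, M = M, N = N,
               direction = direction, p = p,
               significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
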