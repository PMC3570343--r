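#' Bootstrap support for a parsimony tree
#'
#' Resamples characters (columns) with replacement, reruns a reduced search
#' per replicate, and returns the majority-rule consensus annotated with the
#' percentage of replicates containing each internal bipartition. The
#' replicate split sets are returned so supports can be recounted.
#'
#' @param coded a `coded_matrix`.
#' @param config a [search_config()]; `bootstrap_replicates` and
#'   `boot_addition_sequences` control the effort.
#' @return list with `consensus` (phylo; `node.label` holds supports),
#'   `supports` (named vector, one entry per consensus bipartition),
#'   `replicate_splits` (list of split sets, one per replicate).
#' @export
mp_bootstrap <- function(coded, config = search_config()) {
  states <- coded_states(coded)
  C <- ncol(states)
  set.seed(config$seed + 1L)
  rep_trees <- vector("list", config$bootstrap_replicates)
  rep_splits <- vector("list", config$bootstrap_replicates)
  for (b in seq_len(config$bootstrap_replicates)) {
    cols <- sample.int(C, C, replace = TRUE)
    bs <- states[, cols, drop = FALSE]
    colnames(bs) <- sprintf("c%d", seq_len(C))
    bcoded <- new_coded_matrix(bs, coded$orientation, coded$ancestral_state)
    bcfg <- config
    bcfg$n_addition_sequences <- config$boot_addition_sequences
    bcfg$swap <- "NNI"
    bcfg$seed <- config$seed + 1000L + b
    res <- mp_search(bcoded, bcfg)
    ut <- ut_from_phylo(res$trees[[1]])
    rep_trees[[b]] <- res$trees[[1]]
    rep_splits[[b]] <- ut_splits(ut)
  }
  keys <- lapply(rep_splits, function(s) vapply(s, paste, "", collapse = ","))
  all_keys <- unlist(keys)
  freq <- table(all_keys) / config$bootstrap_replicates * 100
  maj <- names(freq)[freq > 50]
  cons <- ape::consensus(lapply(rep_trees, ape::unroot), p = 0.5)
  ucons <- ut_from_phylo(cons)
  cons_splits <- ut_splits(ucons)
  cons_keys <- vapply(cons_splits, paste, "", collapse = ",")
  supports <- as.numeric(freq[cons_keys])
  names(supports) <- cons_keys
  list(consensus = cons, supports = supports,
       replicate_splits = rep_splits, majority_keys = maj)
}

#' Per-character and ensemble parsimony fit statistics
#'
#' For each ordered character: `s` = steps on the tree, `m` = minimum
#' conceivable steps (state range max - min), `g_star` = maximum conceivable
#' steps (the optimum on a completely unresolved star tree, minimized over
#' the integer center), consistency index `ci = m/s` and retention index
#' `ri = (g_star - s) / (g_star - m)`. Characters with `g_star = m`
#' (parsimony-uninformative) get `ri = NA` and are excluded from the
#' ensemble RI. Ensemble CI and RI use the summed quantities.
#'
#' @param phy a `phylo` tree over the coded taxa.
#' @param coded a `coded_matrix`.
#' @return list with `per_character` (data frame: character, s, m, g_star,
#'   ci, ri, informative) and `ensemble_ci`, `ensemble_ri`.
#' @export
fit_statistics <- function(phy, coded) {
  states <- coded_states(coded)[phy$tip.label, , drop = FALSE]
  s <- tree_length(phy, coded, per_character = TRUE)
  rng_min <- apply(states, 2, min)
  rng_max <- apply(states, 2, max)
  m <- as.numeric(rng_max - rng_min)
  g_star <- vapply(seq_len(ncol(states)), function(j) {
    v <- rng_min[j]:rng_max[j]
    min(vapply(v, function(c0) sum(abs(states[, j] - c0)), 0))
  }, 0)
  ci <- ifelse(s > 0, m / s, NA_real_)
  informative <- g_star > m
  ri <- ifelse(informative, (g_star - s) / (g_star - m), NA_real_)
  per_char <- data.frame(character = colnames(states), s = s, m = m,
                         g_star = g_star, ci = ci, ri = ri,
                         informative = informative, row.names = NULL)
  list(per_character = per_char,
       ensemble_ci = sum(m) / sum(s),
       ensemble_ri = (sum(g_star) - sum(s)) / (sum(g_star) - sum(m)))
}

#' Skewness g1 of the tree-length distribution over random topologies
#'
#' Scores `n_random_trees` uniformly sampled unrooted topologies and returns
#' the standardized third-moment skewness of their lengths. Strongly
#' tree-structured data give left-skewed (negative g1) distributions.
#'
#' @param coded a `coded_matrix`.
#' @param n_random_trees number of random topologies (>= 3).
#' @param seed integer seed.
#' @return g1 value (NaN, flagged by attribute `degenerate`, when all
#'   sampled lengths are equal).
#' @export
g1_skewness <- function(coded, n_random_trees = 1000, seed = 1) {
  stopifnot(n_random_trees >= 3)
  states <- coded_states(coded)
  set.seed(seed)
  lens <- vapply(seq_len(n_random_trees), function(i) {
    phy <- ape::rtopology(nrow(states), rooted = FALSE,
                          tip.label = rownames(states))
    ut_score(ut_from_phylo(phy), states)
  }, 0)
  mu <- mean(lens)
  m2 <- mean((lens - mu)^2)
  if (m2 == 0) return(structure(NaN, degenerate = TRUE))
  m3 <- mean((lens - mu)^3)
  structure(m3 / m2^1.5, degenerate = FALSE)
}
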