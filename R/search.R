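#' Search configuration for maximum-parsimony tree reconstruction
#'
#' @param n_addition_sequences number of random-addition-sequence starts.
#' @param swap branch-swapping scheme: `"NNI"` or `"SPR"` (`"SPR"` also runs
#'   NNI implicitly, as every NNI is an SPR move).
#' @param max_trees_held cap on equally parsimonious trees retained.
#' @param seed integer seed; mandatory, all randomness in the search derives
#'   from it.
#' @param bootstrap_replicates replicates used by [mp_bootstrap()].
#' @param boot_addition_sequences addition sequences per bootstrap replicate
#'   (fewer than the final search, for speed).
#' @return a `search_config` list.
#' @export
search_config <- function(n_addition_sequences = 5, swap = c("SPR", "NNI"),
                          max_trees_held = 8, seed = 1,
                          bootstrap_replicates = 100,
                          boot_addition_sequences = 1) {
  swap <- match.arg(swap)
  stopifnot(n_addition_sequences >= 1, max_trees_held >= 1,
            bootstrap_replicates >= 1, boot_addition_sequences >= 1)
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  structure(list(n_addition_sequences = as.integer(n_addition_sequences),
                 swap = swap, max_trees_held = as.integer(max_trees_held),
                 seed = as.integer(seed),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 boot_addition_sequences = as.integer(boot_addition_sequences)),
            class = "search_config")
}

coded_states <- function(coded) {
  stopifnot(inherits(coded, "coded_matrix"))
  coded$states
}

# one random-addition-sequence stepwise-addition tree (internal)
stepwise_tree <- function(states, order) {
  taxa <- rownames(states)[order]
  ut <- ut_new(taxa[1:3])
  for (t in taxa[-(1:3)]) {
    unit <- linear_cost_profile(states[t, ])
    costs <- ut_attach_costs(ut, states, unit)
    e <- which.min(costs)  # first minimum: deterministic tie-break
    ut <- ut_insert_tip(ut, e, t)$ut
  }
  ut
}

# best-improvement NNI sweep; returns list(ut, score, improved)
nni_sweep <- function(ut, states, cur) {
  improved <- FALSE
  repeat {
    better <- FALSE
    for (v in ut_edges(ut)) {
      if (!length(ut$children[[v]])) next       # internal edges only
      p <- ut$parent[v]
      sibs <- setdiff(ut$children[[p]], v)
      kids <- ut$children[[v]]
      for (w in sibs) {
        for (x in kids) {
          ut2 <- ut
          ut2$children[[p]][ut2$children[[p]] == w] <- x
          ut2$children[[v]][ut2$children[[v]] == x] <- w
          ut2$parent[w] <- v; ut2$parent[x] <- p
          s2 <- ut_score(ut2, states)
          if (s2 < cur) {
            ut <- ut2; cur <- s2; better <- TRUE; improved <- TRUE
            break
          }
        }
        if (better) break
      }
      if (better) break
    }
    if (!better) break
  }
  list(ut = ut, score = cur, improved = improved)
}

# one best-improvement SPR pass over all prunable subtrees
spr_sweep <- function(ut, states, cur) {
  improved <- FALSE
  repeat {
    better <- FALSE
    for (v in ut_edges(ut)) {
      p <- ut$parent[v]
      if (p == ut$root && length(ut$children[[ut$root]]) <= 3 &&
          sum(vapply(setdiff(ut$children[[ut$root]], v),
                     function(x) length(ut$children[[x]]) > 0, TRUE)) == 0)
        next  # pruning would leave no internal junction
      base <- tryCatch(ut_prune(ut, v), error = function(e) NULL)
      if (is.null(base)) next
      Usub <- sankoff_up(ut, states)[[v]]   # subtree vectors (ids preserved)
      unit <- minconv_linear(Usub)
      costs <- ut_attach_costs(base, states, unit)
      e <- which.min(costs)
      s2 <- costs[e]
      if (!is.na(s2) && s2 < cur) {
        ut <- ut_attach_subtree(base, e, v)
        cur <- s2; better <- TRUE; improved <- TRUE
        break
      }
    }
    if (!better) break
  }
  list(ut = ut, score = cur, improved = improved)
}

# canonical string key of an unrooted topology, for duplicate filtering
topology_key <- function(ut) {
  splits <- ut_splits(ut)
  paste(sort(vapply(splits, paste, "", collapse = ",")), collapse = ";")
}

# list of non-trivial bipartitions; each canonicalized as the sorted side
# not containing the alphabetically first taxon
ut_splits <- function(ut) {
  tips <- ut_tips(ut)
  all_labels <- sort(ut$label[tips])
  first <- all_labels[1]
  out <- list()
  for (v in ut_edges(ut)) {
    if (!length(ut$children[[v]])) next
    side <- sort(ut$label[intersect(ut_subtree_nodes(ut, v), tips)])
    if (length(side) < 2 || length(side) > length(all_labels) - 2) next
    if (first %in% side) side <- sort(setdiff(all_labels, side))
    out[[length(out) + 1]] <- side
  }
  unique(out)
}

#' Maximum-parsimony search over tree topologies
#'
#' Random-addition-sequence stepwise addition followed by branch swapping
#' (NNI or SPR) under ordered 24-state Wagner parsimony. All equally optimal
#' topologies found are retained (up to `config$max_trees_held`) and each is
#' Lundberg-rooted with the declared ancestral state.
#'
#' @param coded a `coded_matrix`.
#' @param config a [search_config()].
#' @return an object of class `mp_search`: list with `trees` (rooted ape
#'   phylo objects), `length` (unrooted optimum, steps), `rooted_length`
#'   (steps including the hypothetical-ancestor edge of the first tree), and
#'   `config`.
#' @export
mp_search <- function(coded, config = search_config()) {
  states <- coded_states(coded)
  n <- nrow(states)
  if (n < 3) stop("need at least 3 taxa")
  if (n == 3) {
    ut <- ut_new(rownames(states))
    best <- list(ut); bl <- ut_score(ut, states)
  } else {
    set.seed(config$seed)
    best <- list(); bl <- Inf
    for (rep in seq_len(config$n_addition_sequences)) {
      ord <- if (rep == 1) seq_len(n) else sample.int(n)
      ut <- stepwise_tree(states, ord)
      cur <- ut_score(ut, states)
      repeat {
        r <- nni_sweep(ut, states, cur)
        ut <- r$ut; cur <- r$score
        if (config$swap == "SPR") {
          r <- spr_sweep(ut, states, cur)
          ut <- r$ut; cur <- r$score
          if (!r$improved) break
        } else break
      }
      if (cur < bl - 1e-9) { best <- list(ut); bl <- cur }
      else if (abs(cur - bl) < 1e-9 && length(best) < config$max_trees_held) {
        keys <- vapply(best, topology_key, "")
        if (!topology_key(ut) %in% keys) best <- c(best, list(ut))
      }
    }
  }
  rooted <- lapply(best, function(u)
    lundberg_root_ut(u, states, coded$ancestral_state))
  structure(list(trees = lapply(rooted, `[[`, "tree"),
                 length = bl,
                 rooted_length = rooted[[1]]$length,
                 tie = rooted[[1]]$tie,
                 config = config),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("MP search: %d optimal topolog%s, %d steps unrooted (%d Lundberg-rooted)\n",
              length(x$trees), if (length(x$trees) == 1) "y" else "ies",
              as.integer(x$length), as.integer(x$rooted_length)))
  invisible(x)
}

# Lundberg rooting on the internal representation
lundberg_root_ut <- function(ut, states, ancestral_state) {
  anc_vec <- rep(as.integer(ancestral_state), ncol(states))
  unit <- linear_cost_profile(anc_vec)
  costs <- ut_attach_costs(ut, states, unit)
  e <- which.min(costs)
  len <- costs[e]
  tie <- sum(abs(costs - len) < 1e-9, na.rm = TRUE) > 1
  # root the tree at the attachment point on edge e: insert a root junction
  p <- ut$parent[e]
  m <- ut_n_nodes(ut) + 1L
  ut$parent <- c(ut$parent, 0L)
  ut$children[[p]][ut$children[[p]] == e] <- m
  ut$parent[e] <- m
  ut$children[[m]] <- c(e, p)
  ut$label <- c(ut$label, NA)
  # reorient the path from p up to the old root so all edges point away from m
  path <- integer(0); x <- p
  while (x != 0L) { path <- c(path, x); x <- ut$parent[x] }
  prev <- m
  for (x in path) {
    oldp <- ut$parent[x]
    ut$parent[x] <- prev
    ut$children[[x]] <- setdiff(ut$children[[x]], prev)
    if (oldp != 0L) ut$children[[x]] <- c(ut$children[[x]], oldp)
    prev <- x
  }
  ut$root <- m
  phy <- ut_to_phylo(ut)
  list(tree = phy, length = unname(len), tie = tie)
}

#' Lundberg rooting of an unrooted tree
#'
#' Attaches a hypothetical ancestor bearing the declared ancestral state at
#' every character to the edge that minimizes total tree length, and returns
#' the tree rooted at that attachment point. No outgroup is required. Ties
#' are broken by the first edge in the deterministic traversal order and
#' flagged.
#'
#' @param phy an unrooted `phylo` tree over the coded taxa.
#' @param coded a `coded_matrix` with `ancestral_state` set.
#' @return list with `tree` (rooted phylo), `length` (steps, including
#'   changes on the ancestor edge) and `tie` (logical).
#' @export
lundberg_root <- function(phy, coded) {
  states <- coded_states(coded)
  miss <- setdiff(phy$tip.label, rownames(states))
  if (length(miss)) stop("taxa missing from coded matrix: ",
                         paste(miss, collapse = ", "))
  ut <- ut_from_phylo(phy)
  lundberg_root_ut(ut, states[phy$tip.label, , drop = FALSE],
                   coded$ancestral_state)
}

#' Parsimony length of a tree under ordered 24-state characters
#'
#' @param phy a `phylo` tree (rooted or unrooted) whose tips are rows of the
#'   coded matrix.
#' @param coded a `coded_matrix`.
#' @param root_state optional state 0-23 to which the basal node is
#'   constrained (used with rooted trees and declared ancestral states).
#' @param per_character return the per-character step counts instead of the
#'   total.
#' @return total steps, or a numeric vector of per-character steps.
#' @export
tree_length <- function(phy, coded, root_state = NULL, per_character = FALSE) {
  states <- coded_states(coded)
  miss <- setdiff(phy$tip.label, rownames(states))
  if (length(miss)) stop("tips lack states: ", paste(miss, collapse = ", "))
  if (!is.null(root_state)) {
    ntip <- length(phy$tip.label)
    nn <- ntip + phy$Nnode
    parent <- integer(nn); children <- rep(list(integer(0)), nn)
    for (k in seq_len(nrow(phy$edge))) {
      parent[phy$edge[k, 2]] <- phy$edge[k, 1]
      children[[phy$edge[k, 1]]] <- c(children[[phy$edge[k, 1]]], phy$edge[k, 2])
    }
    ut <- list(parent = parent, children = children,
               label = c(phy$tip.label, rep(NA, phy$Nnode)), root = ntip + 1L)
    return(ut_score(ut, states[phy$tip.label, , drop = FALSE],
                    root_state = as.integer(root_state),
                    per_character = per_character))
  }
  ut <- ut_from_phylo(phy)
  ut_score(ut, states[phy$tip.label, , drop = FALSE],
           per_character = per_character)
}
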