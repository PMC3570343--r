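# Internal mutable-ish tree representation used by the parsimony engine.
#
# An unrooted binary tree is held rooted at an arbitrary internal junction
# ("root") with three children; every other internal node has two. Nodes are
# integer ids into parallel vectors; each non-root node has exactly one
# parent, so an *edge* is identified by its child node id. This makes edge
# enumeration, tip insertion and subtree pruning O(1) bookkeeping, with a
# fresh postorder computed on demand. Conversion to/from ape's phylo happens
# only at the package boundary.

ut_new <- function(labels3) {
  stopifnot(length(labels3) == 3)
  list(parent = c(0L, 1L, 1L, 1L),
       children = list(c(2L, 3L, 4L), integer(0), integer(0), integer(0)),
       label = c(NA, labels3),
       root = 1L)
}

ut_n_nodes <- function(ut) length(ut$parent)

ut_tips <- function(ut) which(!is.na(ut$label))

# edges are the non-root nodes (edge = link to parent)
ut_edges <- function(ut) setdiff(seq_along(ut$parent), ut$root)

ut_postorder <- function(ut) {
  # iterative DFS from root; returns node ids children-before-parents
  n <- ut_n_nodes(ut)
  order <- integer(n)
  stack <- ut$root
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order[k] <- v
    kids <- ut$children[[v]]
    if (length(kids)) stack <- c(stack, kids)
  }
  rev(order[seq_len(k)])
}

# insert a new tip above node `edge`; returns list(ut, new_tip_id)
ut_insert_tip <- function(ut, edge, label) {
  p <- ut$parent[edge]
  stopifnot(p != 0L)
  m <- ut_n_nodes(ut) + 1L   # new junction
  t <- m + 1L                # new tip
  ut$parent <- c(ut$parent, p, m)
  ut$children[[p]][ut$children[[p]] == edge] <- m
  ut$parent[edge] <- m
  ut$children[[m]] <- c(edge, t)
  ut$children[[t]] <- integer(0)
  ut$label <- c(ut$label, NA, label)
  list(ut = ut, tip = t)
}

# attach an existing (detached) subtree rooted at node `sub` above `edge`
ut_attach_subtree <- function(ut, edge, sub) {
  p <- ut$parent[edge]
  m <- ut_n_nodes(ut) + 1L
  ut$parent <- c(ut$parent, p)
  ut$children[[p]][ut$children[[p]] == edge] <- m
  ut$parent[edge] <- m
  ut$parent[sub] <- m
  ut$children[[m]] <- c(edge, sub)
  ut$label <- c(ut$label, NA)
  ut
}

# prune the subtree rooted at `v` (v != root); the parent junction is
# suppressed. Returns the modified tree; node ids are preserved (the pruned
# nodes simply become unreachable), so `v` can be re-attached later.
ut_prune <- function(ut, v) {
  m <- ut$parent[v]
  ut$parent[v] <- 0L
  if (m == ut$root) {
    rest <- setdiff(ut$children[[m]], v)
    if (length(rest) < 2) stop("cannot prune: tree too small")
    # pick an internal remaining child as the new root junction
    intl <- rest[vapply(rest, function(x) length(ut$children[[x]]) > 0, TRUE)]
    if (!length(intl)) stop("cannot prune: resulting tree trivial")
    nr <- intl[1]
    other <- setdiff(rest, nr)
    ut$children[[nr]] <- c(ut$children[[nr]], other)
    ut$parent[other] <- nr
    ut$parent[nr] <- 0L
    ut$children[[m]] <- integer(0)
    ut$root <- nr
  } else {
    q <- ut$parent[m]
    w <- setdiff(ut$children[[m]], v)
    ut$children[[q]][ut$children[[q]] == m] <- w
    ut$parent[w] <- q
    ut$parent[m] <- 0L
    ut$children[[m]] <- integer(0)
  }
  ut
}

# reachable nodes of the subtree rooted at v
ut_subtree_nodes <- function(ut, v) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, x)
    stack <- c(stack, ut$children[[x]])
  }
  out
}

ut_to_phylo <- function(ut) {
  po <- ut_postorder(ut)
  tips <- po[vapply(po, function(v) length(ut$children[[v]]) == 0, TRUE)]
  internals <- po[vapply(po, function(v) length(ut$children[[v]]) > 0, TRUE)]
  ntip <- length(tips)
  id <- integer(ut_n_nodes(ut))
  id[tips] <- seq_len(ntip)
  # ape wants the root numbered ntip+1
  internals <- c(ut$root, setdiff(internals, ut$root))
  id[internals] <- ntip + seq_along(internals)
  kids <- setdiff(po, ut$root)
  edge <- cbind(id[ut$parent[kids]], id[kids])
  phy <- list(edge = edge, tip.label = ut$label[tips],
              Nnode = length(internals))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

ut_from_phylo <- function(phy) {
  ntip <- length(phy$tip.label)
  if (ntip < 3) stop("need at least 3 taxa")
  nn <- ntip + phy$Nnode
  parent <- integer(nn)
  children <- rep(list(integer(0)), nn)
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]; c <- phy$edge[k, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- ntip + 1L
  label <- c(phy$tip.label, rep(NA, phy$Nnode))
  ut <- list(parent = parent, children = children, label = label, root = root)
  # a rooted binary tree has a 2-child root: suppress it so the structure is
  # the unrooted topology expected by the scorer
  if (length(children[[root]]) == 2) {
    kids <- children[[root]]
    intl <- kids[vapply(kids, function(x) length(children[[x]]) > 0, TRUE)]
    if (length(intl)) {
      nr <- intl[1]
      other <- setdiff(kids, nr)
      ut$children[[nr]] <- c(ut$children[[nr]], other)
      ut$parent[other] <- nr
      ut$parent[nr] <- 0L
      ut$children[[root]] <- integer(0)
      ut$root <- nr
    }
  }
  ut
}
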