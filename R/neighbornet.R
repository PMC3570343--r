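#' Uncorrected-P distances from a presence/absence matrix
#'
#' The distance between two taxa is the fraction of columns in which they
#' differ (Hamming mismatches / number of columns).
#'
#' @param occ binary matrix, taxa in rows.
#' @return symmetric distance matrix with zero diagonal.
#' @export
uncorrected_p <- function(occ) {
  stopifnot(is.matrix(occ))
  if (ncol(occ) == 0) stop("matrix has zero columns")
  if (nrow(occ) < 2) stop("need at least two taxa")
  x <- (occ > 0) + 0
  # mismatches = x(1-x)' + (1-x)x'
  mm <- x %*% t(1 - x)
  d <- (mm + t(mm)) / ncol(occ)
  dimnames(d) <- list(rownames(occ), rownames(occ))
  d
}

# --- NeighborNet agglomeration ---------------------------------------------
#
# Agglomerative construction of a circular ordering of taxa (Bryant-Moulton
# style). Active nodes live in components that are chains holding at most
# two active ends; joining two chains links one end of each, and any node
# that becomes interior is removed by the 3-to-2 reduction
#   d(u,.) = 2/3 d(x,.) + 1/3 d(y,.)
#   d(v,.) = 1/3 d(y,.) + 2/3 d(z,.)
#   d(u,v) = (d(x,y) + d(y,z) + d(x,z)) / 3
# recorded on a stack so the final 3-cycle expands back to a circular order
# of the original taxa. All ties break toward the smallest node index, so
# the ordering is deterministic in the input order.

#' Circular taxon ordering by the NeighborNet agglomeration
#'
#' @param d symmetric distance matrix with taxon labels.
#' @return character vector: the taxa in circular order (an arbitrary
#'   rotation/reflection of the underlying cyclic ordering). Fewer than 4
#'   taxa return the input order with a note attribute.
#' @export
neighbornet_order <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 4) {
    return(structure(labels, note = "fewer than 4 taxa: trivial order"))
  }
  # node bookkeeping; nodes are rows of D (grown by reductions)
  D <- matrix(0, 2 * n, 2 * n)
  D[1:n, 1:n] <- d
  active <- seq_len(n)
  node_count <- n
  # components: list of integer chains (active node ids, ends first/last)
  comp <- as.list(seq_len(n))
  # links between active nodes within a chain (interior nodes get reduced,
  # so a chain has at most 2 active nodes and at most 1 internal link)
  reductions <- list()

  comp_dist <- function(a, b) mean(D[a, b])

  while (length(active) > 3 && length(comp) >= 2) {
    m <- length(comp)
    # 1. component selection (NJ criterion on component-average distances)
    CD <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      CD[i, j] <- CD[j, i] <- comp_dist(comp[[i]], comp[[j]])
    R <- rowSums(CD)
    best <- c(NA, NA); bq <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * CD[i, j] - R[i] - R[j]
      if (q < bq - 1e-12) { bq <- q; best <- c(i, j) }
    }
    A <- comp[[best[1]]]; B <- comp[[best[2]]]
    others <- comp[-best]
    # 2. endpoint selection among ends of the two chains
    mhat <- (m - 2) + length(A) + length(B)
    endsA <- unique(c(A[1], A[length(A)]))
    endsB <- unique(c(B[1], B[length(B)]))
    sumd <- function(x) {
      s <- sum(vapply(others, function(C) comp_dist(x, C), 0))
      s + sum(D[x, setdiff(c(A, B), x)])
    }
    bx <- NA; by <- NA; bq2 <- Inf
    for (x in endsA) for (y in endsB) {
      q <- (mhat - 2) * D[x, y] - sumd(x) - sumd(y)
      if (q < bq2 - 1e-12) { bq2 <- q; bx <- x; by <- y }
    }
    # 3. join: orient chains so bx and by are adjacent
    chainA <- if (A[length(A)] == bx) A else rev(A)
    chainB <- if (B[1] == by) B else rev(B)
    chain <- c(chainA, chainB)
    comp <- c(others, list(chain))
    # 4. reduce interior nodes left to right while allowed
    ci <- length(comp)
    while (length(comp[[ci]]) >= 3 && length(active) > 3) {
      ch <- comp[[ci]]
      x <- ch[1]; y <- ch[2]; z <- ch[3]
      u <- node_count + 1L; v <- node_count + 2L
      node_count <- node_count + 2L
      if (node_count > nrow(D)) {
        D2 <- matrix(0, 2 * node_count, 2 * node_count)
        D2[seq_len(nrow(D)), seq_len(nrow(D))] <- D
        D <- D2
      }
      rest <- setdiff(active, c(x, y, z))
      D[u, rest] <- D[rest, u] <- 2 / 3 * D[x, rest] + 1 / 3 * D[y, rest]
      D[v, rest] <- D[rest, v] <- 1 / 3 * D[y, rest] + 2 / 3 * D[z, rest]
      D[u, v] <- D[v, u] <- (D[x, y] + D[y, z] + D[x, z]) / 3
      reductions[[length(reductions) + 1]] <- c(u = u, v = v, x = x, y = y, z = z)
      active <- c(setdiff(active, c(x, y, z)), u, v)
      comp[[ci]] <- c(u, v, ch[-(1:3)])
    }
  }
  # close the cycle over the remaining (<= 3 active) nodes
  chains <- comp
  cycle <- unlist(chains)
  # expansion: replace the adjacent pair (u,v) by (x,y,z), x inheriting u's
  # outer neighbor and z inheriting v's. Rotate so u sits at position 1.
  for (r in rev(reductions)) {
    k <- length(cycle)
    iu <- match(r[["u"]], cycle)
    cycle <- c(cycle[iu:k], cycle[seq_len(iu - 1)])
    if (cycle[2] == r[["v"]]) {
      cycle <- c(r[["x"]], r[["y"]], r[["z"]], cycle[-(1:2)])
    } else if (cycle[k] == r[["v"]]) {
      cycle <- c(cycle[2:(k - 1)], r[["z"]], r[["y"]], r[["x"]])
    } else {
      stop("internal error: reduced pair not adjacent in cycle")
    }
  }
  labels[cycle]
}

# all interval splits of a circular order; each split is the set of
# positions 2..n forming a contiguous arc that excludes position 1
interval_splits <- function(n) {
  out <- list()
  for (i in 2:n) for (j in i:n) out[[length(out) + 1]] <- i:j
  out
}

#' Least-squares split weights on a circular ordering
#'
#' Estimates non-negative weights for all interval splits of the circular
#' order by non-negative least squares against the observed distances, and
#' prunes splits with weight below `epsilon`. For distances that are
#' additive on a tree whose splits are compatible with the order, the
#' recovered splits are exactly the tree's splits with weights equal to
#' branch lengths.
#'
#' @param d symmetric distance matrix.
#' @param order circular taxon order, e.g. from [neighbornet_order()].
#' @param epsilon weights below this are dropped (default 1e-9).
#' @return an object of class `split_system`: list with `taxa` (the circular
#'   order), `splits` (list of character vectors; each is the split side not
#'   containing the alphabetically first taxon), `weights`, `order`.
#' @export
split_weights <- function(d, order, epsilon = 1e-9) {
  n <- length(order)
  stopifnot(all(order %in% rownames(d)), n >= 2)
  dv <- d[order, order]
  pairs <- t(utils::combn(n, 2))
  obs <- dv[pairs]
  if (all(obs == 0)) {
    return(new_split_system(order, list(), numeric(0)))
  }
  sp <- interval_splits(n)
  A <- matrix(0, nrow(pairs), length(sp))
  for (s in seq_along(sp)) {
    side <- logical(n); side[sp[[s]]] <- TRUE
    A[, s] <- as.numeric(side[pairs[, 1]] != side[pairs[, 2]])
  }
  w <- pracma::lsqnonneg(A, obs)$x
  keep <- which(w > epsilon)
  splits <- lapply(keep, function(s) sort(order[sp[[s]]]))
  new_split_system(order, splits, w[keep])
}

new_split_system <- function(order, splits, weights, supports = NULL) {
  taxa <- sort(order)
  canon <- lapply(splits, function(s) {
    if (taxa[1] %in% s) sort(setdiff(taxa, s)) else s
  })
  structure(list(taxa = taxa, order = order, splits = canon,
                 weights = weights, supports = supports),
            class = "split_system")
}

split_keys <- function(ss) vapply(ss$splits, paste, "", collapse = ",")

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("split system: %d taxa, %d splits (total weight %.4g)\n",
              length(x$taxa), length(x$splits), sum(x$weights)))
  invisible(x)
}

#' Distances induced by a split system
#'
#' @param ss a `split_system`.
#' @return symmetric matrix of split-decomposition distances.
#' @export
split_distances <- function(ss) {
  n <- length(ss$taxa)
  d <- matrix(0, n, n, dimnames = list(ss$taxa, ss$taxa))
  for (s in seq_along(ss$splits)) {
    inside <- ss$taxa %in% ss$splits[[s]]
    sep <- outer(inside, inside, `!=`)
    d <- d + sep * ss$weights[s]
  }
  d
}

#' NeighborNet split network from a presence/absence matrix
#'
#' Convenience wrapper: uncorrected-P distances, circular ordering,
#' non-negative least-squares split weights.
#'
#' @param occ binary matrix, taxa in rows.
#' @param epsilon weight pruning threshold.
#' @return a `split_system`.
#' @export
neighbornet <- function(occ, epsilon = 1e-9) {
  d <- uncorrected_p(occ)
  ord <- neighbornet_order(d)
  split_weights(d, ord, epsilon = epsilon)
}

#' Bootstrap support for NeighborNet splits
#'
#' Columns are resampled with replacement; each replicate's split system is
#' rebuilt from scratch and a split's support is the percentage of
#' replicates containing it.
#'
#' @param occ binary matrix, taxa in rows.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param epsilon weight pruning threshold.
#' @return a `split_system` with `supports` filled in, plus attribute
#'   `replicate_splits` (list of split-key character vectors).
#' @export
split_bootstrap <- function(occ, replicates = 100, seed = 1, epsilon = 1e-9) {
  stopifnot(replicates >= 1)
  ss <- neighbornet(occ, epsilon = epsilon)
  keys <- split_keys(ss)
  set.seed(seed)
  rep_keys <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(occ), ncol(occ), replace = TRUE)
    rs <- tryCatch(neighbornet(occ[, cols, drop = FALSE], epsilon = epsilon),
                   error = function(e) NULL)
    rep_keys[[b]] <- if (is.null(rs)) character(0) else split_keys(rs)
  }
  counts <- vapply(keys, function(k)
    sum(vapply(rep_keys, function(rk) k %in% rk, TRUE)), 0)
  ss$supports <- counts / replicates * 100
  attr(ss, "replicate_splits") <- rep_keys
  ss
}

#' Write a split system as TSV (bitmask, weight, support)
#'
#' @param ss a `split_system`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_splits <- function(ss, file) {
  mask <- vapply(ss$splits, function(s)
    paste(as.integer(ss$taxa %in% s), collapse = ""), "")
  df <- data.frame(split = split_keys(ss), bitmask = mask,
                   weight = ss$weights,
                   support = if (is.null(ss$supports))
                     rep(NA_real_, length(ss$splits)) else ss$supports)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
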