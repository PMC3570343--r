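# Ordered (Wagner) parsimony scoring by Sankoff dynamic programming with
# linear step costs |i - j| on the 24-state alphabet. Cost vectors are S x C
# matrices (S = 24 states, C = characters) so all characters are scored in
# one vectorized sweep. The min-plus convolution with a linear cost only
# needs a forward and a backward running-minimum pass.

N_STATES <- 24L

BIG <- 1e9  # finite "infinity": keeps arithmetic exact for integer step counts

# min_i (v[i] + |i - j|) for every j, column-wise over characters
minconv_linear <- function(m) {
  S <- nrow(m)
  for (i in 2:S) {
    a <- m[i - 1, ] + 1
    lt <- a < m[i, ]
    if (any(lt)) m[i, lt] <- a[lt]
  }
  for (i in (S - 1):1) {
    a <- m[i + 1, ] + 1
    lt <- a < m[i, ]
    if (any(lt)) m[i, lt] <- a[lt]
  }
  m
}

# leaf cost matrix for a vector of observed states (one per character)
leaf_cost <- function(states, S = N_STATES) {
  C <- length(states)
  m <- matrix(BIG, S, C)
  m[cbind(states + 1L, seq_len(C))] <- 0
  m
}

# |i - j| cost profile of a fixed state vector (used for ancestor taxa)
linear_cost_profile <- function(states, S = N_STATES) {
  outer(0:(S - 1), states, function(i, a) abs(i - a))
}

# Postorder Sankoff sweep. Returns the list of subtree ("up") cost matrices
# indexed by node id, for the tree rooted at ut$root.
sankoff_up <- function(ut, states) {
  po <- ut_postorder(ut)
  U <- vector("list", ut_n_nodes(ut))
  for (v in po) {
    kids <- ut$children[[v]]
    if (!length(kids)) {
      U[[v]] <- leaf_cost(states[ut$label[v], ])
    } else {
      acc <- minconv_linear(U[[kids[1]]])
      for (k in kids[-1]) acc <- acc + minconv_linear(U[[k]])
      U[[v]] <- acc
    }
  }
  U
}

# Total (and optionally per-character) parsimony length of the unrooted tree.
# root_state, if given, constrains the basal junction to that state.
ut_score <- function(ut, states, root_state = NULL, per_character = FALSE) {
  U <- sankoff_up(ut, states)
  rootvec <- U[[ut$root]]
  lens <- if (is.null(root_state)) apply(rootvec, 2, min)
          else rootvec[root_state + 1L, ]
  if (per_character) lens else sum(lens)
}

# "Down" cost matrices: for every non-root node v, J[[v]] is the cost of the
# whole tree minus subtree(v), as a function of the state at parent(v).
# MCJ[[v]] = minconv(J[[v]]) is that cost as seen from just below the edge.
sankoff_down <- function(ut, U) {
  po <- ut_postorder(ut)
  pre <- rev(po)
  n <- ut_n_nodes(ut)
  J <- vector("list", n)
  MCJ <- vector("list", n)
  MCU <- vector("list", n)
  for (v in po) if (!is.null(U[[v]])) MCU[[v]] <- minconv_linear(U[[v]])
  for (p in pre) {
    kids <- ut$children[[p]]
    if (!length(kids)) next
    base <- if (p == ut$root) 0 else MCJ[[p]]
    if (length(kids) == 2) {
      J[[kids[1]]] <- base + MCU[[kids[2]]]
      J[[kids[2]]] <- base + MCU[[kids[1]]]
    } else {
      for (v in kids) {
        acc <- base
        for (s in setdiff(kids, v))
          acc <- if (is.null(acc) || identical(acc, 0)) MCU[[s]] else acc + MCU[[s]]
        J[[v]] <- if (identical(base, 0)) acc else acc
      }
    }
    for (v in kids) {
      if (identical(J[[v]], 0)) J[[v]] <- matrix(0, N_STATES, ncol(U[[ut$root]]))
      MCJ[[v]] <- minconv_linear(J[[v]])
    }
  }
  list(J = J, MCJ = MCJ, MCU = MCU)
}

# Length of the tree with an extra unit attached to each edge.
# `unit_cost` is the S x C cost profile of the attaching unit: for a tip with
# fixed states use linear_cost_profile(); for a pruned subtree pass
# minconv(U[subtree root]). Returns a numeric vector indexed by edge (child
# node id; non-edges are NA).
ut_attach_costs <- function(ut, states, unit_cost, vectors = NULL) {
  if (is.null(vectors)) {
    U <- sankoff_up(ut, states)
    vectors <- c(sankoff_down(ut, U), list(U = U))
  }
  MCU <- vectors$MCU; MCJ <- vectors$MCJ
  out <- rep(NA_real_, ut_n_nodes(ut))
  for (v in ut_edges(ut)) {
    if (is.null(MCU[[v]]) || is.null(MCJ[[v]])) next
    m <- MCU[[v]] + MCJ[[v]] + unit_cost
    best <- m[1, ]
    for (i in 2:N_STATES) {
      lt <- m[i, ] < best
      if (any(lt)) best[lt] <- m[i, lt]
    }
    out[v] <- sum(best)
  }
  out
}
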