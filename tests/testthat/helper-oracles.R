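# Independent oracles and fixture builders used across the suite.

# brute-force ordered parsimony length: enumerate all internal-node state
# assignments over the observed state range (tiny trees only)
brute_ordered_length <- function(phy, states_vec) {
  states_vec <- states_vec[phy$tip.label]
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  rng <- min(states_vec):max(states_vec)
  grids <- do.call(expand.grid, rep(list(rng), nint))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    assign_all <- c(states_vec, as.numeric(grids[r, ]))
    len <- sum(abs(assign_all[phy$edge[, 1]] - assign_all[phy$edge[, 2]]))
    best <- min(best, len)
  }
  best
}

# independent Fitch (unordered binary) parsimony length
fitch_length <- function(phy, states_vec) {
  states_vec <- states_vec[phy$tip.label]
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- states_vec[i]
  po <- ape::reorder.phylo(phy, "postorder")
  len <- 0
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (nd in unique(po$edge[, 1])) {
    acc <- NULL
    for (k in kids[[as.character(nd)]]) {
      if (is.null(acc)) { acc <- sets[[k]]; next }
      inter <- intersect(acc, sets[[k]])
      if (length(inter)) acc <- inter
      else { acc <- union(acc, sets[[k]]); len <- len + 1 }
    }
    sets[[nd]] <- acc
  }
  len
}

# random coded matrix fixture
random_coded <- function(n_taxa, n_char, max_state = 5, seed = 1,
                         ancestral = 0L) {
  set.seed(seed)
  st <- matrix(sample(0:max_state, n_taxa * n_char, replace = TRUE),
               n_taxa, n_char,
               dimnames = list(paste0("t", seq_len(n_taxa)),
                               paste0("c", seq_len(n_char))))
  domcensus:::new_coded_matrix(st, "ToP", ancestral)
}

# small census fixture with a known clade structure
toy_census <- function() {
  asn <- data.frame(
    proteome_id = rep(c("A1", "A2", "B1", "B2", "E1", "E2", "V1"), each = 3),
    css = rep(c("c.37.1", "b.40.4", "a.1.1"), 7),
    count = c(6, 2, 0,  5, 3, 0,  4, 0, 2,  4, 0, 3,
              3, 1, 5,  3, 1, 4,  2, 0, 0))
  met <- data.frame(proteome_id = c("A1", "A2", "B1", "B2", "E1", "E2", "V1"),
                    supergroup = c("A", "A", "B", "B", "E", "E", "V"),
                    lifestyle = c("FL", "FL", "FL", "P", "FL", "FL", "FL"))
  parse_assignments(asn, met)
}
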