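small_cfg <- function(seed = 1, ...) {
  sim_config(n_per_group = 4, n_core = 5, n_primordial = 8, seed = seed, ...)
}

test_that("simulation is deterministic given config and seed", {
  s1 <- simulate_census(small_cfg(7))
  s2 <- simulate_census(small_cfg(7))
  expect_identical(s1$census$g, s2$census$g)
  expect_identical(s1$truth$events, s2$truth$events)
  s3 <- simulate_census(small_cfg(8))
  expect_false(identical(s1$census$g, s3$census$g))
})

test_that("with all rates zero every leaf equals the root genome", {
  cfg <- small_cfg(3, origination_rate = 0, min_internal_originations = 0,
                   duplication_rate = 0, loss_rate = 0,
                   reductive_multiplier = 0)
  sim <- simulate_census(cfg)
  g0 <- round(sim$truth$root_genome)
  for (r in seq_len(nrow(sim$census$g))) {
    expect_equal(unname(sim$census$g[r, names(g0)]), unname(as.integer(g0)))
  }
})

test_that("without loss, column sums never decrease from root to leaves", {
  cfg <- small_cfg(4, loss_rate = 0)
  sim <- simulate_census(cfg)
  g0 <- sim$truth$root_genome
  occ <- occurrence(sim$census)
  # every root FSF is retained in every proteome and at least as abundant
  for (f in names(g0)) {
    expect_true(all(sim$census$g[, f] >= floor(g0[[f]])))
  }
})

test_that("the event log replays to the emitted census cell-for-cell", {
  sim <- simulate_census(small_cfg(9, loss_rate = 0.1, hgt_rate = 0.2))
  rp <- replay_events(sim$truth)
  full <- matrix(0L, nrow(sim$census$g), length(sim$truth$birth_order),
                 dimnames = list(rownames(sim$census$g),
                                 names(sim$truth$birth_order)))
  full[, colnames(sim$census$g)] <- sim$census$g
  expect_identical(rp[rownames(full), colnames(full)], full)
})

test_that("reductive clades have stochastically smaller distinct-FSF counts", {
  sim <- simulate_census(sim_config(seed = 11, loss_rate = 0.15,
                                    reductive_multiplier = 12))
  occ <- occurrence(sim$census)
  sg <- sim$census$proteomes$supergroup
  v_counts <- rowSums(occ[sg == "V", , drop = FALSE])
  e_counts <- rowSums(occ[sg == "E", , drop = FALSE])
  expect_lt(mean(v_counts), mean(e_counts))
})

test_that("without HGT every FSF occupies a connected subtree minus losses", {
  sim <- simulate_census(small_cfg(12, hgt_rate = 0))
  phy <- sim$truth$tree
  ntip <- length(phy$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, desc))
  }
  for (f in colnames(sim$census$g)) {
    born_at <- sim$truth$birth_node[[f]]
    carriers <- rownames(sim$census$g)[sim$census$g[, f] > 0]
    expect_true(all(carriers %in% desc(born_at)), label = f)
  }
})

test_that("birth order is tied to birth time and covers every FSF", {
  sim <- simulate_census(small_cfg(5))
  expect_setequal(names(sim$truth$birth_order), names(sim$truth$birth_time))
  expect_equal(sim$truth$birth_order,
               rank(sim$truth$birth_time, ties.method = "average"))
  expect_true(all(colnames(sim$census$g) %in% names(sim$truth$birth_order)))
})

test_that("recovery report flags taxon mismatches and scores the truth itself", {
  sim <- simulate_census(small_cfg(6))
  rec <- recovery_report(sim$truth, sim$truth$tree)
  expect_equal(rec$rf, 0)
  expect_true(all(rec$monophyly))
  wrong <- ape::rtree(5)
  expect_error(recovery_report(sim$truth, wrong), "taxon mismatch")
})
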