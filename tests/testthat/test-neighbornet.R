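test_that("uncorrected-P counts mismatch fractions", {
  occ <- rbind(a = c(0, 1, 0, 1), b = c(0, 1, 1, 0), c = c(1, 0, 1, 0))
  d <- uncorrected_p(occ)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 1)     # complementary rows
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  occ2 <- rbind(a = c(1, 0), b = c(1, 0))
  expect_equal(uncorrected_p(occ2)["a", "b"], 0)
  expect_error(uncorrected_p(occ[, 0, drop = FALSE]), "zero columns")
})

test_that("tree metrics are recovered exactly: splits, weights, distances", {
  set.seed(31)
  for (i in 1:5) {
    tr <- ape::rtree(8)
    tr$edge.length <- runif(nrow(tr$edge), 0.3, 2)
    d <- ape::cophenetic.phylo(tr)
    ord <- neighbornet_order(d)
    ss <- split_weights(d, ord, epsilon = 1e-8)
    # induced distances match the input to solver tolerance
    ind <- split_distances(ss)
    expect_lt(max(abs(ind[rownames(d), colnames(d)] - d)), 1e-6)
    # non-trivial splits equal the tree's internal splits, weights equal
    # branch lengths
    pp <- ape::prop.part(ape::unroot(tr))
    labs <- attr(pp, "labels")
    all_taxa <- sort(tr$tip.label)
    canon <- function(s) {
      if (all_taxa[1] %in% s) sort(setdiff(all_taxa, s)) else sort(s)
    }
    tree_keys <- vapply(pp[-1], function(cl)
      paste(canon(labs[cl]), collapse = ","), "")
    got <- vapply(ss$splits, paste, "", collapse = ",")
    nontrivial <- ss$splits[vapply(ss$splits, length, 0L) >= 2 &
                              vapply(ss$splits, length, 0L) <= 6]
    expect_setequal(vapply(nontrivial, paste, "", collapse = ","), tree_keys)
    expect_true(all(ss$weights >= 0))
  }
})

test_that("input permutation leaves the recovered split system unchanged", {
  # several circular orders can embed the same split system; what must be
  # invariant under relabeling is the set of weighted splits it supports
  set.seed(32)
  tr <- ape::rtree(7); tr$edge.length <- runif(11, 0.5, 1.5)
  d <- ape::cophenetic.phylo(tr)
  keyset <- function(d) {
    ss <- split_weights(d, neighbornet_order(d), epsilon = 1e-8)
    ord <- order(vapply(ss$splits, paste, "", collapse = ","))
    list(keys = vapply(ss$splits, paste, "", collapse = ",")[ord],
         w = ss$weights[ord])
  }
  k1 <- keyset(d)
  perm <- sample(nrow(d))
  k2 <- keyset(d[perm, perm])
  expect_equal(k1$keys, k2$keys)
  expect_equal(k1$w, k2$w, tolerance = 1e-6)
})

test_that("degenerate inputs are handled: few taxa and zero distances", {
  d3 <- matrix(0.1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  o <- neighbornet_order(d3)
  expect_equal(sort(o), letters[1:3])
  expect_match(attr(o, "note"), "trivial")
  dz <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  ss <- split_weights(dz, letters[1:5])
  expect_length(ss$splits, 0)
})

test_that("a two-cluster design yields one dominant inter-cluster split", {
  taxa <- c(paste0("x", 1:3), paste0("y", 1:3))
  d <- matrix(1, 6, 6, dimnames = list(taxa, taxa))
  d[1:3, 1:3] <- 0.1; d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  ord <- neighbornet_order(d)
  ss <- split_weights(d, ord)
  nontriv <- which(vapply(ss$splits, length, 0L) %in% 2:4)
  big <- nontriv[which.max(ss$weights[nontriv])]
  expect_setequal(ss$splits[[big]], paste0("y", 1:3))
})

test_that("split bootstrap supports are recountable and hit 100 on clean signal", {
  set.seed(33)
  occ <- rbind(matrix(c(1, 0), 4, 10, byrow = FALSE),
               matrix(c(0, 1), 4, 10, byrow = FALSE))
  occ <- cbind(occ, matrix(rbinom(80, 1, 0.5), 8, 10))
  rownames(occ) <- c(paste0("p", 1:4), paste0("q", 1:4))
  colnames(occ) <- paste0("c", 1:20)
  sb <- split_bootstrap(occ, replicates = 20, seed = 5)
  keys <- vapply(sb$splits, paste, "", collapse = ",")
  qkey <- paste(sort(paste0("q", 1:4)), collapse = ",")
  if (qkey %in% keys) {
    expect_equal(unname(sb$supports[keys == qkey]), 100)
  }
  # recount every support from the stored replicate split systems
  reps <- attr(sb, "replicate_splits")
  for (k in seq_along(keys)) {
    manual <- mean(vapply(reps, function(r) keys[k] %in% r, TRUE)) * 100
    expect_equal(unname(sb$supports[k]), manual)
  }
})
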