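#' Configuration for the proteome-evolution simulator
#'
#' The generator evolves FSF content along a known organismal tree: four
#' supergroup clades (V, A, B, E) hang off a ladder-like backbone, viruses
#' diverging first. A small ancestral core of FSFs is present at the root at
#' elevated abundance; along every branch new FSFs originate (Poisson in the
#' branch length), existing counts grow multiplicatively (duplications), and
#' FSF columns are deleted lineage-wise (losses). Reductive clades (V and A)
#' lose *inherited* FSFs — those born outside the clade — at
#' `reductive_multiplier` times the base rate, emulating reductive evolution
#' of the ancient repertoire, while their clade-native FSFs are lost at the
#' base rate. The ancestral core itself is lost at
#' `core_loss_multiplier` times the base rate (0 = an essential, immune
#' core). Optional horizontal transfer copies an FSF column (with its count)
#' from an already-simulated donor lineage.
#'
#' @param n_per_group proteomes per supergroup.
#' @param n_core ancestral core FSFs present at the root: the oldest
#'   domains, protected from loss (an essential universal machinery).
#' @param n_primordial additional root FSFs that are *not* protected: the
#'   ancient repertoire that reductive clades shed.
#' @param trunk_length duration of the pre-divergence epoch. Core and
#'   primordial FSFs are born sequentially along it, and their abundance at
#'   the root follows the same exponential growth law as later duplication,
#'   so age is encoded in the root genome too.
#' @param origination_rate expected new FSFs per unit branch length on the
#'   backbone and clade stems.
#' @param clade_orig_factor factor (<= 1) applied to `origination_rate`
#'   inside the clade radiations: domain innovation slows after the
#'   supergroups diversify, so most late originations are clade-wide.
#' @param origination_count founding copy number of a newly born FSF.
#' @param min_internal_originations floor on originations along internal
#'   branches: every divergence leaves at least this many novel FSFs, so the
#'   generating tree is identifiable from the census (set 0 to disable).
#' @param duplication_rate per-copy duplication rate per unit branch length.
#' @param loss_rate per-FSF loss rate per unit branch length.
#' @param reductive_multiplier loss-rate factor for inherited FSFs on the
#'   reductive (V, A) clades.
#' @param core_loss_multiplier loss-rate factor for the ancestral core.
#' @param hgt_rate expected horizontal-transfer events per unit branch length.
#' @param backbone_step,stem_length,clade_depth branch lengths of the true
#'   tree: ladder segments between supergroup divergences, the stem leading
#'   to each clade radiation, and the height of each within-clade radiation.
#' @param tree optional fixed organismal tree (`phylo`, tips labelled like
#'   `V01`, `A03`, ...) overriding the generated shape.
#' @param seed integer seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_group = 10, n_core = 15, n_primordial = 30,
                       trunk_length = 6,
                       origination_rate = 2, clade_orig_factor = 0.35,
                       origination_count = 4, min_internal_originations = 1,
                       duplication_rate = 0.3,
                       loss_rate = 0.005, reductive_multiplier = 12,
                       core_loss_multiplier = 0, hgt_rate = 0,
                       backbone_step = 1.5, stem_length = 1.5,
                       clade_depth = 0.8,
                       tree = NULL, seed = 1) {
  stopifnot(n_per_group >= 2, n_core >= 1, n_primordial >= 0,
            trunk_length > 0,
            origination_rate >= 0, clade_orig_factor >= 0,
            clade_orig_factor <= 1, origination_count >= 1,
            min_internal_originations >= 0,
            duplication_rate >= 0, loss_rate >= 0,
            reductive_multiplier >= 0, core_loss_multiplier >= 0,
            hgt_rate >= 0)
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "sim_config")
}

REDUCTIVE_CLADES <- c("V", "A")

# organismal tree: ladder backbone (V first, then A, then B/E) with clade
# radiations; returns phylo with $clade tagging each node's supergroup
# context ("" on the backbone). The tree is globally ultrametric: stems are
# stretched so every radiation starts at the same epoch and every tip sits
# at the same depth, so differences between census rows reflect lineage
# events rather than a root-to-tip path-length clock.
sim_tree <- function(config) {
  offset <- c(V = 0, A = config$backbone_step,
              B = 2 * config$backbone_step, E = 2 * config$backbone_step)
  clades <- lapply(SUPERGROUPS, function(s) {
    tr <- ape::rtree(config$n_per_group,
                     tip.label = sprintf("%s%02d", s, seq_len(config$n_per_group)))
    tr <- ape::compute.brlen(tr)  # ultrametric radiation
    tr$edge.length <- tr$edge.length * config$clade_depth
    tr$root.edge <- config$stem_length +
      (max(offset) - offset[[s]])
    tr
  })
  names(clades) <- SUPERGROUPS
  bb <- ape::read.tree(text = sprintf(
    "(VX:0,(AX:0,(BX:0,EX:0):%g):%g);",
    config$backbone_step, config$backbone_step))
  phy <- bb
  for (s in SUPERGROUPS) {
    where <- which(phy$tip.label == paste0(s, "X"))
    phy <- ape::bind.tree(phy, clades[[s]], where = where)
  }
  phy
}

# supergroup context of every node: the clade whose crown subtree contains
# it (stem edges count as the clade), "" for backbone nodes
node_clades <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  sg <- substr(phy$tip.label, 1, 1)
  clade <- character(nn)
  clade[seq_len(ntip)] <- sg
  # a node belongs to supergroup s iff all descendant tips are s
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    cc <- clade[ch]
    if (clade[p] == "") clade[p] <- cc
    else if (clade[p] != cc) clade[p] <- "-"
  }
  clade[clade == "-"] <- ""
  clade
}

#' Simulate an FSF abundance census with known ground truth
#'
#' @param config a [sim_config()].
#' @return list with `census` (an `abundance_matrix` over the leaf
#'   proteomes; never-observed FSFs pruned), `truth` (list: `tree` the true
#'   organismal phylo, `birth_order` named rank vector over all FSFs ever
#'   born, `birth_node` named vector of originating edge child nodes,
#'   `events` the replayable event log, `config`).
#' @export
simulate_census <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  phy <- if (is.null(config$tree)) sim_tree(config) else config$tree
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  clade <- node_clades(phy)
  root <- ntip + 1L

  fsf_counter <- 0L
  new_fsf <- function() {
    fsf_counter <<- fsf_counter + 1L
    sprintf("SF%04d", fsf_counter)
  }
  core <- vapply(seq_len(config$n_core), function(i) new_fsf(), "")
  primordial <- vapply(seq_len(config$n_primordial), function(i) new_fsf(), "")
  root_fsfs <- c(core, primordial)
  birth_node <- stats::setNames(rep(root, length(root_fsfs)), root_fsfs)
  native_clade <- stats::setNames(rep("", length(root_fsfs)), root_fsfs)

  # pre-divergence history: root FSFs born sequentially along the trunk
  # (core first), abundance at the root graded by the growth law
  n_root <- length(root_fsfs)
  t0 <- -config$trunk_length * (n_root + 1 - seq_len(n_root)) / n_root
  root_birth_time <- stats::setNames(t0, root_fsfs)
  genomes <- vector("list", nn)
  g0 <- stats::setNames(
    pmax(1, round(config$origination_count *
                    exp(config$duplication_rate * (0 - t0)))),
    root_fsfs)
  genomes[[root]] <- g0

  events <- list()
  log_event <- function(node, event, fsf, count) {
    events[[length(events) + 1]] <<- data.frame(
      node = node, event = event, fsf = fsf, count = count,
      stringsAsFactors = FALSE)
  }

  node_time <- ape::node.depth.edgelength(phy)
  birth_time <- root_birth_time

  pre <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    p <- pre$edge[k, 1]; ch <- pre$edge[k, 2]
    len <- pre$edge.length[k]
    g <- genomes[[p]]

    # duplications: per-copy binomial growth; stochastic and per-FSF, so
    # abundance both records age (expected exponential growth) and varies
    # independently across characters
    if (length(g) && config$duplication_rate > 0 && len > 0) {
      p_dup <- 1 - exp(-config$duplication_rate * len)
      gains <- stats::rbinom(length(g), g, p_dup)
      grew <- gains > 0
      if (any(grew)) {
        g[grew] <- g[grew] + gains[grew]
        for (i in which(grew)) log_event(ch, "duplication", names(g)[i], g[[i]])
      }
    }

    # losses: reductive clades shed their inherited repertoire on the stem
    # leading to the radiation (massive early loss), base rate elsewhere
    if (length(g) && config$loss_rate > 0 && len > 0) {
      mult <- rep(1, length(g))
      nc <- native_clade[names(g)]
      stem <- clade[ch] != "" && clade[p] == ""
      if (stem && clade[ch] %in% REDUCTIVE_CLADES)
        mult[nc != clade[ch]] <- config$reductive_multiplier
      mult[names(g) %in% core] <- config$core_loss_multiplier
      p_loss <- 1 - exp(-config$loss_rate * len * mult)
      lost <- stats::runif(length(g)) < p_loss
      if (any(lost)) {
        for (f in names(g)[lost]) log_event(ch, "loss", f, 0)
        g <- g[!lost]
      }
    }

    # originations: innovation slows once a lineage is clade-restricted
    # (stems and radiations); the backbone keeps the full rate
    orate <- config$origination_rate *
      (if (clade[ch] != "") config$clade_orig_factor else 1)
    nb <- if (len > 0) stats::rpois(1, orate * len) else 0L
    if (ch > ntip) nb <- max(nb, config$min_internal_originations)
    if (nb > 0) {
      # on clade-restricted branches the innovation burst accompanies the
      # diversification at the branch end; elsewhere births are uniform
      pos <- sort(stats::runif(nb))
      if (clade[ch] != "") pos <- pos^(1 / 4)
      for (i in seq_len(nb)) {
        f <- new_fsf()
        birth_node[f] <- ch
        native_clade[f] <- clade[ch]
        birth_time[f] <- node_time[p] + pos[i] * len
        g[f] <- config$origination_count
        log_event(ch, "origination", f, config$origination_count)
      }
    }

    # horizontal transfer from an already-simulated lineage
    if (config$hgt_rate > 0 && len > 0) {
      nh <- stats::rpois(1, config$hgt_rate * len)
      donors <- which(!vapply(genomes, is.null, TRUE))
      donors <- setdiff(donors, c(p, ch))
      for (i in seq_len(nh)) {
        if (!length(donors)) break
        dnode <- donors[sample.int(length(donors), 1)]
        dg <- genomes[[dnode]]
        if (!length(dg)) next
        f <- names(dg)[sample.int(length(dg), 1)]
        g[f] <- dg[[f]]
        log_event(ch, "hgt", f, dg[[f]])
      }
    }

    genomes[[ch]] <- g
    if (length(g) == 0 && ch <= ntip)
      warning("leaf proteome ", phy$tip.label[ch], " has an empty genome")
  }

  all_fsfs <- sprintf("SF%04d", seq_len(fsf_counter))
  gmat <- matrix(0L, ntip, fsf_counter,
                 dimnames = list(phy$tip.label, all_fsfs))
  for (tip in seq_len(ntip)) {
    g <- genomes[[tip]]
    if (length(g)) gmat[tip, names(g)] <- as.integer(round(g))
  }
  meta <- data.frame(proteome_id = phy$tip.label,
                     supergroup = substr(phy$tip.label, 1, 1),
                     lifestyle = "FL", n_proteins = NA_integer_,
                     stringsAsFactors = FALSE)
  empty <- colSums(gmat) == 0L
  census <- new_abundance_matrix(gmat[, !empty, drop = FALSE], meta,
                                 pruned = colnames(gmat)[empty])
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(node = integer(0), event = character(0),
               fsf = character(0), count = numeric(0))
  bt <- birth_time[all_fsfs]
  truth <- list(tree = phy,
                birth_time = bt,
                birth_order = rank(bt, ties.method = "average"),
                birth_node = birth_node,
                native_clade = native_clade,
                root_genome = g0,
                events = events,
                config = config)
  list(census = census, truth = truth)
}

#' Replay a simulation event log
#'
#' Deterministically reconstructs the leaf abundance matrix from the true
#' tree, the root genome and the event log, without any random draws; used
#' to verify that the log fully explains the emitted census.
#'
#' @param truth the `truth` component returned by [simulate_census()].
#' @return integer matrix (leaves x all ever-born FSFs).
#' @export
replay_events <- function(truth) {
  phy <- truth$tree
  ntip <- length(phy$tip.label)
  genomes <- vector("list", ntip + phy$Nnode)
  genomes[[ntip + 1L]] <- truth$root_genome
  ev <- truth$events
  pre <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    p <- pre$edge[k, 1]; ch <- pre$edge[k, 2]
    g <- genomes[[p]]
    e <- ev[ev$node == ch, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      f <- e$fsf[i]
      switch(e$event[i],
             duplication = , hgt = , origination = { g[f] <- e$count[i] },
             loss = { g <- g[names(g) != f] })
    }
    genomes[[ch]] <- g
  }
  all_fsfs <- names(truth$birth_order)
  out <- matrix(0L, ntip, length(all_fsfs),
                dimnames = list(phy$tip.label, all_fsfs))
  for (tip in seq_len(ntip)) {
    g <- genomes[[tip]]
    if (length(g)) out[tip, names(g)] <- as.integer(round(g))
  }
  out
}

#' Compare inferred trees and ages with simulation ground truth
#'
#' @param truth the `truth` component from [simulate_census()].
#' @param inferred_top inferred tree of proteomes (`phylo`).
#' @param inferred_ages optional age table from [node_distance()] on the
#'   inferred tree of domains.
#' @return list with `rf` (Robinson-Foulds distance inferred vs true
#'   unrooted topology), `rf_normalized`, `monophyly` (named logical per
#'   supergroup), and when ages are supplied `age_spearman` (rank
#'   correlation between nd and true birth order over the FSFs present in
#'   both).
#' @export
recovery_report <- function(truth, inferred_top, inferred_ages = NULL) {
  true_tree <- truth$tree
  if (!setequal(true_tree$tip.label, inferred_top$tip.label))
    stop("taxon mismatch between truth and inferred tree")
  t1 <- ape::unroot(true_tree)
  t2 <- ape::unroot(inferred_top)
  rf <- as.numeric(ape::dist.topo(t1, t2, method = "PH85"))
  nint <- function(t) t$Nnode - 1
  rfmax <- nint(t1) + nint(t2)
  mono <- vapply(SUPERGROUPS, function(s) {
    tips <- grep(paste0("^", s), inferred_top$tip.label, value = TRUE)
    length(tips) > 0 && ape::is.monophyletic(inferred_top, tips)
  }, TRUE)
  out <- list(rf = rf, rf_normalized = if (rfmax > 0) rf / rfmax else 0,
              monophyly = mono)
  if (!is.null(inferred_ages)) {
    common <- intersect(inferred_ages$fsf, names(truth$birth_order))
    if (length(common) < 3) {
      out$age_spearman <- NA_real_
      out$age_spearman_note <- "fewer than 3 shared FSFs"
    } else {
      nd <- inferred_ages$nd[match(common, inferred_ages$fsf)]
      bo <- truth$birth_order[common]
      out$age_spearman <- suppressWarnings(
        stats::cor(nd, bo, method = "spearman"))
    }
  }
  out
}
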