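#' Sample proteomes per supergroup for tree-of-proteome reconstruction
#'
#' Uniform sampling without replacement within each supergroup, optionally
#' excluding parasitic (P) and obligate-parasitic (OP) lifestyles first.
#'
#' @param metadata proteome metadata data frame (see [parse_assignments()]).
#' @param per_group_n proteomes to draw from each supergroup present.
#' @param lifestyle_filter drop P/OP proteomes before sampling.
#' @param seed integer seed.
#' @return character vector of selected proteome ids (canonical metadata
#'   order). If a supergroup has exactly `per_group_n` proteomes available
#'   they are all returned.
#' @export
sample_proteomes <- function(metadata, per_group_n, lifestyle_filter = TRUE,
                             seed = 1) {
  metadata <- validate_metadata(metadata)
  if (lifestyle_filter) metadata <- metadata[metadata$lifestyle == "FL", ]
  set.seed(seed)
  ids <- character(0)
  for (s in intersect(SUPERGROUPS, unique(metadata$supergroup))) {
    pool <- metadata$proteome_id[metadata$supergroup == s]
    if (length(pool) < per_group_n)
      stop("supergroup ", s, " has only ", length(pool),
           " proteomes after filtering (need ", per_group_n, ")")
    ids <- c(ids, if (length(pool) == per_group_n) pool
             else sample(pool, per_group_n))
  }
  metadata$proteome_id[metadata$proteome_id %in% ids]
}

#' Run the full census-to-trees analysis and write its artifacts
#'
#' Orchestrates the pipeline on an abundance census: census export,
#' character coding, tree of domains + age timeline, sampled tree of
#' proteomes, taxonomic-group assignment and enrichment, NeighborNet split
#' network, optional function tallies, and a machine-readable manifest.
#' Every number in the manifest is re-derivable from the emitted files.
#'
#' @param census an `abundance_matrix`.
#' @param outdir output directory (created if needed).
#' @param per_group_n proteomes sampled per supergroup for the tree of
#'   proteomes and the network (default: all available).
#' @param lifestyle_filter exclude P/OP proteomes from the ToP sample.
#' @param character_subset `"all"` or `"ABEV"` (restrict ToP characters to
#'   FSFs shared by all four supergroups).
#' @param sample_supergroup supergroup treated as the enrichment sample.
#' @param config a [search_config()]; its seed drives all sampling.
#' @param function_mapping optional FSF-to-function mapping (path or data
#'   frame) enabling the function tallies.
#' @param network_bootstrap NeighborNet bootstrap replicates (0 = none).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_census_pipeline <- function(census, outdir,
                                per_group_n = NULL,
                                lifestyle_filter = TRUE,
                                character_subset = c("all", "ABEV"),
                                sample_supergroup = "V",
                                config = search_config(),
                                function_mapping = NULL,
                                network_bootstrap = 0) {
  stopifnot(inherits(census, "abundance_matrix"))
  character_subset <- match.arg(character_subset)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(outdir, ...)

  write_census(census, pth("census.tsv"))
  groups <- assign_groups(census)

  # tree of domains and age timeline (always on the full census)
  tod <- fsf_tree(census, "ToD", config)
  ape::write.tree(tod$tree, pth("tod.nwk"))
  write_coded(tod$coded, pth("tod.nex"), "nexus")
  ages <- domain_ages(tod)
  f_total <- distribution_index(census, "total")
  timeline <- data.frame(
    fsf = ages$fsf, nd = ages$nd,
    f_total = unname(f_total[ages$fsf]),
    category = unname(groups$category[ages$fsf]))
  for (s in intersect(SUPERGROUPS, unique(census$proteomes$supergroup)))
    timeline[[paste0("f_", s)]] <-
      unname(distribution_index(census, s)[ages$fsf])
  utils::write.table(timeline, pth("timeline.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  curve <- f_vs_nd(ages, f_total)

  # sampled tree of proteomes
  avail <- table(census$proteomes$supergroup[
    !lifestyle_filter | census$proteomes$lifestyle == "FL"])
  if (is.null(per_group_n)) per_group_n <- min(avail)
  ids <- sample_proteomes(census$proteomes, per_group_n, lifestyle_filter,
                          seed = config$seed)
  sub <- subset_census(census, proteomes = ids)
  if (character_subset == "ABEV") {
    gsub_ <- assign_groups(sub)
    sub <- subset_census(sub, fsfs = names(gsub_$category)[
      gsub_$category == "ABEV"])
  }
  top <- fsf_tree(sub, "ToP", config)
  ape::write.tree(top$tree, pth("top.nwk"))
  write_coded(top$coded, pth("top.nex"), "nexus")

  # enrichment
  enr <- enrichment_table(groups, sample_supergroup)
  utils::write.table(enr, pth("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # split network on the sampled occurrence matrix
  occ <- occurrence(sub)
  net <- if (network_bootstrap > 0)
    split_bootstrap(occ, replicates = network_bootstrap, seed = config$seed)
  else neighbornet(occ)
  write_splits(net, pth("splits.tsv"))

  # function tallies
  tallies <- NULL
  if (!is.null(function_mapping)) {
    ann <- annotate_functions(ages$fsf, function_mapping)
    tallies <- tally_by_phase(ann, ages)
    utils::write.table(as.data.frame(tallies$by_major),
                       pth("function_tallies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    n_proteomes = nrow(census$g),
    n_fsfs = ncol(census$g),
    n_pruned = length(census$pruned),
    group_tally = as.list(groups$tally),
    tod_length = tod$length,
    tod_ci = tod$fit$ensemble_ci, tod_ri = tod$fit$ensemble_ri,
    top_taxa = nrow(top$coded$states),
    top_characters = ncol(top$coded$states),
    top_length = top$length,
    f_min_nd = curve$f_min_nd,
    n_splits = length(net$splits),
    seed = config$seed)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
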