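#' Fit a rooted parsimony tree to an FSF census
#'
#' The central estimator of the package: encodes an abundance census as
#' 24-state linearly ordered characters (unless a `coded_matrix` is passed
#' directly), searches tree space under Wagner parsimony, Lundberg-roots the
#' optimal trees with the declared ancestral state, and attaches
#' per-character and ensemble fit statistics. With `orientation = "ToD"` the
#' result is a tree of domains (FSFs as taxa, ancestral state 23); with
#' `"ToP"` a tree of proteomes (ancestral state 0).
#'
#' @param x an `abundance_matrix` or a `coded_matrix`.
#' @param orientation `"ToD"` or `"ToP"` (ignored when `x` is already coded).
#' @param config a [search_config()].
#' @param bootstrap if `TRUE`, bootstrap supports are computed with
#'   `config$bootstrap_replicates` replicates.
#' @return an object of class `fsf_tree`: list with `tree` (first optimal
#'   rooted phylo), `trees` (all retained optima), `length`,
#'   `rooted_length`, `fit` (from [fit_statistics()]), `coded`, `boot`
#'   (optional, from [mp_bootstrap()]) and `config`.
#' @examples
#' asn <- data.frame(
#'   proteome_id = rep(c("P1", "P2", "P3", "P4"), each = 2),
#'   css = rep(c("c.37.1", "b.40.4"), 4),
#'   count = c(8, 1, 7, 1, 2, 5, 1, 6))
#' met <- data.frame(proteome_id = paste0("P", 1:4),
#'                   supergroup = c("A", "A", "B", "B"))
#' fit <- fsf_tree(parse_assignments(asn, met), orientation = "ToP",
#'                 config = search_config(n_addition_sequences = 2, seed = 1))
#' fit
#' @export
fsf_tree <- function(x, orientation = c("ToP", "ToD"),
                     config = search_config(), bootstrap = FALSE) {
  orientation <- match.arg(orientation)
  coded <- if (inherits(x, "coded_matrix")) x else encode_matrix(x, orientation)
  res <- mp_search(coded, config)
  fit <- fit_statistics(res$trees[[1]], coded)
  boot <- if (bootstrap) mp_bootstrap(coded, config) else NULL
  structure(list(tree = res$trees[[1]], trees = res$trees,
                 length = res$length, rooted_length = res$rooted_length,
                 tie = res$tie, fit = fit, coded = coded, boot = boot,
                 config = config),
            class = "fsf_tree")
}

#' @export
print.fsf_tree <- function(x, ...) {
  cat(sprintf("Rooted Wagner parsimony tree (%s): %d taxa, %d characters\n",
              x$coded$orientation, nrow(x$coded$states), ncol(x$coded$states)))
  cat(sprintf("  length: %d steps unrooted, %d rooted (ancestral state %d)\n",
              as.integer(x$length), as.integer(x$rooted_length),
              x$coded$ancestral_state))
  cat(sprintf("  ensemble CI = %.4f, RI = %.4f; %d optimal topolog%s\n",
              x$fit$ensemble_ci, x$fit$ensemble_ri, length(x$trees),
              if (length(x$trees) == 1) "y" else "ies"))
  invisible(x)
}

#' @export
summary.fsf_tree <- function(object, ...) {
  ri <- object$fit$per_character$ri
  out <- list(orientation = object$coded$orientation,
              n_taxa = nrow(object$coded$states),
              n_characters = ncol(object$coded$states),
              length = object$length,
              rooted_length = object$rooted_length,
              ensemble_ci = object$fit$ensemble_ci,
              ensemble_ri = object$fit$ensemble_ri,
              ri_quartiles = stats::quantile(ri, na.rm = TRUE),
              n_uninformative = sum(!object$fit$per_character$informative),
              n_trees = length(object$trees))
  class(out) <- "summary.fsf_tree"
  out
}

#' @export
print.summary.fsf_tree <- function(x, ...) {
  cat(sprintf("%s: %d taxa, %d ordered characters (%d uninformative)\n",
              x$orientation, x$n_taxa, x$n_characters, x$n_uninformative))
  cat(sprintf("length %d (rooted %d), CI %.4f, RI %.4f, %d optimal tree(s)\n",
              as.integer(x$length), as.integer(x$rooted_length),
              x$ensemble_ci, x$ensemble_ri, x$n_trees))
  cat("per-character retention index:\n")
  print(round(x$ri_quartiles, 3))
  invisible(x)
}

#' @export
plot.fsf_tree <- function(x, show_support = TRUE, ...) {
  phy <- x$tree
  ape::plot.phylo(phy, ...)
  if (show_support && !is.null(x$boot)) {
    cons <- x$boot$consensus
    ape::plot.phylo(cons, main = "bootstrap majority-rule consensus", ...)
  }
  invisible(x)
}

#' Domain age table from a fitted tree of domains
#'
#' Convenience wrapper: [node_distance()] on the reported tree, plus the
#' cross-tree nd standard deviation over all retained optimal trees as a
#' stability diagnostic when the search kept more than one.
#'
#' @param fit an `fsf_tree` with orientation `"ToD"`.
#' @return an age table (see [node_distance()]); when several optimal trees
#'   were retained it has an extra column `nd_sd` across trees.
#' @export
domain_ages <- function(fit) {
  stopifnot(inherits(fit, "fsf_tree"))
  if (fit$coded$orientation != "ToD")
    stop("domain ages need a tree of domains (orientation ToD)")
  ages <- node_distance(fit$tree)
  if (length(fit$trees) > 1) {
    nds <- vapply(fit$trees, function(t) {
      a <- node_distance(t)
      a$nd[match(ages$fsf, a$fsf)]
    }, numeric(nrow(ages)))
    ages$nd_sd <- apply(nds, 1, stats::sd)
  }
  ages
}
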