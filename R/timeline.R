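#' Relative domain ages (node distance) from a rooted tree of domains
#'
#' The node distance of a leaf counts the internal nodes on its root-to-leaf
#' path and rescales the counts to 0-1: nd = 0 is the origin of protein
#' domains, nd = 1 the present. Leaves tied at one depth share an nd value;
#' if every leaf has the same depth the table is flagged degenerate and all
#' nd are 0.
#'
#' @param tod a rooted `phylo` tree with FSFs as tips.
#' @return a data frame (`age_table`) with columns `fsf`, `raw_depth`, `nd`,
#'   plus attribute `degenerate`.
#' @export
node_distance <- function(tod) {
  if (!inherits(tod, "phylo")) stop("tod must be a phylo tree")
  if (!ape::is.rooted(tod)) stop("tree of domains must be rooted")
  ntip <- length(tod$tip.label)
  parent <- integer(ntip + tod$Nnode)
  parent[tod$edge[, 2]] <- tod$edge[, 1]
  root <- ntip + 1L
  depth <- vapply(seq_len(ntip), function(tip) {
    d <- 0L; x <- parent[tip]
    while (x != 0L) { d <- d + 1L; x <- parent[x] }
    d
  }, 0L)
  rng <- range(depth)
  degenerate <- rng[1] == rng[2]
  nd <- if (degenerate) rep(0, ntip) else (depth - rng[1]) / (rng[2] - rng[1])
  structure(data.frame(fsf = tod$tip.label, raw_depth = depth, nd = nd,
                       row.names = NULL),
            degenerate = degenerate, class = c("age_table", "data.frame"))
}

#' Join domain ages with distribution indices
#'
#' @param ages an age table from [node_distance()].
#' @param f named numeric vector from [distribution_index()]; names must
#'   match the age table's FSF set exactly.
#' @param bins number of equal-width nd bins used for the summary curve.
#' @return a list with `series` (data frame fsf/nd/f sorted by nd), `curve`
#'   (binned median f versus bin midpoint), and `f_min_nd` (the nd at the
#'   minimum of the binned curve, the empirical phase boundary).
#' @export
f_vs_nd <- function(ages, f, bins = 10) {
  sym <- c(setdiff(ages$fsf, names(f)), setdiff(names(f), ages$fsf))
  if (length(sym)) stop("FSF mismatch between age table and f: ",
                        paste(sym, collapse = ", "))
  ser <- data.frame(fsf = ages$fsf, nd = ages$nd, f = unname(f[ages$fsf]))
  ser <- ser[order(ser$nd, ser$fsf), , drop = FALSE]
  rownames(ser) <- NULL
  if (nrow(ser) == 1) {
    return(list(series = ser,
                curve = data.frame(mid = ser$nd, median_f = ser$f, n = 1L),
                f_min_nd = ser$nd))
  }
  edges <- seq(0, 1, length.out = bins + 1)
  bin <- pmin(findInterval(ser$nd, edges, rightmost.closed = TRUE), bins)
  med <- tapply(ser$f, factor(bin, levels = seq_len(bins)), stats::median)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  curve <- data.frame(mid = mid, median_f = as.numeric(med),
                      n = as.integer(table(factor(bin, levels = seq_len(bins)))))
  occupied <- !is.na(curve$median_f)
  cm <- curve[occupied, , drop = FALSE]
  f_min_nd <- cm$mid[which.min(cm$median_f)]
  list(series = ser, curve = curve, f_min_nd = f_min_nd)
}

#' Age distribution of taxonomic groups along the timeline
#'
#' @param ages an age table from [node_distance()].
#' @param groups a group assignment from [assign_groups()].
#' @return data frame per non-empty category: n, min/median/max nd, ordered
#'   by median nd (most ancient first). Empty categories are omitted.
#' @export
group_age_summary <- function(ages, groups) {
  cat <- groups$category
  miss <- setdiff(ages$fsf, names(cat))
  if (length(miss)) stop("FSFs lack a group assignment: ",
                         paste(miss, collapse = ", "))
  nd <- ages$nd
  names(nd) <- ages$fsf
  cats <- unique(cat[ages$fsf])
  rows <- lapply(cats, function(cc) {
    v <- nd[names(cat)[cat == cc]]
    v <- v[!is.na(v)]
    data.frame(category = cc, n = length(v), min_nd = min(v),
               median_nd = stats::median(v), max_nd = max(v))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$median_nd, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
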