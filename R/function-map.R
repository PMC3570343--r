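#' Molecular-function category skeleton
#'
#' The seven major molecular-function categories (Metabolism, Information,
#' Intracellular processes, Extracellular processes, Regulation, General,
#' Other) and their minor subcategories, bundled for validating user-supplied
#' FSF-to-function mapping files. The per-FSF mapping itself is user data;
#' only the major/minor skeleton ships with the package.
#'
#' @return data frame with columns `major`, `minor`.
#' @export
function_categories <- function() {
  utils::read.delim(system.file("extdata", "function_categories.tsv",
                                package = "domcensus"),
                    stringsAsFactors = FALSE)
}

#' Annotate FSFs with molecular-function categories
#'
#' Left-joins a user-supplied mapping table (css, major, minor) onto a set
#' of FSFs. Every mapping row must be consistent with the bundled
#' major/minor skeleton; FSFs without a mapping entry get `NA` categories
#' and are counted in the coverage statistic.
#'
#' @param fsfs character vector of FSF css.
#' @param mapping data frame or TSV path with columns `css`, `major`, `minor`.
#' @return data frame (fsf, major, minor) with attribute `coverage`
#'   (fraction annotated).
#' @export
annotate_functions <- function(fsfs, mapping) {
  if (is.character(mapping) && length(mapping) == 1)
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  need <- c("css", "major", "minor")
  miss <- setdiff(need, names(mapping))
  if (length(miss)) stop("mapping lacks columns: ", paste(miss, collapse = ", "))
  skel <- function_categories()
  key <- paste(mapping$major, mapping$minor, sep = "\r")
  ok <- key %in% paste(skel$major, skel$minor, sep = "\r")
  if (any(!ok))
    stop("mapping rows inconsistent with the major/minor skeleton: ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  if (anyDuplicated(mapping$css)) stop("duplicate css in mapping")
  idx <- match(parse_css(fsfs), if (nrow(mapping)) parse_css(mapping$css) else character(0))
  out <- data.frame(fsf = fsfs,
                    major = mapping$major[idx],
                    minor = mapping$minor[idx],
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- mean(!is.na(out$major))
  out
}

#' Tally functional categories along the age timeline
#'
#' Counts FSFs per (nd phase, category) cell. Default phase edges 0.4 and
#' 0.6 cut the timeline into early, middle and late phases; bins are
#' half-open `[lo, hi)` with the last bin closed. Unannotated FSFs are
#' tallied in an explicit `<unannotated>` row.
#'
#' @param annotation data frame from [annotate_functions()].
#' @param ages an age table from [node_distance()] over the same FSFs.
#' @param bin_edges interior nd cut points in (0,1), strictly increasing.
#' @return list with `phase_totals` (counts per phase), `by_major` and
#'   `by_minor` (phase x category count tables).
#' @export
tally_by_phase <- function(annotation, ages, bin_edges = c(0.4, 0.6)) {
  if (length(bin_edges) && (any(diff(bin_edges) <= 0) ||
                            any(bin_edges <= 0) || any(bin_edges >= 1)))
    stop("bin_edges must be strictly increasing, inside (0, 1)")
  sym <- c(setdiff(annotation$fsf, ages$fsf), setdiff(ages$fsf, annotation$fsf))
  if (length(sym)) stop("FSF mismatch: ", paste(sym, collapse = ", "))
  edges <- c(0, bin_edges, 1)
  labs <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                  c(rep(")", length(edges) - 2), "]"))
  nd <- ages$nd[match(annotation$fsf, ages$fsf)]
  phase <- cut(nd, breaks = edges, labels = labs, right = FALSE,
               include.lowest = TRUE)
  phase[nd == 1] <- labs[length(labs)]
  major <- ifelse(is.na(annotation$major), "<unannotated>", annotation$major)
  minor <- ifelse(is.na(annotation$minor), "<unannotated>", annotation$minor)
  list(phase_totals = table(phase),
       by_major = table(phase, major),
       by_minor = table(phase, minor))
}
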