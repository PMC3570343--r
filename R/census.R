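#' Parse and validate SCOP concise classification strings
#'
#' A concise classification string (css) identifies a SCOP unit by class
#' letter and numeric levels, e.g. `"c.37.1"` is class c, fold 37,
#' superfamily 1. Fold-family level strings (`"c.37.1.5"`) are accepted and
#' truncated to superfamily (FSF) level, since the census works at FSF
#' granularity.
#'
#' @param css character vector of classification strings.
#' @return character vector of FSF-level css (`letter.digits.digits`).
#' @examples
#' parse_css(c("c.37.1", "c.37.1.5", "b.40.4"))
#' @export
parse_css <- function(css) {
  css <- trimws(as.character(css))
  ok <- grepl("^[a-z]\\.[0-9]+\\.[0-9]+(\\.[0-9]+)?$", css)
  if (any(!ok)) {
    stop("malformed css: ", paste(unique(css[!ok]), collapse = ", "))
  }
  sub("^([a-z]\\.[0-9]+\\.[0-9]+)(\\.[0-9]+)?$", "\\1", css)
}

SUPERGROUPS <- c("A", "B", "E", "V")
LIFESTYLES  <- c("FL", "P", "OP")

validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need <- c("proteome_id", "supergroup")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$proteome_id))
    stop("duplicate proteome ids in metadata")
  if (!all(metadata$supergroup %in% SUPERGROUPS))
    stop("supergroup must be one of ", paste(SUPERGROUPS, collapse = "/"))
  if (is.null(metadata$lifestyle)) metadata$lifestyle <- "FL"
  metadata$lifestyle[is.na(metadata$lifestyle) | metadata$lifestyle == ""] <- "FL"
  if (!all(metadata$lifestyle %in% LIFESTYLES))
    stop("lifestyle must be one of ", paste(LIFESTYLES, collapse = "/"))
  if (is.null(metadata$n_proteins)) metadata$n_proteins <- NA_integer_
  metadata[, c("proteome_id", "supergroup", "lifestyle", "n_proteins")]
}

#' Build a proteome-by-FSF abundance matrix from domain assignments
#'
#' Reads a long-format assignment table (one row per proteome/css/count) and
#' proteome metadata, collapses fold-family css to FSF level by summing
#' counts, and drops FSF columns with no representation in any proteome
#' (reporting them in the `pruned` field).
#'
#' @param assignments data frame or TSV path with columns `proteome_id`,
#'   `css`, `count`.
#' @param metadata data frame or TSV path with columns `proteome_id`,
#'   `supergroup` (one of A/B/E/V) and optionally `lifestyle` (FL/P/OP,
#'   default FL) and `n_proteins`.
#' @return an object of class `abundance_matrix`: a list with `g` (integer
#'   matrix, proteomes in rows, FSFs in columns), `proteomes` (metadata data
#'   frame, row order matching `g`), and `pruned` (css of dropped all-zero
#'   FSF columns).
#' @examples
#' asn <- data.frame(proteome_id = c("P1", "P1", "P2"),
#'                   css = c("c.37.1", "c.37.1.5", "b.40.4"),
#'                   count = c(3, 2, 1))
#' met <- data.frame(proteome_id = c("P1", "P2"), supergroup = c("B", "E"))
#' ab <- parse_assignments(asn, met)
#' ab$g
#' @export
parse_assignments <- function(assignments, metadata) {
  if (is.character(assignments) && length(assignments) == 1)
    assignments <- utils::read.delim(assignments, stringsAsFactors = FALSE)
  if (is.character(metadata) && length(metadata) == 1)
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  metadata <- validate_metadata(metadata)
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  need <- c("proteome_id", "css", "count")
  miss <- setdiff(need, names(assignments))
  if (length(miss)) stop("assignment table lacks columns: ",
                         paste(miss, collapse = ", "))

  if (nrow(assignments) == 0) {
    g <- matrix(0L, nrow = nrow(metadata), ncol = 0,
                dimnames = list(metadata$proteome_id, character(0)))
    return(new_abundance_matrix(g, metadata, pruned = character(0)))
  }

  bad <- !(assignments$proteome_id %in% metadata$proteome_id)
  if (any(bad)) {
    stop("unknown proteome id in assignment rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         " (id ", paste(unique(assignments$proteome_id[bad]), collapse = ", "), ")")
  }
  cnt <- assignments$count
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("counts must be non-negative integers")

  fsf <- parse_css(assignments$css)
  fsfs <- sort(unique(fsf))
  g <- matrix(0L, nrow = nrow(metadata), ncol = length(fsfs),
              dimnames = list(metadata$proteome_id, fsfs))
  i <- match(assignments$proteome_id, metadata$proteome_id)
  j <- match(fsf, fsfs)
  for (k in seq_along(i)) g[i[k], j[k]] <- g[i[k], j[k]] + as.integer(cnt[k])

  empty <- colSums(g) == 0L
  pruned <- colnames(g)[empty]
  g <- g[, !empty, drop = FALSE]
  new_abundance_matrix(g, metadata, pruned = pruned)
}

new_abundance_matrix <- function(g, proteomes, pruned = character(0)) {
  stopifnot(is.matrix(g), nrow(g) == nrow(proteomes))
  storage.mode(g) <- "integer"
  structure(list(g = g, proteomes = proteomes, pruned = pruned),
            class = "abundance_matrix")
}

#' Subset an abundance matrix by proteomes and/or FSFs
#'
#' @param x an `abundance_matrix`.
#' @param proteomes,fsfs character vectors of labels to keep (default all).
#' @param drop_empty drop FSF columns that become all-zero after proteome
#'   subsetting (the retained-width convention used throughout).
#' @return an `abundance_matrix`.
#' @export
subset_census <- function(x, proteomes = NULL, fsfs = NULL, drop_empty = TRUE) {
  stopifnot(inherits(x, "abundance_matrix"))
  g <- x$g
  meta <- x$proteomes
  if (!is.null(proteomes)) {
    miss <- setdiff(proteomes, rownames(g))
    if (length(miss)) stop("unknown proteomes: ", paste(miss, collapse = ", "))
    keep <- rownames(g) %in% proteomes
    g <- g[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (!is.null(fsfs)) {
    miss <- setdiff(fsfs, colnames(g))
    if (length(miss)) stop("unknown FSFs: ", paste(miss, collapse = ", "))
    g <- g[, colnames(g) %in% fsfs, drop = FALSE]
  }
  pruned <- x$pruned
  if (drop_empty) {
    empty <- colSums(g) == 0L
    pruned <- c(pruned, colnames(g)[empty])
    g <- g[, !empty, drop = FALSE]
  }
  new_abundance_matrix(g, meta, pruned = pruned)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("FSF abundance census:", nrow(x$g), "proteomes x", ncol(x$g), "FSFs\n")
  tab <- table(factor(x$proteomes$supergroup, levels = SUPERGROUPS))
  cat("supergroups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (length(x$pruned))
    cat("pruned all-zero FSFs:", length(x$pruned), "\n")
  invisible(x)
}

#' @export
summary.abundance_matrix <- function(object, ...) {
  occ <- occurrence(object)
  out <- list(
    n_proteomes = nrow(object$g),
    n_fsfs = ncol(object$g),
    n_pruned = length(object$pruned),
    g_max = if (length(object$g)) max(object$g) else 0L,
    distinct_per_proteome = rowSums(occ > 0),
    total_per_proteome = rowSums(object$g)
  )
  class(out) <- "summary.abundance_matrix"
  out
}

#' @export
print.summary.abundance_matrix <- function(x, ...) {
  cat("FSF abundance census:", x$n_proteomes, "proteomes x", x$n_fsfs, "FSFs",
      sprintf("(g_max = %d, %d pruned)\n", x$g_max, x$n_pruned))
  cat("distinct FSFs per proteome:\n")
  print(summary(x$distinct_per_proteome))
  invisible(x)
}

#' Presence/absence matrix from an abundance census
#'
#' @param x an `abundance_matrix` (or a bare count matrix).
#' @return integer 0/1 matrix of the same shape: 1 where abundance > 0.
#' @export
occurrence <- function(x) {
  g <- if (inherits(x, "abundance_matrix")) x$g else x
  stopifnot(is.matrix(g))
  occ <- (g > 0) + 0L
  dimnames(occ) <- dimnames(g)
  occ
}

scope_rows <- function(x, scope) {
  if (identical(scope, "total")) return(seq_len(nrow(x$g)))
  if (scope %in% SUPERGROUPS) {
    rows <- which(x$proteomes$supergroup == scope)
    if (!length(rows)) stop("scope selects no proteomes: ", scope)
    return(rows)
  }
  stop("scope must be 'total' or one of ", paste(SUPERGROUPS, collapse = "/"))
}

#' Distribution index f: fraction of proteomes harboring each FSF
#'
#' `f` ranges 0-1 and is the fraction of proteomes in the chosen scope in
#' which the FSF occurs at least once; an FSF found in every proteome of the
#' scope has `f = 1`.
#'
#' @param x an `abundance_matrix`.
#' @param scope `"total"` or a supergroup letter (A/B/E/V).
#' @return named numeric vector (one entry per retained FSF).
#' @export
distribution_index <- function(x, scope = "total") {
  stopifnot(inherits(x, "abundance_matrix"))
  rows <- scope_rows(x, scope)
  colSums(x$g[rows, , drop = FALSE] > 0) / length(rows)
}

#' Assign FSFs to taxonomic (Venn) groups of supergroups
#'
#' Each FSF is placed in the category named by the sorted set of supergroup
#' letters (A < B < E < V) in which it occurs at least once, one of the 15
#' non-empty subsets of \{A,B,E,V\} (A, B, ..., AB, ..., ABEV).
#'
#' @param x an `abundance_matrix` whose proteomes all carry supergroup labels.
#' @return a list with `category` (named character vector, FSF -> category)
#'   and `tally` (named integer vector over the 15 categories, zero-count
#'   categories included).
#' @export
assign_groups <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (ncol(x$g) == 0) stop("census has no FSFs")
  zero <- colSums(x$g) == 0
  if (any(zero))
    stop("FSFs with zero total occurrence (should have been pruned): ",
         paste(colnames(x$g)[zero], collapse = ", "))
  sg <- x$proteomes$supergroup
  present <- vapply(SUPERGROUPS, function(s) {
    rows <- sg == s
    if (!any(rows)) rep(FALSE, ncol(x$g))
    else colSums(x$g[rows, , drop = FALSE] > 0) > 0
  }, logical(ncol(x$g)))
  if (is.null(dim(present))) present <- matrix(present, nrow = 1)
  category <- apply(present, 1, function(p) paste(SUPERGROUPS[p], collapse = ""))
  names(category) <- colnames(x$g)
  cats <- unlist(lapply(1:4, function(k)
    apply(utils::combn(SUPERGROUPS, k), 2, paste, collapse = "")))
  tally <- table(factor(category, levels = cats))
  list(category = category, tally = c(tally))
}

#' Average reuse of FSF domains in one proteome
#'
#' Total domain count divided by the number of distinct FSFs, i.e. the mean
#' genomic abundance of the FSFs the proteome actually encodes.
#'
#' @param x an `abundance_matrix`.
#' @param proteome proteome id.
#' @return a single number >= 1.
#' @export
reuse_ratio <- function(x, proteome) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (!proteome %in% rownames(x$g)) stop("unknown proteome: ", proteome)
  row <- x$g[proteome, ]
  distinct <- sum(row > 0)
  if (distinct == 0) stop("proteome has no FSF assignments: ", proteome)
  sum(row) / distinct
}

#' Spread of partner-shared vs partner-specific FSFs within a supergroup
#'
#' Splits the FSF repertoire of a focal supergroup into FSFs shared with a
#' partner supergroup (default the viral supergroup) and the remainder, and
#' returns the distribution indices of both sets scoped to the focal
#' supergroup's proteomes, with medians.
#'
#' @param x an `abundance_matrix`.
#' @param focal supergroup letter whose proteomes define the scope.
#' @param partner supergroup letter defining the shared set (default `"V"`).
#' @return list with `shared_f`, `specific_f` (named numeric vectors),
#'   `median_shared`, `median_specific` (NA when the set is empty).
#' @export
shared_vs_specific <- function(x, focal, partner = "V") {
  stopifnot(inherits(x, "abundance_matrix"))
  rows_f <- scope_rows(x, focal)
  rows_p <- scope_rows(x, partner)
  in_focal   <- colSums(x$g[rows_f, , drop = FALSE] > 0) > 0
  in_partner <- colSums(x$g[rows_p, , drop = FALSE] > 0) > 0
  f <- distribution_index(x, focal)
  shared   <- f[in_focal & in_partner]
  specific <- f[in_focal & !in_partner]
  list(shared_f = shared,
       specific_f = specific,
       median_shared   = if (length(shared))   stats::median(shared)   else NA_real_,
       median_specific = if (length(specific)) stats::median(specific) else NA_real_)
}

#' Write an abundance census to TSV with a JSON sidecar
#'
#' The TSV holds proteomes in rows and FSFs in columns; the sidecar JSON
#' records the pruned FSFs and the taxonomic-group tallies so every report
#' number is re-derivable from emitted files.
#'
#' @param x an `abundance_matrix`.
#' @param file path of the TSV to write; the sidecar is `<file>.json` and the
#'   metadata table `<file>.meta.tsv`.
#' @return `file`, invisibly.
#' @export
write_census <- function(x, file) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(proteome_id = rownames(x$g), x$g, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$proteomes, paste0(file, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- list(pruned = x$pruned,
               tally = if (ncol(x$g)) as.list(assign_groups(x)$tally) else list())
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' Read an abundance census written by [write_census()]
#'
#' @param file path of the TSV written by [write_census()].
#' @return an `abundance_matrix`.
#' @export
read_census <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(paste0(file, ".meta.tsv"), stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df$proteome_id
  storage.mode(g) <- "integer"
  pruned <- character(0)
  side_path <- paste0(file, ".json")
  if (file.exists(side_path))
    pruned <- unlist(jsonlite::read_json(side_path)$pruned, use.names = FALSE)
  new_abundance_matrix(g, validate_metadata(meta),
                       pruned = as.character(pruned))
}
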