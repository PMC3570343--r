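#' @name coding
#' @title 24-state ordered character coding of genomic abundance
#'
#' @description
#' Abundance counts are compressed to a 0-23 scale by
#' `round(ln(g + 1) / ln(g_max + 1) * 23)` with `g_max` the single largest
#' count in the matrix, and written with the alphanumeric alphabet 0-9, A-N.
#' The 24 levels behave as linearly ordered multistate characters: a change
#' between states i and j costs |i - j| steps. Rounding is half-up
#' (x.5 rounds away from zero), so every downstream step count is
#' reproducible.
NULL

STATE_SYMBOLS <- c(as.character(0:9), LETTERS[1:14])  # "0"-"9","A"-"N"

#' Normalize an abundance count to a 0-23 ordered state
#'
#' @param g non-negative count(s), each `<= g_max`.
#' @param g_max the maximum count in the matrix (>= 1).
#' @return integer state(s) in 0..23; 0 iff `g = 0`, 23 iff `g = g_max`.
#' @examples
#' normalize_abundance(25, 1000)  # 11
#' @export
normalize_abundance <- function(g, g_max) {
  if (length(g_max) != 1 || is.na(g_max) || g_max < 1)
    stop("g_max must be a single count >= 1")
  if (any(g < 0) || any(g > g_max)) stop("g must lie in [0, g_max]")
  x <- log(g + 1) / log(g_max + 1) * 23
  as.integer(floor(x + 0.5))  # round half-up
}

#' Map integer states 0-23 to the 0-9/A-N alphabet and back
#'
#' @param state integer vector in 0..23.
#' @return character vector of single symbols.
#' @export
state_to_symbol <- function(state) {
  state <- as.integer(state)
  if (any(is.na(state)) || any(state < 0L) || any(state > 23L))
    stop("states must be integers in 0..23")
  STATE_SYMBOLS[state + 1L]
}

#' @rdname state_to_symbol
#' @param symbol character vector of symbols from "0123456789ABCDEFGHIJKLMN".
#' @export
symbol_to_state <- function(symbol) {
  idx <- match(symbol, STATE_SYMBOLS)
  if (any(is.na(idx))) stop("unknown state symbol: ",
                            paste(unique(symbol[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Encode an abundance census as an ordered multistate character matrix
#'
#' Applies [normalize_abundance()] with the global matrix maximum. For a tree
#' of domains (`"ToD"`) FSFs are the taxa, proteomes the characters, and the
#' ancestral state is declared 23 (the most abundant state is oldest); for a
#' tree of proteomes (`"ToP"`) the grid is transposed and the ancestral state
#' is 0 (the primordial proteome is simplest).
#'
#' @param x an `abundance_matrix`.
#' @param orientation `"ToD"` or `"ToP"`.
#' @return an object of class `coded_matrix`: list with `states` (integer
#'   matrix, taxa in rows, characters in columns), `orientation`,
#'   `ancestral_state` (23 for ToD, 0 for ToP).
#' @export
encode_matrix <- function(x, orientation = c("ToD", "ToP")) {
  stopifnot(inherits(x, "abundance_matrix"))
  orientation <- match.arg(orientation)
  if (length(x$g) == 0) stop("census is empty")
  g_max <- max(x$g)
  states <- matrix(normalize_abundance(as.vector(x$g), g_max),
                   nrow = nrow(x$g), dimnames = dimnames(x$g))
  if (orientation == "ToD") states <- t(states)
  new_coded_matrix(states, orientation,
                   ancestral_state = if (orientation == "ToD") 23L else 0L)
}

new_coded_matrix <- function(states, orientation, ancestral_state) {
  stopifnot(is.matrix(states))
  storage.mode(states) <- "integer"
  if (any(states < 0L) || any(states > 23L)) stop("states must lie in 0..23")
  if (!ancestral_state %in% c(0L, 23L)) stop("ancestral state must be 0 or 23")
  if (is.null(rownames(states)) || anyDuplicated(rownames(states)))
    stop("taxa must carry unique labels")
  structure(list(states = states, orientation = orientation,
                 ancestral_state = as.integer(ancestral_state)),
            class = "coded_matrix")
}

#' @export
print.coded_matrix <- function(x, ...) {
  cat(sprintf("coded matrix (%s): %d taxa x %d ordered 24-state characters, ancestral state %d ('%s')\n",
              x$orientation, nrow(x$states), ncol(x$states),
              x$ancestral_state, state_to_symbol(x$ancestral_state)))
  invisible(x)
}

#' Write a coded character matrix
#'
#' NEXUS output declares the ordered 24-symbol alphabet in a DATA block and
#' the ancestral-state vector in an ASSUMPTIONS block; `"phylip"` writes a
#' relaxed PHYLIP matrix and `"tsv"` a plain table of integer states. All
#' three round-trip through [read_coded()].
#'
#' @param coded a `coded_matrix`.
#' @param file output path.
#' @param format `"nexus"`, `"phylip"` or `"tsv"`.
#' @return `file`, invisibly.
#' @export
write_coded <- function(coded, file, format = c("nexus", "phylip", "tsv")) {
  stopifnot(inherits(coded, "coded_matrix"))
  format <- match.arg(format)
  s <- coded$states
  rows <- apply(s, 1, function(r) paste(state_to_symbol(r), collapse = ""))
  taxa <- rownames(s)
  if (format == "nexus") {
    lines <- c(
      "#NEXUS",
      sprintf("[orientation=%s]", coded$orientation),
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(s), ncol(s)),
      sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
              paste(STATE_SYMBOLS, collapse = "")),
      "  MATRIX",
      sprintf("    %s  %s", format(taxa, width = max(nchar(taxa))), rows),
      "  ;",
      "END;",
      "BEGIN ASSUMPTIONS;",
      "  OPTIONS DEFTYPE=ORD;",
      sprintf("  ANCSTATES * anc = %s;",
              paste(rep(state_to_symbol(coded$ancestral_state), ncol(s)),
                    collapse = "")),
      "END;")
    writeLines(lines, file)
  } else if (format == "phylip") {
    lines <- c(sprintf("%d %d", nrow(s), ncol(s)),
               sprintf("%s  %s", format(taxa, width = max(nchar(taxa))), rows))
    writeLines(c(lines,
                 sprintf("# orientation=%s ancestral=%d",
                         coded$orientation, coded$ancestral_state)), file)
  } else {
    df <- data.frame(taxon = taxa, s, check.names = FALSE)
    con <- file(file, "w")
    writeLines(sprintf("# orientation=%s ancestral=%d",
                       coded$orientation, coded$ancestral_state), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(file)
}

#' Read a coded character matrix written by [write_coded()]
#'
#' @param file input path.
#' @param format `"nexus"`, `"phylip"` or `"tsv"`.
#' @return a `coded_matrix`.
#' @export
read_coded <- function(file, format = c("nexus", "phylip", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(file)
  if (format == "nexus") {
    orientation <- sub("^\\[orientation=(\\w+)\\]$", "\\1",
                       grep("^\\[orientation=", lines, value = TRUE)[1])
    mstart <- grep("^\\s*MATRIX\\s*$", lines)[1]
    mend <- mstart + grep("^\\s*;\\s*$", lines[-seq_len(mstart)])[1]
    rows <- trimws(lines[(mstart + 1):(mend - 1)])
    rows <- rows[nzchar(rows)]
    anc_line <- grep("ANCSTATES", lines, value = TRUE)[1]
    anc_sym <- substr(sub(".*=\\s*", "", anc_line), 1, 1)
    anc <- symbol_to_state(anc_sym)
  } else if (format == "phylip") {
    hdr <- lines[length(lines)]
    orientation <- sub(".*orientation=(\\w+).*", "\\1", hdr)
    anc <- as.integer(sub(".*ancestral=(\\d+).*", "\\1", hdr))
    rows <- trimws(lines[2:(length(lines) - 1)])
  } else {
    hdr <- lines[1]
    orientation <- sub(".*orientation=(\\w+).*", "\\1", hdr)
    anc <- as.integer(sub(".*ancestral=(\\d+).*", "\\1", hdr))
    df <- utils::read.delim(text = lines[-1], check.names = FALSE,
                            stringsAsFactors = FALSE)
    s <- as.matrix(df[, -1, drop = FALSE])
    rownames(s) <- df$taxon
    return(new_coded_matrix(s, orientation, anc))
  }
  parts <- regmatches(rows, regexpr("\\S+$", rows))
  taxa <- trimws(sub("\\S+$", "", rows))
  s <- t(vapply(strsplit(parts, ""), symbol_to_state,
                integer(nchar(parts[1]))))
  if (ncol(s) == 1 && length(taxa) > 1) s <- matrix(s, ncol = 1)
  rownames(s) <- taxa
  new_coded_matrix(s, orientation, anc)
}
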