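#' @keywords internal
"_PACKAGE"

## IUPAC DNA alphabet accepted in alignments; '-' is the gap symbol,
## 'N' and '?' are fully missing.
IUPAC_SYMBOLS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-", "?")

## Symbols regarded as determined character states when extracting splits
## (gap kept as a 5th state; ambiguity codes and N/? are missing).
STATE_SYMBOLS <- c("A", "C", "G", "T", "-")

#' Construct a sequence alignment
#'
#' A `seq_alignment` is a character matrix of upper-case IUPAC nucleotide
#' symbols (plus `-` for gaps and `?`/`N` for missing data), one row per
#' taxon. Optional per-taxon group metadata (e.g. wild / hulled /
#' free-threshing / outgroup) is carried as an attribute and propagated by
#' all curation operations.
#'
#' @param x character matrix with unique row names (taxon labels), or a
#'   named character vector of equal-length sequence strings.
#' @param locus optional locus name.
#' @param groups optional named character vector mapping taxon labels to a
#'   group/category tag.
#' @param orig_cols optional integer vector of original column indices
#'   (provenance through column-filtering operations).
#' @return an object of class `seq_alignment`.
#' @export
seq_alignment <- function(x, locus = NULL, groups = NULL, orig_cols = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequence vector must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      stop("alignment error: sequences have unequal lengths")
    labs <- names(x)
    x <- do.call(rbind, lapply(unname(x), function(s) strsplit(s, "")[[1]]))
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    rownames(x) <- labs
  }
  if (!is.matrix(x) || !is.character(x)) stop("x must be a character matrix")
  if (is.null(rownames(x))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x))) stop("input error: duplicate taxon labels")
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), IUPAC_SYMBOLS)
  if (length(bad))
    stop("input error: symbols outside the IUPAC DNA alphabet: ",
         paste(bad, collapse = " "))
  if (is.null(orig_cols)) orig_cols <- seq_len(ncol(x))
  if (length(orig_cols) != ncol(x)) stop("orig_cols length mismatch")
  if (!is.null(groups)) {
    extra <- setdiff(names(groups), rownames(x))
    groups <- groups[setdiff(names(groups), extra)]
  }
  structure(x, locus = locus, groups = groups,
            orig_cols = as.integer(orig_cols),
            class = c("seq_alignment", "matrix", "array"))
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d taxa x %d sites", nrow(x), ncol(x)))
  if (!is.null(attr(x, "locus"))) cat(sprintf(" [locus %s]", attr(x, "locus")))
  cat("\n")
  show <- utils::head(rownames(x), 5L)
  for (lab in show) {
    s <- paste(x[lab, seq_len(min(ncol(x), 60L))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", lab, s, if (ncol(x) > 60L) "..." else ""))
  }
  if (nrow(x) > 5L) cat(sprintf("  ... %d more taxa\n", nrow(x) - 5L))
  invisible(x)
}

## keep attributes through single-bracket subsetting of rows/columns
#' @export
`[.seq_alignment` <- function(x, i, j, ..., drop = FALSE) {
  oc <- attr(x, "orig_cols")
  m <- unclass(x)
  attr(m, "locus") <- attr(m, "groups") <- attr(m, "orig_cols") <- NULL
  out <- m[i, j, drop = FALSE]
  if (missing(j)) ocj <- oc else ocj <- oc[j]
  seq_alignment(out, locus = attr(x, "locus"), groups = attr(x, "groups"),
                orig_cols = ocj)
}

#' Taxon labels of an alignment, marker matrix or tree
#' @param x object with taxa.
#' @return character vector of labels.
#' @export
taxa_of <- function(x) {
  if (inherits(x, "phylo")) return(x$tip.label)
  if (inherits(x, "split_system")) return(x$taxa)
  if (inherits(x, "taxon_split")) return(sort(c(x$a, x$b)))
  if (is.matrix(x)) return(rownames(x))
  stop("no taxa for this object")
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param source path to a FASTA file, or a character scalar holding FASTA
#'   text (recognized by a leading `>`).
#' @param locus optional locus name stored on the alignment.
#' @param groups optional named character vector of taxon group tags.
#' @return a [seq_alignment()].
#' @export
read_alignment <- function(source, locus = NULL, groups = NULL) {
  path <- source
  if (length(source) == 1L && grepl("^\\s*>", source)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(source, path)
  } else if (length(source) > 1L) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(source, path)
  }
  if (!file.exists(path)) stop("input error: file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("input error: malformed FASTA: ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("input error: empty FASTA")
  labs <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(labs)) stop("input error: duplicate taxon labels")
  seqs <- toupper(as.character(ss))
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment error: sequences have unequal lengths")
  names(seqs) <- labs
  seq_alignment(seqs, locus = locus, groups = groups)
}

#' Write an alignment to FASTA
#' @param aln a [seq_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(aln), "\n", seqs), path)
  invisible(path)
}

#' Read a sidecar taxon metadata table
#'
#' Two- or three-column delimited table: label, category, optional region.
#' @param path file path or literal text with embedded newlines.
#' @return named character vector label -> category, with a `region`
#'   attribute when present.
#' @export
read_groups <- function(path) {
  df <- read_table_flex(path)
  if (ncol(df) < 2L) stop("input error: metadata needs >= 2 columns")
  g <- as.character(df[[2L]])
  names(g) <- as.character(df[[1L]])
  if (anyDuplicated(names(g))) stop("input error: duplicate labels in metadata")
  if (ncol(df) >= 3L) attr(g, "region") <- stats::setNames(
    as.character(df[[3L]]), names(g))
  g
}

## read a TSV/CSV from a path or from literal text
read_table_flex <- function(source, ...) {
  path <- source
  if (length(source) == 1L && grepl("\n", source)) {
    path <- tempfile()
    on.exit(unlink(path))
    writeLines(source, path)
  }
  if (!file.exists(path)) stop("input error: file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character", ...)
}
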