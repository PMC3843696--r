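#' Construct a binary insertion-marker matrix
#'
#' Presence/absence calls for dominant markers such as retrotransposon
#' insertions in rDNA arrays: 1 = insertion present, 0 = absent, `NA` =
#' missing/unscorable call.
#'
#' @param x integer/numeric matrix of 0, 1 and `NA`, with unique row names
#'   (taxa) and unique column names (markers).
#' @param groups optional named character vector of taxon group tags.
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(x, groups = NULL) {
  if (!is.matrix(x)) stop("x must be a matrix")
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("input error: rows must carry unique taxon labels")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("input error: columns must carry unique marker names")
  vals <- unique(as.vector(x))
  if (!all(vals %in% c(0L, 1L, NA_integer_)))
    stop("input error: marker calls must be 0, 1 or missing")
  structure(x, groups = groups, class = c("marker_matrix", "matrix", "array"))
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d taxa x %d markers (%d missing calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a binary marker table
#'
#' Delimited text (TSV or CSV) with a header row of marker names and taxon
#' labels in the first column. Cells must be 0, 1 or the missing token.
#'
#' @param source file path or literal table text.
#' @param missing_token string coding a missing call (default `"NA"`).
#' @param groups optional named character vector of taxon group tags.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(source, missing_token = "NA", groups = NULL) {
  df <- read_table_flex(source, na.strings = character())
  if (ncol(df) < 2L) stop("input error: marker table needs >= 2 columns")
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m == missing_token] <- NA
  bad <- setdiff(unique(as.vector(m)), c("0", "1", NA))
  if (length(bad))
    stop("input error: non-binary marker cell(s): ", paste(bad, collapse = " "))
  storage.mode(m) <- "integer"
  rownames(m) <- labs
  marker_matrix(m, groups = groups)
}

#' Write a marker matrix as TSV
#' @param mm a [marker_matrix()].
#' @param path output path.
#' @param missing_token token used for missing calls.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(mm, path, missing_token = "NA") {
  df <- data.frame(taxon = rownames(mm), unclass(mm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}
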