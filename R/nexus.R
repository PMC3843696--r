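#' Write a split system as a NEXUS TAXA + SPLITS file
#'
#' Emits the SPLITS-block dialect understood by splits-graph viewers: taxa
#' indexed 1..n in TAXA-block order, each split encoded as the index set of
#' one side plus a floating-point weight. Round-trips through
#' [read_splits_nexus()].
#'
#' @param system a [split_system()].
#' @param path output path; if missing the NEXUS text is returned.
#' @return the NEXUS text (invisibly when written to `path`).
#' @export
write_splits_nexus <- function(system, path = NULL) {
  taxa <- system$taxa
  n <- length(taxa)
  lines <- c("#NEXUS", "",
             "BEGIN TAXA;",
             sprintf("DIMENSIONS ntax=%d;", n),
             "TAXLABELS",
             sprintf("  [%d] '%s'", seq_len(n), taxa),
             ";", "END;", "",
             "BEGIN SPLITS;",
             sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(system$splits)),
             "FORMAT labels=no weights=yes;",
             "MATRIX")
  for (i in seq_along(system$splits)) {
    s <- system$splits[[i]]
    idx <- sort(match(s$a, taxa))
    lines <- c(lines, sprintf("  [%d] %g  %s,", i, s$weight,
                              paste(idx, collapse = " ")))
  }
  lines <- c(lines, ";", "END;")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a NEXUS TAXA + SPLITS file
#'
#' @param source path or NEXUS text.
#' @return a [split_system()].
#' @export
read_splits_nexus <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    lines <- readLines(source)
  else lines <- strsplit(paste(source, collapse = "\n"), "\n")[[1]]
  lines <- trimws(lines)
  ## taxa
  tl <- grep("^\\[\\d+\\]\\s+'", lines, value = TRUE)
  taxa <- sub("^\\[\\d+\\]\\s+'(.*)'\\s*$", "\\1", tl)
  if (!length(taxa)) stop("parse error: no TAXLABELS found")
  ## splits: lines inside the SPLITS MATRIX, "  [i] w  idx idx ...,"
  mstart <- grep("^MATRIX$", lines)
  mstart <- mstart[length(mstart)]
  splits <- list()
  if (length(mstart)) {
    i <- mstart + 1L
    while (i <= length(lines) && lines[i] != ";") {
      ln <- sub(",$", "", lines[i])
      ln <- sub("^\\[\\d+\\]\\s*", "", ln)
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) >= 2L) {
        w <- as.numeric(toks[1L])
        idx <- as.integer(toks[-1L])
        splits[[length(splits) + 1L]] <-
          taxon_split(taxa[idx], taxa[setdiff(seq_along(taxa), idx)],
                      weight = w)
      }
      i <- i + 1L
    }
  }
  split_system(taxa, splits)
}
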