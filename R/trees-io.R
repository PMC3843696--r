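#' Read trees from Newick text
#'
#' Reads one or more trees (one per line or semicolon-separated). Trees may
#' be partial — leaf sets are allowed to differ between trees, as for gene
#' trees sequenced for different accession subsets. Multifurcations are
#' preserved. Numeric internal node labels are kept as support values;
#' non-numeric ones are dropped.
#'
#' @param source path to a Newick file, or Newick text.
#' @param rooted logical; if `TRUE` trees are interpreted as rooted (a
#'   basal polytomy is a rooted polytomy), if `FALSE` trees are unrooted,
#'   if `NA` (default) the shape found in the file is kept.
#' @return a list of `phylo` objects.
#' @export
read_trees <- function(source, rooted = NA) {
  txt <- source
  if (length(source) == 1L && !grepl("[();]", source)) {
    if (!file.exists(source)) stop("input error: file not found: ", source)
    txt <- paste(readLines(source), collapse = "\n")
  } else txt <- paste(source, collapse = "\n")
  op <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  cl <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (op != cl) stop("parse error: unbalanced parentheses in Newick input")
  trees <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(trees)) stop("parse error: no trees found")
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    if (!is.null(tr$node.label)) {
      num <- suppressWarnings(as.numeric(tr$node.label))
      if (all(is.na(num) | tr$node.label == "")) tr$node.label <- NULL
      else tr$node.label <- ifelse(is.na(num), "", tr$node.label)
    }
    if (isFALSE(rooted) && ape::is.rooted(tr)) tr <- ape::unroot(tr)
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Write trees to Newick
#' @param trees a `phylo` or list of `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  ape::write.tree(trees, file = path)
  invisible(path)
}

## leaf set (cluster) below every internal edge of a rooted tree,
## as a list of character vectors (proper, nontrivial clusters included;
## trivial single-leaf clusters excluded)
tree_clusters <- function(phy, nontrivial_only = TRUE) {
  n <- length(phy$tip.label)
  if (is.null(phy$edge) || nrow(phy$edge) == 0L) return(list())
  desc <- descendant_tips(phy)
  out <- list()
  for (node in seq_len(phy$Nnode) + n) {
    tips <- desc[[node]]
    if (length(tips) == n) next                      # root cluster
    if (nontrivial_only && length(tips) < 2L) next
    out[[length(out) + 1L]] <- sort(phy$tip.label[tips])
  }
  unique(out)
}

## tip indices below every node (list indexed by node id)
descendant_tips <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  eo <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}
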