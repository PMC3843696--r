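#' Construct a (partial) taxon split
#'
#' A split is an unordered bipartition `A | B` of a subset of the taxa (its
#' support domain). Splits from partial gene trees or markers with missing
#' calls speak only about the taxa they were observed on. Canonical form:
#' both sides sorted, and the side containing the lexicographically smallest
#' taxon of the domain stored as `a`.
#'
#' @param a,b disjoint, nonempty character vectors of taxon labels.
#' @param weight nonnegative split weight (default 1).
#' @return an object of class `taxon_split` with fields `a`, `b`, `weight`.
#' @export
taxon_split <- function(a, b, weight = 1) {
  a <- sort(unique(as.character(a))); b <- sort(unique(as.character(b)))
  if (!length(a) || !length(b)) stop("split sides must be nonempty")
  if (length(intersect(a, b))) stop("split sides must be disjoint")
  if (weight < 0) stop("split weight must be nonnegative")
  if (b[1L] < a[1L]) { tmp <- a; a <- b; b <- tmp }
  structure(list(a = a, b = b, weight = weight), class = "taxon_split")
}

#' @export
print.taxon_split <- function(x, ...) {
  cat(sprintf("{%s} | {%s}  w=%g%s\n", paste(x$a, collapse = ","),
              paste(x$b, collapse = ","), x$weight,
              if (is_trivial_split(x)) " [trivial]" else ""))
  invisible(x)
}

#' @rdname taxon_split
#' @param s a `taxon_split`.
#' @export
split_key <- function(s) paste(paste(s$a, collapse = ","),
                               paste(s$b, collapse = ","), sep = "|")

#' @rdname taxon_split
#' @export
is_trivial_split <- function(s) min(length(s$a), length(s$b)) == 1L

#' @rdname taxon_split
#' @export
split_domain <- function(s) sort(c(s$a, s$b))

#' Construct a split system
#'
#' A collection of distinct splits over a full taxon set; duplicate splits
#' are merged (weights summed, support counts kept at the maximum).
#'
#' @param taxa character vector: the full taxon set.
#' @param splits list of [taxon_split()] objects with domains within `taxa`.
#' @return an object of class `split_system` with fields `taxa`, `splits`.
#' @export
split_system <- function(taxa, splits = list()) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("taxa must be unique")
  keys <- vapply(splits, split_key, "")
  out <- list()
  for (i in seq_along(splits)) {
    s <- splits[[i]]
    if (length(setdiff(split_domain(s), taxa)))
      stop("split mentions taxa outside the system")
    k <- keys[i]
    if (is.null(out[[k]])) out[[k]] <- s
    else {
      out[[k]]$weight <- out[[k]]$weight + s$weight
      sc <- c(attr(out[[k]], "support_count"), attr(s, "support_count"))
      if (length(sc)) attr(out[[k]], "support_count") <- max(sc)
    }
  }
  structure(list(taxa = taxa, splits = unname(out)), class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  nt <- sum(!vapply(x$splits, is_trivial_split, TRUE))
  cat(sprintf("split_system: %d taxa, %d splits (%d nontrivial)\n",
              length(x$taxa), length(x$splits), nt))
  invisible(x)
}

#' @export
length.split_system <- function(x) length(x$splits)

#' Splits from a polymorphic alignment column
#'
#' An alignment column is dissolved into splits: a binary-state column gives
#' one split (taxa with state 1 versus taxa with state 2); a column with k >
#' 2 states gives one state-versus-rest split per state. Taxa with a missing
#' symbol at the column are excluded from both sides (partial split). Gaps
#' count as a 5th character state; ambiguity codes and `N`/`?` are missing.
#'
#' @param aln a [seq_alignment()].
#' @param column column index.
#' @return list of [taxon_split()] (deduplicated, canonical).
#' @export
split_from_column <- function(aln, column) {
  col <- unclass(aln)[, column]
  keep <- col %in% STATE_SYMBOLS
  states <- unique(col[keep])
  if (length(states) < 2L)
    stop("monomorphic column: no split at column ", column)
  labs <- rownames(aln)
  if (length(states) == 2L) {
    return(list(taxon_split(labs[keep & col == states[1L]],
                            labs[keep & col == states[2L]])))
  }
  out <- list()
  for (st in states) {
    s <- taxon_split(labs[keep & col == st], labs[keep & col != st])
    out[[split_key(s)]] <- s
  }
  unname(out)
}

#' Split from a binary marker
#'
#' The marker's presence side versus its absence side; taxa with missing
#' calls are excluded. Markers present (or absent) in a single taxon are
#' phylogenetically uninformative and are flagged with attribute
#' `uninformative = TRUE` so callers can discard them.
#'
#' @param mm a [marker_matrix()].
#' @param marker marker (column) name.
#' @return a [taxon_split()], possibly flagged uninformative.
#' @export
split_from_marker <- function(mm, marker) {
  v <- unclass(mm)[, marker]
  pres <- rownames(mm)[!is.na(v) & v == 1L]
  abs_ <- rownames(mm)[!is.na(v) & v == 0L]
  if (!length(pres) || !length(abs_))
    stop("constant marker: ", marker, " has no split")
  s <- taxon_split(pres, abs_)
  if (min(length(pres), length(abs_)) == 1L) attr(s, "uninformative") <- TRUE
  s
}

#' All informative splits of a marker matrix
#'
#' @param mm a [marker_matrix()].
#' @param drop_uninformative drop singleton (single-sample) markers,
#'   mirroring the rule that insertions seen in only one sample carry no
#'   grouping signal.
#' @return list of [taxon_split()], named by marker.
#' @export
splits_from_markers <- function(mm, drop_uninformative = TRUE) {
  out <- list()
  for (m in colnames(mm)) {
    s <- tryCatch(split_from_marker(mm, m), error = function(e) NULL)
    if (is.null(s)) next
    if (drop_uninformative && isTRUE(attr(s, "uninformative"))) next
    out[[m]] <- s
  }
  out
}

#' Splits induced by a tree
#'
#' One split per internal edge: the leaves below the edge versus the rest of
#' the tree's own leaf set (partial trees give partial splits relative to a
#' larger study). Optionally includes the trivial splits of pendant edges.
#'
#' @param t a `phylo`.
#' @param include_trivial include one singleton split per leaf.
#' @return a [split_system()] over the tree's leaves.
#' @export
splits_from_tree <- function(t, include_trivial = FALSE) {
  labs <- t$tip.label
  cl <- tree_clusters(if (ape::is.rooted(t)) t else
    ape::root(t, outgroup = labs[1L], resolve.root = FALSE))
  sp <- list()
  for (X in cl) {
    rest <- setdiff(labs, X)
    if (!length(rest)) next
    s <- taxon_split(X, rest)
    sp[[split_key(s)]] <- s
  }
  sp <- Filter(Negate(is_trivial_split), sp)
  if (include_trivial)
    for (x in labs) {
      s <- taxon_split(x, setdiff(labs, x))
      sp[[split_key(s)]] <- s
    }
  split_system(labs, unname(sp))
}

#' Split compatibility (four-point / four-gamete criterion)
#'
#' Two (partial) splits are compared on their common support domain; they
#' are compatible iff at least one of the four side intersections is empty.
#' Splits sharing fewer than four taxa are always compatible.
#'
#' @param s,t [taxon_split()] objects.
#' @return logical.
#' @export
are_compatible <- function(s, t) {
  dom <- intersect(split_domain(s), split_domain(t))
  if (length(dom) < 4L) return(TRUE)
  a1 <- intersect(s$a, dom); b1 <- intersect(s$b, dom)
  a2 <- intersect(t$a, dom); b2 <- intersect(t$b, dom)
  if (!length(a1) || !length(b1) || !length(a2) || !length(b2)) return(TRUE)
  !length(intersect(a1, a2)) || !length(intersect(a1, b2)) ||
    !length(intersect(b1, a2)) || !length(intersect(b1, b2))
}

#' Restrict a split to a taxon subset
#'
#' @param s a [taxon_split()].
#' @param taxa character vector.
#' @return the restricted split, or `NULL` if either side becomes empty.
#' @export
restrict_split <- function(s, taxa) {
  a <- intersect(s$a, taxa); b <- intersect(s$b, taxa)
  if (!length(a) || !length(b)) return(NULL)
  taxon_split(a, b, weight = s$weight)
}
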