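## Pairwise rooted-tree conflict analysis: restrict tree pairs to common
## taxa, flag conflicting cluster structure, and compute the minimum number
## of hybridization events explaining a conflict via exact maximum acyclic
## agreement forest (MAAF) search -- h = |MAAF| - 1, found by iterative
## deepening over the number of edges cut in the first tree.

#' Restrict a tree pair to their common taxa
#'
#' @param t1,t2 `phylo` trees sharing at least two leaves.
#' @return list of the two restricted trees (degree-2 nodes suppressed).
#' @export
restrict_pair <- function(t1, t2) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 2L)
    stop("fewer than 2 common taxa: cannot compare trees")
  r <- function(t) {
    if (length(common) == length(t$tip.label)) return(t)
    ape::keep.tip(t, common)
  }
  list(r(t1), r(t2))
}

## rooted-cluster incompatibility: neither nested nor disjoint
clusters_incompatible <- function(X, Y) {
  i <- length(intersect(X, Y))
  i > 0L && i < length(X) && i < length(Y)
}

#' Do two rooted trees conflict?
#'
#' After restriction to common taxa, `TRUE` iff some cluster of one tree is
#' incompatible (overlapping but not nested) with some cluster of the other.
#'
#' @param t1,t2 rooted `phylo` trees.
#' @return logical.
#' @export
trees_conflict <- function(t1, t2) {
  p <- restrict_pair(t1, t2)
  c1 <- tree_clusters(p[[1L]])
  c2 <- tree_clusters(p[[2L]])
  for (X in c1) for (Y in c2)
    if (clusters_incompatible(X, Y)) return(TRUE)
  FALSE
}

## ---- agreement forest machinery ----------------------------------------

## rooted tree -> internal representation with an added root leaf "rho":
## list(parent = named parent map over node ids, leafset, clusters)
af_tree <- function(phy, rho = ".rho") {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  parent <- integer(nn); parent[] <- 0L
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- which(parent == 0L)[1L]
  ## attach rho above the root: new root id nn+1, rho leaf id nn+2
  parent <- c(parent, 0L, nn + 1L)
  parent[root] <- nn + 1L
  labels <- c(phy$tip.label, rep(NA_character_, phy$Nnode), NA, rho)
  leaf_ids <- c(seq_len(n), nn + 2L)
  list(parent = parent, labels = labels, leaf_ids = leaf_ids,
       leaves = labels[leaf_ids], root = nn + 1L)
}

af_ancestors <- function(tr, v) {
  out <- integer()
  while (tr$parent[v] != 0L) { v <- tr$parent[v]; out <- c(out, v) }
  out
}

## nodes on paths between the leaves of X (spanning/Steiner nodes incl. mrca)
af_span <- function(tr, X) {
  ids <- tr$leaf_ids[match(X, tr$leaves)]
  if (length(ids) == 1L) return(ids)
  anc <- lapply(ids, function(v) c(v, af_ancestors(tr, v)))
  common <- Reduce(intersect, anc)
  mrca <- common[1L]
  span <- unique(unlist(lapply(anc, function(a) a[seq_len(match(mrca, a))])))
  span
}

af_mrca <- function(tr, X) {
  ids <- tr$leaf_ids[match(X, tr$leaves)]
  if (length(ids) == 1L) return(ids)
  anc <- lapply(ids, function(v) c(v, af_ancestors(tr, v)))
  Reduce(intersect, anc)[1L]
}

## nontrivial proper clusters of the restriction of tr to leaf set X,
## as a sorted key set
af_restricted_clusters <- function(tr, X) {
  ids <- tr$leaf_ids[match(X, tr$leaves)]
  keys <- character()
  if (length(X) < 3L) return(keys)
  anc <- lapply(ids, function(v) c(v, af_ancestors(tr, v)))
  names(anc) <- X
  nodes <- unique(unlist(anc))
  for (v in nodes) {
    below <- X[vapply(anc, function(a) v %in% a, TRUE)]
    if (length(below) >= 2L && length(below) < length(X))
      keys <- c(keys, paste(sort(below), collapse = ","))
  }
  sort(unique(keys))
}

## is the leaf partition `parts` an acyclic agreement forest for tr1, tr2?
af_valid <- function(tr1, tr2, parts) {
  ## agreement: identical restricted cluster sets in both trees
  for (X in parts)
    if (!identical(af_restricted_clusters(tr1, X),
                   af_restricted_clusters(tr2, X))) return(FALSE)
  ## node-disjoint spanning subtrees in both trees
  for (tr in list(tr1, tr2)) {
    spans <- lapply(parts, function(X) af_span(tr, X))
    all_nodes <- unlist(spans)
    if (anyDuplicated(all_nodes)) return(FALSE)
  }
  ## acyclicity of the inheritance digraph over components
  k <- length(parts)
  if (k > 1L) {
    adj <- matrix(FALSE, k, k)
    for (tr in list(tr1, tr2)) {
      roots <- lapply(parts, function(X) af_mrca(tr, X))
      ancs <- lapply(roots, function(v) af_ancestors(tr, v))
      for (i in seq_len(k)) for (j in seq_len(k))
        if (i != j && roots[[i]] %in% ancs[[j]]) adj[i, j] <- TRUE
    }
    ## cycle detection (Kahn)
    indeg <- colSums(adj)
    active <- rep(TRUE, k)
    repeat {
      z <- which(active & indeg == 0L)
      if (!length(z)) break
      active[z] <- FALSE
      indeg <- indeg - colSums(adj[z, , drop = FALSE])
    }
    if (any(active)) return(FALSE)
  }
  TRUE
}

## components (leaf partitions) obtained by deleting edge set `cut`
## (indexed by child node) from tr
af_components <- function(tr, cut) {
  find_comp <- function(v) {
    while (tr$parent[v] != 0L && !(v %in% cut)) v <- tr$parent[v]
    v
  }
  comp <- vapply(tr$leaf_ids, find_comp, 1L)
  unname(split(tr$leaves, comp))
}

## enumerate binary resolutions of a multifurcating rooted tree (ape phylo);
## polytomies of degree > cap raise an error
resolve_multifurcations <- function(phy, cap = 5L) {
  if (ape::is.binary(phy)) return(list(phy))
  deg <- tabulate(phy$edge[, 1L])
  if (max(deg) > cap)
    stop("polytomy of degree ", max(deg), " exceeds resolution cap ", cap)
  res <- list()
  nres <- 200L
  for (i in seq_len(nres)) {
    r <- ape::multi2di(phy, random = TRUE)
    res[[edges_split_key(phylo_to_edges(r, r$tip.label), r$tip.label)]] <- r
    if (length(res) >= 100L) break
  }
  unname(res)
}

#' Minimum hybridization number of a rooted tree pair
#'
#' The smallest number h of hybridization events such that both trees can
#' be explained by a network with h reticulations; equal to the size of a
#' maximum acyclic agreement forest minus one. Found exactly by iterative
#' deepening: for h = 0, 1, ... all ways of cutting h edges of the first
#' tree are tested for yielding an acyclic agreement forest with the
#' second. Multifurcations are soft: the minimum over (a bounded sample of)
#' binary resolutions is returned.
#'
#' @param t1,t2 rooted `phylo` trees (restricted to common taxa first if
#'   necessary).
#' @param cap search cap; `cap + 1` is returned as a sentinel when no
#'   forest within `cap` cuts exists.
#' @param exact_limit largest common-taxon count accepted (default 12).
#' @return integer h (or `cap + 1`).
#' @export
min_hybridization <- function(t1, t2, cap = 8L, exact_limit = 12L) {
  p <- restrict_pair(t1, t2)
  t1 <- p[[1L]]; t2 <- p[[2L]]
  if (length(t1$tip.label) > exact_limit)
    stop("more than ", exact_limit,
         " common taxa: subsample before exact hybridization counting")
  if (!trees_conflict(t1, t2)) return(0L)
  r1 <- resolve_multifurcations(t1)
  r2 <- resolve_multifurcations(t2)
  best <- cap + 1L
  for (a in r1) for (b in r2) {
    h <- maaf_search(a, b, cap = min(cap, best))
    if (h < best) best <- h
    if (best == 1L) break
  }
  as.integer(best)
}

maaf_search <- function(t1, t2, cap) {
  tr1 <- af_tree(t1)
  tr2 <- af_tree(t2)
  ## candidate cut edges: all non-root edges of tr1 (indexed by child),
  ## excluding the rho pendant edge
  cand <- which(tr1$parent != 0L)
  cand <- setdiff(cand, tr1$leaf_ids[length(tr1$leaf_ids)])
  for (h in seq_len(cap)) {
    for (cut in utils::combn(cand, h, simplify = FALSE)) {
      parts <- af_components(tr1, cut)
      if (length(parts) != h + 1L) next
      if (af_valid(tr1, tr2, parts)) return(h)
    }
  }
  cap + 1L
}

#' Pairwise conflict and hybridization report
#'
#' Examines all unordered pairs of a tree list: restricts each pair to
#' common taxa, flags conflicts, and computes the minimum hybridization
#' number for conflicting pairs (NA when the common taxon count exceeds the
#' exact limit). The mean is taken over conflicting pairs only.
#'
#' @param trees list of rooted `phylo` trees.
#' @param cap passed to [min_hybridization()].
#' @param exact_limit passed to [min_hybridization()].
#' @return object of class `pairwise_conflict_report`: list with `n_pairs`,
#'   `n_conflicting`, `pairs` (data.frame), `mean_hybridizations`.
#' @export
pairwise_report <- function(trees, cap = 8L, exact_limit = 12L) {
  k <- length(trees)
  if (k < 2L) stop("need >= 2 trees")
  rows <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    common <- length(intersect(trees[[i]]$tip.label, trees[[j]]$tip.label))
    if (common < 2L) {
      rows <- rbind(rows, data.frame(i = i, j = j, common = common,
                                     conflict = FALSE, h = 0L))
      next
    }
    cf <- trees_conflict(trees[[i]], trees[[j]])
    h <- 0L
    if (cf) {
      h <- tryCatch(min_hybridization(trees[[i]], trees[[j]], cap, exact_limit),
                    error = function(e) NA_integer_)
      if (is.na(h)) warning("pair (", i, ",", j, ") exceeds exact limit; h = NA")
    }
    rows <- rbind(rows, data.frame(i = i, j = j, common = common,
                                   conflict = cf, h = h))
  }
  hc <- rows$h[rows$conflict]
  mh <- if (any(rows$conflict)) round(mean(hc, na.rm = TRUE), 1L) else NA_real_
  structure(list(n_pairs = nrow(rows),
                 n_conflicting = sum(rows$conflict),
                 pairs = rows,
                 mean_hybridizations = mh),
            class = "pairwise_conflict_report")
}

#' @export
print.pairwise_conflict_report <- function(x, ...) {
  cat(sprintf("pairwise_conflict_report: %d/%d pairs conflicting",
              x$n_conflicting, x$n_pairs))
  if (!is.na(x$mean_hybridizations))
    cat(sprintf("; mean %.1f hybridizations per conflicting pair",
                x$mean_hybridizations))
  cat("\n")
  invisible(x)
}
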