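## Synthetic-data generators with planted, fully recorded ground truth:
## homoplasy-free alignments evolved on a tree, binary marker matrices with
## planted hybrid (mosaic) accessions, and sets of per-locus gene trees
## with planted hybridization (lineage-transfer) events and taxon dropout.
## Every generator is deterministic under a fixed seed and returns a
## `truth` object sufficient to score recovery without reopening internals.

#' Simulate a homoplasy-free alignment on a tree
#'
#' Infinite-sites-style generation: each variable site receives exactly one
#' mutation, placed on an edge with probability proportional to edge length
#' (uniform lengths when absent), so every nontrivial column split is a
#' tree split and the data are free of homoplasy. With probability
#' `1 - subst_rate` a site is left invariant. A finite-sites stress mode
#' places a Poisson number of mutations per site instead, admitting
#' homoplasy.
#'
#' @param t a `phylo` (rooted or unrooted; rooted internally at a leaf).
#' @param L number of sites.
#' @param subst_rate probability that a site is variable (default 1).
#' @param seed RNG seed.
#' @param distinct_sites if `TRUE`, sample mutation edges without
#'   replacement; an error is raised when `L` exceeds the number of
#'   available edges (distinct site patterns).
#' @param model `"infinite"` (default) or `"finite"`.
#' @return list with `alignment` (a [seq_alignment()]) and `truth` (list:
#'   `tree`, `site_edges`, `splits` = planted split keys).
#' @export
gen_alignment_on_tree <- function(t, L, subst_rate = 1, seed = 1L,
                                  distinct_sites = FALSE,
                                  model = c("infinite", "finite")) {
  model <- match.arg(model)
  set.seed(seed)
  phy <- if (ape::is.rooted(t)) t else
    ape::root(t, outgroup = t$tip.label[1L], resolve.root = TRUE)
  ne <- nrow(phy$edge)
  elen <- if (is.null(phy$edge.length)) rep(1, ne) else phy$edge.length
  desc <- descendant_tips(phy)
  n <- length(phy$tip.label)
  bases <- c("A", "C", "G", "T")
  aln <- matrix("A", n, L, dimnames = list(phy$tip.label, NULL))
  site_edges <- rep(NA_integer_, L)
  variable <- stats::runif(L) < subst_rate
  if (model == "infinite") {
    if (distinct_sites) {
      if (sum(variable) > ne)
        stop("L exceeds available distinct patterns (", ne, " edges)")
      eidx <- sample.int(ne, sum(variable), prob = elen)
    } else {
      eidx <- sample.int(ne, sum(variable), replace = TRUE, prob = elen)
    }
    site_edges[variable] <- eidx
    for (s in which(variable)) {
      anc <- sample(bases, 1L)
      der <- sample(setdiff(bases, anc), 1L)
      below <- desc[[phy$edge[site_edges[s], 2L]]]
      aln[, s] <- anc
      aln[below, s] <- der
    }
  } else {
    for (s in seq_len(L)) {
      if (!variable[s]) next
      nmut <- max(1L, stats::rpois(1L, 2))
      col <- rep(sample(bases, 1L), n)
      for (m in seq_len(nmut)) {
        e <- sample.int(ne, 1L, prob = elen)
        below <- desc[[phy$edge[e, 2L]]]
        col[below] <- sample(bases, 1L)
      }
      aln[, s] <- col
    }
  }
  planted <- character()
  for (s in which(!is.na(site_edges))) {
    below <- desc[[phy$edge[site_edges[s], 2L]]]
    if (length(below) >= 2L && length(below) <= n - 2L)
      planted <- c(planted, split_key(
        taxon_split(phy$tip.label[below], phy$tip.label[-below])))
  }
  list(alignment = seq_alignment(aln),
       truth = list(tree = phy, site_edges = site_edges,
                    splits = sort(unique(planted))))
}

#' Generate a marker matrix with planted hybrid accessions
#'
#' Populations carry diagnostic marker blocks (every member of population p
#' has the markers of block p and no others), so individual markers can be
#' shared along population lines while marker combinations remain
#' group-specific. Each planted hybrid is a per-marker mosaic of two
#' parental populations, guaranteed to carry at least one marker from each
#' parent's block — creating marker combinations absent from any parental
#' population although every individual marker exists in a parent.
#'
#' @param n_per_pop integer vector of population sizes (default three
#'   populations of 4: two parental gene pools plus an outgroup population,
#'   the minimal design in which a hybrid's two marker classes are
#'   incompatible and display as a box).
#' @param n_markers total marker count, split evenly into diagnostic blocks.
#' @param hybrid_spec list of `c(parentA, parentB, mixture)` rows: parental
#'   population indices and the probability a marker of the combined
#'   parental block set is inherited from parent A.
#' @param seed RNG seed.
#' @return list with `markers` (a [marker_matrix()]) and `truth` (list:
#'   `blocks` (marker -> population), `hybrids` (data.frame), expected
#'   diagnostic split keys per hybrid in `hybrid_splits`).
#' @export
gen_hybrid_markers <- function(n_per_pop = c(4L, 4L, 4L), n_markers = 12L,
                               hybrid_spec = list(c(1L, 2L, 0.5)),
                               seed = 1L) {
  k <- length(n_per_pop)
  stopifnot(k >= 2L, n_markers >= k)
  set.seed(seed)
  block <- rep(seq_len(k), length.out = n_markers)
  block <- sort(block)
  marker_names <- sprintf("M%02d_p%d", seq_len(n_markers), block)
  pop_of <- rep(seq_len(k), n_per_pop)
  taxa <- sprintf("P%d_%02d", pop_of, unlist(lapply(n_per_pop, seq_len)))
  m <- matrix(0L, length(taxa), n_markers,
              dimnames = list(taxa, marker_names))
  for (i in seq_along(taxa)) m[i, block == pop_of[i]] <- 1L
  hybrids <- NULL
  hybrid_splits <- list()
  for (hidx in seq_along(hybrid_spec)) {
    hs <- hybrid_spec[[hidx]]
    pa <- as.integer(hs[1L]); pb <- as.integer(hs[2L]); mix <- as.numeric(hs[3L])
    lab <- sprintf("H%d_p%dx%d", hidx, pa, pb)
    row <- integer(n_markers)
    sel <- block %in% c(pa, pb)
    from_a <- stats::runif(n_markers) < mix
    row[sel] <- ifelse(from_a[sel], block[sel] == pa, block[sel] == pb)
    ## guarantee the mosaic: >= 1 marker from each parental block
    if (!any(row[block == pa] == 1L)) row[which(block == pa)[1L]] <- 1L
    if (!any(row[block == pb] == 1L)) row[which(block == pb)[1L]] <- 1L
    m <- rbind(m, row)
    rownames(m)[nrow(m)] <- lab
    hybrids <- rbind(hybrids, data.frame(hybrid = lab, parent_a = pa,
                                         parent_b = pb, mixture = mix))
    ## diagnostic splits the hybrid's markers induce: hybrid with parent A
    ## versus the rest, and hybrid with parent B versus the rest
    pa_taxa <- taxa[pop_of == pa]; pb_taxa <- taxa[pop_of == pb]
    all_t <- c(taxa, lab)
    hybrid_splits[[lab]] <- c(
      with_a = split_key(taxon_split(c(pa_taxa, lab),
                                     setdiff(all_t, c(pa_taxa, lab)))),
      with_b = split_key(taxon_split(c(pb_taxa, lab),
                                     setdiff(all_t, c(pb_taxa, lab)))))
  }
  groups <- stats::setNames(c(paste0("pop", pop_of),
                              rep("hybrid", length(hybrid_spec))),
                            rownames(m))
  list(markers = marker_matrix(m, groups = groups),
       truth = list(blocks = stats::setNames(block, marker_names),
                    populations = stats::setNames(pop_of, taxa),
                    hybrids = hybrids, hybrid_splits = hybrid_splits))
}

#' Generate discordant per-locus gene trees
#'
#' Each locus tree starts from the species tree and receives `hybrid_edges`
#' random lineage-transfer events (a leaf pruned and regrafted onto another
#' edge: a rooted SPR move, modelling introgression into one accession),
#' then loses each leaf with probability `taxon_dropout` to emulate partial
#' per-locus taxon coverage. Trees are kept when at least four leaves
#' survive.
#'
#' @param species_tree rooted `phylo`.
#' @param n_loci number of gene trees.
#' @param hybrid_edges planted events per locus (default 0).
#' @param taxon_dropout per-leaf dropout probability (default 0).
#' @param seed RNG seed.
#' @return list with `trees` (list of `phylo`) and `truth` (list:
#'   `species_tree`, `moves` data.frame of per-locus planted events).
#' @export
gen_discordant_trees <- function(species_tree, n_loci, hybrid_edges = 0L,
                                 taxon_dropout = 0, seed = 1L) {
  stopifnot(hybrid_edges >= 0L)
  set.seed(seed)
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  trees <- vector("list", n_loci)
  moves <- NULL
  for (l in seq_len(n_loci)) {
    tr <- species_tree
    for (e in seq_len(hybrid_edges)) {
      tr2 <- random_leaf_spr(tr)
      moves <- rbind(moves, data.frame(locus = l, event = e,
                                       leaf = attr(tr2, "moved_leaf")))
      attr(tr2, "moved_leaf") <- NULL
      tr <- tr2
    }
    if (taxon_dropout > 0) {
      repeat {
        drop <- which(stats::runif(length(tr$tip.label)) < taxon_dropout)
        if (length(tr$tip.label) - length(drop) >= 4L) break
      }
      if (length(drop)) tr <- ape::drop.tip(tr, drop)
    }
    trees[[l]] <- tr
  }
  list(trees = trees,
       truth = list(species_tree = species_tree, moves = moves))
}

## one random leaf prune-and-regraft on a rooted tree; the reattachment
## edge is required to change the topology (not the leaf's original edge
## or its sibling edge)
random_leaf_spr <- function(phy) {
  n <- length(phy$tip.label)
  stopifnot(n >= 4L)
  repeat {
    tip <- sample.int(n, 1L)
    lab <- phy$tip.label[tip]
    pruned <- ape::drop.tip(phy, tip)
    ## candidate attachment edges: all edges of the pruned tree
    ne <- nrow(pruned$edge)
    e <- sample.int(ne, 1L)
    out <- add_tip_on_edge(pruned, e, lab)
    if (!identical(sort_key_tree(out), sort_key_tree(phy))) {
      attr(out, "moved_leaf") <- lab
      return(out)
    }
  }
}

## attach a new leaf in the middle of edge row e of a rooted phylo
add_tip_on_edge <- function(phy, e, label) {
  n <- length(phy$tip.label)
  ## renumber: new tip id n+1 -> old internals shift by 1
  edge <- phy$edge
  edge[edge > n] <- edge[edge > n] + 1L
  u <- edge[e, 1L]; v <- edge[e, 2L]
  w <- n + 1L + phy$Nnode + 1L      # new internal id (appended)
  edge[e, ] <- c(u, w)
  edge <- rbind(edge, c(w, v), c(w, n + 1L))
  out <- list(edge = edge, tip.label = c(phy$tip.label, label),
              Nnode = phy$Nnode + 1L)
  class(out) <- "phylo"
  out
}

## canonical rooted-topology key (sorted cluster keys)
sort_key_tree <- function(phy) {
  cl <- tree_clusters(phy, nontrivial_only = FALSE)
  paste(sort(vapply(cl, paste, "", collapse = ",")), collapse = ";")
}
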