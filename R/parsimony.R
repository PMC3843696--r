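## Maximum parsimony: Hartigan/Fitch small-parsimony scoring (exact on
## multifurcating trees), exhaustive search for small taxon sets, and a
## jumbled stepwise-addition + NNI heuristic above that, with bootstrap,
## consensus and the concatenated-vs-per-locus incongruence ratio.

## bitmask encoding of IUPAC symbols; A=1 C=2 G=4 T=8, gap optionally 16
iupac_masks <- function(gap_as_state = FALSE) {
  m <- c(A = 1L, C = 2L, G = 4L, T = 8L,
         R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
         B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, "?" = 15L)
  if (gap_as_state) {
    m["-"] <- 16L
    m["?"] <- 31L
  } else m["-"] <- 15L
  m
}

## compress an alignment into unique column patterns of bitmasks
## -> list(masks = taxa x patterns integer matrix, weights, taxa)
encode_patterns <- function(aln, gap_as_state = FALSE) {
  mm <- iupac_masks(gap_as_state)
  m <- unclass(aln)
  enc <- matrix(mm[m], nrow(m), ncol(m))
  if (anyNA(enc)) stop("unencodable symbol in alignment")
  keys <- apply(enc, 2L, paste, collapse = ",")
  first <- !duplicated(keys)
  w <- as.vector(table(factor(keys, levels = keys[first])))
  list(masks = enc[, first, drop = FALSE], weights = w, taxa = rownames(m))
}

## per-pattern minimum-change counts on a rooted edge matrix.
## edges: (parent, child) integer matrix; leaves 1..n index rows of
## leaf_masks; internal ids arbitrary > n. Hartigan's bottom-up pass:
## exact for binary and multifurcating nodes alike.
fitch_patterns <- function(edges, leaf_masks, n_leaves, bits = c(1L, 2L, 4L, 8L, 16L)) {
  P <- ncol(leaf_masks)
  maxid <- max(edges)
  M <- matrix(0L, maxid, P)
  M[seq_len(n_leaves), ] <- leaf_masks
  kids <- split(edges[, 2L], edges[, 1L])
  root <- setdiff(unique(edges[, 1L]), edges[, 2L])
  ## postorder over internal nodes
  po <- integer(0); stack <- root; seen <- logical(maxid)
  while (length(stack)) {
    v <- stack[length(stack)]
    ch <- kids[[as.character(v)]]
    ch_int <- ch[ch > n_leaves & !seen[ch]]
    if (length(ch_int)) stack <- c(stack, ch_int)
    else { po <- c(po, v); stack <- stack[-length(stack)] }
    seen[v] <- TRUE
  }
  cost <- numeric(P)
  for (v in po) {
    ch <- kids[[as.character(v)]]
    if (length(ch) == 2L) {
      i <- bitwAnd(M[ch[1L], ], M[ch[2L], ])
      z <- i == 0L
      cost <- cost + z
      M[v, ] <- ifelse(z, bitwOr(M[ch[1L], ], M[ch[2L], ]), i)
    } else {
      cnt <- matrix(0L, length(bits), P)
      for (c_ in ch) for (b in seq_along(bits))
        cnt[b, ] <- cnt[b, ] + as.integer(bitwAnd(M[c_, ], bits[b]) > 0L)
      mx <- apply(cnt, 2L, max)
      cost <- cost + (length(ch) - mx)
      sel <- cnt == rep(mx, each = length(bits))
      M[v, ] <- as.integer(colSums(sel * bits))
    }
  }
  cost
}

## map a phylo to an edge matrix whose leaf ids index `taxa`
phylo_to_edges <- function(phy, taxa) {
  idx <- match(phy$tip.label, taxa)
  if (anyNA(idx)) stop("leaf without sequence: ",
                       paste(phy$tip.label[is.na(idx)], collapse = ", "))
  n <- length(phy$tip.label)
  e <- phy$edge
  remap <- function(v) ifelse(v <= n, idx[v], v - n + length(taxa))
  cbind(remap(e[, 1L]), remap(e[, 2L]))
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of character changes over the tree, summed across
#' alignment columns (Hartigan's generalization: multifurcations are scored
#' exactly as given, not resolved). Missing symbols and, by default, gaps
#' act as wildcards carrying the full state set.
#'
#' @param t a `phylo`; leaves must be a subset of the alignment's taxa.
#' @param aln a [seq_alignment()].
#' @param gap_as_state score `-` as a 5th state instead of missing.
#' @return integer parsimony length.
#' @export
fitch_score <- function(t, aln, gap_as_state = FALSE) {
  enc <- encode_patterns(aln, gap_as_state)
  keep <- match(t$tip.label, enc$taxa)
  if (anyNA(keep)) stop("leaf without sequence: ",
                        paste(t$tip.label[is.na(keep)], collapse = ", "))
  edges <- phylo_to_edges(t, enc$taxa)
  as.integer(sum(enc$weights *
                   fitch_patterns(edges, enc$masks, length(enc$taxa))))
}

## --- tree enumeration and surgery on raw edge matrices -------------------

## all unrooted binary topologies on leaf ids `leaves` (displayed with a
## basal trichotomy); internal ids start at id0
all_topologies <- function(leaves, id0) {
  base <- cbind(id0, leaves[1:3])
  trees <- list(base)
  nxt <- id0 + 1L
  for (k in seq_along(leaves)[-(1:3)]) {
    x <- leaves[k]
    trees <- unlist(lapply(trees, function(e) {
      lapply(seq_len(nrow(e)), function(r) insert_leaf(e, r, x, nxt))
    }), recursive = FALSE)
    nxt <- nxt + 1L
  }
  trees
}

## attach leaf x onto edge row r: (u,v) -> (u,w),(w,v),(w,x)
insert_leaf <- function(edges, r, x, w) {
  u <- edges[r, 1L]; v <- edges[r, 2L]
  edges[r, ] <- c(u, w)
  rbind(edges, c(w, v), c(w, x))
}

## the two NNI rearrangements across internal edge row r (child end internal)
nni_neighbors <- function(edges, r) {
  u <- edges[r, 1L]; v <- edges[r, 2L]
  a_rows <- which(edges[, 1L] == u & edges[, 2L] != v)
  c_rows <- which(edges[, 1L] == v)
  if (!length(a_rows) || length(c_rows) != 2L) return(list())
  ar <- a_rows[1L]
  lapply(c_rows, function(cr) {
    e2 <- edges
    tmp <- e2[ar, 2L]
    e2[ar, 2L] <- e2[cr, 2L]
    e2[cr, 2L] <- tmp
    e2
  })
}

## canonical topology key: sorted nontrivial split keys over leaf labels
edges_split_key <- function(edges, taxa) {
  n_leaves <- length(taxa)
  kids <- split(edges[, 2L], edges[, 1L])
  below <- function(v) {
    if (v <= n_leaves) return(v)
    unlist(lapply(kids[[as.character(v)]], below))
  }
  internal_children <- edges[edges[, 2L] > n_leaves, 2L]
  keys <- vapply(internal_children, function(v) {
    tips <- sort(below(v))
    if (length(tips) < 2L || length(tips) > n_leaves - 2L) return(NA_character_)
    split_key(taxon_split(taxa[tips], taxa[-tips]))
  }, "")
  paste(sort(keys[!is.na(keys)]), collapse = ";")
}

edges_to_phylo <- function(edges, taxa) {
  n <- length(taxa)
  ints <- sort(unique(edges[edges > n]))
  remap <- c(seq_len(n), rep(NA_integer_, max(edges) - n))
  remap[ints] <- n + seq_along(ints)
  e <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
  phy <- list(edge = e, tip.label = taxa, Nnode = length(ints))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

score_edges <- function(edges, enc) {
  sum(enc$weights * fitch_patterns(edges, enc$masks, length(enc$taxa)))
}

#' Maximum-parsimony tree search
#'
#' Exact search over all unrooted binary topologies when the taxon count is
#' at most `exhaustive_limit`; otherwise a heuristic of `n_jumbles`
#' restarts, each inserting taxa stepwise in a random order and hill
#' climbing by nearest-neighbour interchange to a local optimum. All
#' distinct best-scoring topologies found are returned.
#'
#' @param aln a [seq_alignment()] with >= 3 taxa.
#' @param n_jumbles number of random-addition restarts (default 10).
#' @param seed RNG seed for the jumbles.
#' @param exhaustive_limit largest taxon count searched exactly (default 9).
#' @param gap_as_state passed to the Fitch scorer.
#' @return object of class `mp_result`: list with `trees` (list of `phylo`),
#'   `score`, `method`.
#' @export
mp_search <- function(aln, n_jumbles = 10L, seed = 1L, exhaustive_limit = 9L,
                      gap_as_state = FALSE) {
  enc <- encode_patterns(aln, gap_as_state)
  res <- mp_search_core(enc, n_jumbles, seed, exhaustive_limit)
  trees <- lapply(res$edges, edges_to_phylo, taxa = enc$taxa)
  structure(list(trees = trees, score = as.integer(res$score),
                 method = res$method), class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("mp_result: %d best tree(s), score %d (%s search)\n",
              length(x$trees), x$score, x$method))
  invisible(x)
}

mp_search_core <- function(enc, n_jumbles, seed, exhaustive_limit) {
  n <- length(enc$taxa)
  if (n < 3L) stop("need >= 3 taxa")
  if (n == 3L) {
    e <- cbind(n + 1L, 1:3)
    return(list(edges = list(e), score = score_edges(e, enc),
                method = "exhaustive"))
  }
  if (n <= exhaustive_limit) {
    all_t <- all_topologies(seq_len(n), n + 1L)
    scores <- vapply(all_t, score_edges, 0, enc = enc)
    best <- min(scores)
    keep <- all_t[scores == best]
    keys <- vapply(keep, edges_split_key, "", taxa = enc$taxa)
    return(list(edges = keep[!duplicated(keys)], score = best,
                method = "exhaustive"))
  }
  ## heuristic: jumbled stepwise addition + NNI
  if (!is.null(seed)) set.seed(seed)
  best_score <- Inf; best_edges <- list(); best_keys <- character()
  for (jm in seq_len(n_jumbles)) {
    ord <- sample.int(n)
    e <- cbind(n + 1L, ord[1:3])
    nxt <- n + 2L
    for (k in 4:n) {
      cands <- lapply(seq_len(nrow(e)), function(r)
        insert_leaf(e, r, ord[k], nxt))
      sc <- vapply(cands, score_edges, 0, enc = enc)
      e <- cands[[which.min(sc)]]
      nxt <- nxt + 1L
    }
    cur <- score_edges(e, enc)
    repeat {
      improved <- FALSE
      internal_rows <- which(e[, 2L] > n)
      for (r in internal_rows) {
        for (e2 in nni_neighbors(e, r)) {
          s2 <- score_edges(e2, enc)
          if (s2 < cur) { e <- e2; cur <- s2; improved <- TRUE; break }
        }
        if (improved) break
      }
      if (!improved) break
    }
    if (cur < best_score) {
      best_score <- cur
      best_edges <- list(e)
      best_keys <- edges_split_key(e, enc$taxa)
    } else if (cur == best_score) {
      key <- edges_split_key(e, enc$taxa)
      if (!key %in% best_keys) {
        best_edges <- c(best_edges, list(e))
        best_keys <- c(best_keys, key)
      }
    }
  }
  list(edges = best_edges, score = best_score, method = "heuristic")
}

## --- consensus -----------------------------------------------------------

consensus_split_counts <- function(trees) {
  labs <- sort(trees[[1L]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), labs))
      stop("consensus error: trees have differing leaf sets; restrict first")
  counts <- list()
  for (tr in trees) {
    keys <- vapply(splits_from_tree(tr)$splits, split_key, "")
    for (k in unique(keys))
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  }
  list(labs = labs, counts = counts)
}

## build a tree (phylo) from a laminar set of clusters rooted at labs[1]
tree_from_clusters <- function(labs, clusters, labels = NULL) {
  nest <- function(set, cls) {
    inside <- cls[vapply(cls, function(x) all(x$cl %in% set) &&
                           length(x$cl) < length(set), TRUE)]
    parts <- character()
    used <- character()
    ## maximal clusters within `set`
    ord <- order(-lengths(lapply(inside, `[[`, "cl")))
    picked <- list()
    for (i in ord) {
      cl <- inside[[i]]$cl
      if (!length(intersect(cl, used))) { picked <- c(picked, inside[i]); used <- c(used, cl) }
    }
    for (p in picked) {
      sub <- nest(p$cl, inside[vapply(inside, function(x)
        all(x$cl %in% p$cl) && length(x$cl) < length(p$cl), TRUE)])
      parts <- c(parts, paste0(sub, if (is.null(p$lab)) "" else p$lab))
    }
    parts <- c(parts, setdiff(set, used))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  cls <- lapply(seq_along(clusters), function(i)
    list(cl = clusters[[i]],
         lab = if (is.null(labels)) NULL else labels[i]))
  txt <- paste0(nest(labs, cls), ";")
  ape::read.tree(text = txt)
}

splits_to_clusters <- function(keys, ref) {
  lapply(keys, function(k) {
    sides <- strsplit(k, "|", fixed = TRUE)[[1]]
    a <- strsplit(sides[1], ",", fixed = TRUE)[[1]]
    b <- strsplit(sides[2], ",", fixed = TRUE)[[1]]
    if (ref %in% a) b else a
  })
}

#' Strict consensus tree
#'
#' Retains exactly the splits present in every input tree. All trees must
#' share one leaf set.
#'
#' @param trees list of `phylo`.
#' @return a `phylo`.
#' @export
strict_consensus <- function(trees) {
  cc <- consensus_split_counts(trees)
  keys <- names(cc$counts)[unlist(cc$counts) == length(trees)]
  tree_from_clusters(cc$labs, splits_to_clusters(keys, cc$labs[1L]))
}

#' Majority-rule consensus tree
#'
#' Retains the splits occurring in more than `threshold_pct` percent of the
#' input trees, annotated with their occurrence percentage.
#'
#' @param trees list of `phylo` on one leaf set.
#' @param threshold_pct retention threshold (default 50; strict greater).
#' @return object of class `consensus_tree`: list with `tree` (`phylo`,
#'   node labels = support percentages) and `supports` (data.frame
#'   `split`, `pct`).
#' @export
majority_consensus <- function(trees, threshold_pct = 50) {
  cc <- consensus_split_counts(trees)
  pct <- 100 * unlist(cc$counts) / length(trees)
  keep <- pct > threshold_pct
  keys <- names(cc$counts)[keep]
  pcts <- round(pct[keep], 1L)
  tr <- tree_from_clusters(cc$labs, splits_to_clusters(keys, cc$labs[1L]),
                           labels = sprintf("%.1f", pcts))
  structure(list(tree = tr,
                 supports = data.frame(split = keys, pct = unname(pcts),
                                       stringsAsFactors = FALSE)),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("consensus_tree with supports (%):\n")
  print(x$supports)
  invisible(x)
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement to the original length,
#' repeats the parsimony search per replicate (one best tree per replicate,
#' the first in canonical order), and reports the majority-rule consensus of
#' the replicate trees with replicate percentages as supports. Fully
#' deterministic under a fixed seed.
#'
#' @param aln a [seq_alignment()].
#' @param replicates number of pseudo-replicates.
#' @param seed RNG seed.
#' @param n_jumbles jumbles per replicate (heuristic regime only).
#' @param exhaustive_limit see [mp_search()].
#' @param threshold_pct consensus threshold.
#' @param gap_as_state passed to the scorer.
#' @return a `consensus_tree` (see [majority_consensus()]).
#' @export
bootstrap_support <- function(aln, replicates = 100L, seed = 1L,
                              n_jumbles = 5L, exhaustive_limit = 9L,
                              threshold_pct = 50, gap_as_state = FALSE) {
  stopifnot(replicates >= 1L)
  enc <- encode_patterns(aln, gap_as_state)
  n <- length(enc$taxa)
  L <- sum(enc$weights)
  set.seed(seed)
  rep_trees <- vector("list", replicates)
  if (n <= exhaustive_limit && n >= 4L) {
    ## scores are linear in column weights: score every topology's
    ## per-pattern costs once, then each replicate is a reweighting
    all_t <- all_topologies(seq_len(n), n + 1L)
    costM <- do.call(rbind, lapply(all_t, function(e)
      fitch_patterns(e, enc$masks, n)))
    keys <- vapply(all_t, edges_split_key, "", taxa = enc$taxa)
    ord <- order(keys)
    for (b in seq_len(replicates)) {
      w <- tabulate(sample.int(ncol(enc$masks), L, replace = TRUE,
                               prob = enc$weights), ncol(enc$masks))
      sc <- as.vector(costM %*% w)
      best <- which(sc == min(sc))
      pick <- best[order(match(best, ord))][1L]
      rep_trees[[b]] <- edges_to_phylo(all_t[[pick]], enc$taxa)
    }
  } else {
    for (b in seq_len(replicates)) {
      idx <- sample.int(ncol(enc$masks), L, replace = TRUE,
                        prob = enc$weights)
      enc_b <- list(masks = enc$masks, weights = tabulate(idx, ncol(enc$masks)),
                    taxa = enc$taxa)
      res <- mp_search_core(enc_b, n_jumbles,
                            seed = sample.int(.Machine$integer.max, 1L),
                            exhaustive_limit = exhaustive_limit)
      keys <- vapply(res$edges, edges_split_key, "", taxa = enc$taxa)
      rep_trees[[b]] <- edges_to_phylo(res$edges[[order(keys)[1L]]], enc$taxa)
    }
  }
  majority_consensus(rep_trees, threshold_pct)
}

#' Concatenated-versus-per-locus incongruence ratio
#'
#' The parsimony score of the concatenated matrix divided by the sum of the
#' per-locus MP scores. Under congruent gene histories the two agree
#' (ratio 1); conflicting histories force extra changes on any single tree,
#' inflating the ratio above 1.
#'
#' @param concat_score integer MP score of the concatenated matrix.
#' @param locus_scores integer vector of per-locus MP scores.
#' @return the ratio (numeric).
#' @export
incongruence_ratio <- function(concat_score, locus_scores) {
  s <- sum(locus_scores)
  if (s == 0) stop("undefined-ratio error: per-locus scores sum to zero")
  if (concat_score < s)
    stop("concatenated score below per-locus sum: scores inconsistent")
  concat_score / s
}
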