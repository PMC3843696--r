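## Median-joining haplotype networks: collapse an alignment to distinct
## allele sequences, link them by minimum-spanning-network edges under
## Hamming distance, and add inferred median (Steiner) haplotypes that
## shorten the network, as in the classic median-joining algorithm.

#' Collapse an alignment into haplotypes
#'
#' Identical rows are merged; each haplotype records its multiplicity and,
#' when the alignment carries group metadata, the count of member taxa per
#' group.
#'
#' @param aln a [seq_alignment()].
#' @return object of class `haplotype_set`: list with `states` (haplotype x
#'   position character matrix), `multiplicity`, `members` (list of taxon
#'   labels), `group_counts` (list of named counts or `NULL`).
#' @export
collapse_haplotypes <- function(aln) {
  m <- unclass(aln)
  keys <- apply(m, 1L, paste, collapse = "")
  first <- !duplicated(keys)
  ids <- paste0("H", match(keys, keys[first]))
  uh <- keys[first]
  states <- m[first, , drop = FALSE]
  rownames(states) <- paste0("H", seq_along(uh))
  members <- split(rownames(m), factor(ids, levels = rownames(states)))
  groups <- attr(aln, "groups")
  gc <- NULL
  if (!is.null(groups))
    gc <- lapply(members, function(tx)
      table(factor(groups[tx], levels = sort(unique(groups)))))
  structure(list(states = states,
                 multiplicity = lengths(members),
                 members = members,
                 group_counts = gc),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes from %d sequences, %d positions\n",
              nrow(x$states), sum(x$multiplicity), ncol(x$states)))
  invisible(x)
}

hamming <- function(states) {
  n <- nrow(states)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j > i) d[i, j] <- d[j, i] <- sum(states[i, ] != states[j, ])
  d
}

## connection level delta(u,v): smallest distance class w such that u and v
## are connected using only edges of weight <= w (minimax path weight)
connection_levels <- function(d) {
  n <- nrow(d)
  delta <- matrix(Inf, n, n)
  comp <- seq_len(n)
  for (w in sort(unique(d[upper.tri(d)]))) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (d[i, j] <= w && comp[i] != comp[j]) comp[comp == comp[j]] <- comp[i]
    newly <- is.infinite(delta) & outer(comp, comp, "==")
    delta[newly] <- w
    if (all(comp == comp[1L])) break
  }
  diag(delta) <- 0
  delta
}

## total weight of a minimum spanning tree of distance matrix d (Prim)
mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1L))
  mind <- d[1L, ]
  cost <- 0
  for (k in seq_len(n - 1L)) {
    i <- which(!intree)[which.min(mind[!intree])]
    cost <- cost + mind[i]
    intree[i] <- TRUE
    mind <- pmin(mind, d[i, ])
  }
  cost
}

#' Minimum spanning network of haplotypes
#'
#' Contains every edge lying on some minimum spanning tree under Hamming
#' distance; `epsilon` relaxes the connection criterion, keeping in addition
#' edges whose length exceeds the pair's connection level by at most
#' `epsilon` mutations.
#'
#' @param haps a [collapse_haplotypes()] result, or a character state matrix.
#' @param epsilon nonnegative integer relaxation (default 0).
#' @return object of class `haplotype_network`: list with `states`,
#'   `observed` (logical per node), `multiplicity`, `edges` (data.frame
#'   `from`, `to`, `length`), `group_counts`.
#' @export
minimum_spanning_network <- function(haps, epsilon = 0L) {
  hs <- as_hapset(haps)
  states <- hs$states
  if (nrow(states) < 2L) stop("need >= 2 haplotypes")
  d <- hamming(states)
  net <- msn_edges(d, epsilon)
  structure(list(states = states,
                 observed = hs$observed,
                 multiplicity = hs$multiplicity,
                 edges = net,
                 group_counts = hs$group_counts),
            class = "haplotype_network")
}

msn_edges <- function(d, epsilon = 0L) {
  delta <- connection_levels(d)
  n <- nrow(d)
  from <- integer(); to <- integer(); len <- integer()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (d[i, j] <= delta[i, j] + epsilon) {
      from <- c(from, i); to <- c(to, j); len <- c(len, d[i, j])
    }
  data.frame(from = from, to = to, length = len)
}

as_hapset <- function(haps) {
  if (inherits(haps, "haplotype_set"))
    return(list(states = haps$states,
                observed = rep(TRUE, nrow(haps$states)),
                multiplicity = haps$multiplicity,
                group_counts = haps$group_counts))
  if (is.matrix(haps)) {
    if (is.null(rownames(haps))) rownames(haps) <- paste0("H", seq_len(nrow(haps)))
    return(list(states = haps, observed = rep(TRUE, nrow(haps)),
                multiplicity = rep(1L, nrow(haps)), group_counts = NULL))
  }
  stop("haps must be a haplotype_set or a state matrix")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d nodes (%d observed, %d median), %d edges, cost %d\n",
              nrow(x$states), sum(x$observed), sum(!x$observed),
              nrow(x$edges), network_cost(x)))
  invisible(x)
}

#' Total Steiner cost of a haplotype network
#'
#' Weight of a minimum spanning tree over the network's node set (observed
#' plus inferred medians) under Hamming distance.
#' @param net a `haplotype_network`.
#' @return integer cost.
#' @export
network_cost <- function(net) as.integer(mst_cost(hamming(net$states)))

#' @export
plot.haplotype_network <- function(x, ...) {
  n <- nrow(x$states)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  xy <- cbind(cos(ang), sin(ang))
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "", asp = 1, ...)
  for (k in seq_len(nrow(x$edges)))
    graphics::segments(xy[x$edges$from[k], 1], xy[x$edges$from[k], 2],
                       xy[x$edges$to[k], 1], xy[x$edges$to[k], 2], col = "grey50")
  graphics::points(xy, cex = ifelse(x$observed, 1 + sqrt(x$multiplicity), 0.8),
                   pch = 21, bg = ifelse(x$observed, "steelblue", "white"))
  graphics::text(xy, labels = rownames(x$states), pos = 3, cex = 0.7)
  invisible(x)
}

#' Median-joining network
#'
#' Iterates: build the minimum spanning network over the current node set;
#' for every triple of nodes of which at least two pairs are network
#' neighbours, compute the per-position majority median vector; add the
#' median that most reduces the network's spanning cost; prune inferred
#' medians that no longer shorten the network. Observed haplotypes are never
#' removed. Ties among equally good medians are broken by lexicographic
#' state vector; majority ties within a position resolve to the state of the
#' first-listed node of the triple, making runs reproducible.
#'
#' @param haps a [collapse_haplotypes()] result or character state matrix.
#' @param epsilon minimum-spanning-network relaxation passed through.
#' @param max_iter iteration cap; exceeding it is an error (diagnostic of
#'   non-termination).
#' @return a `haplotype_network` (see [minimum_spanning_network()]).
#' @export
median_joining <- function(haps, epsilon = 0L, max_iter = 100L) {
  hs <- as_hapset(haps)
  states <- hs$states
  observed <- hs$observed
  if (nrow(states) < 2L) stop("need >= 2 haplotypes")
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("median_joining failed to converge after ", max_iter,
           " iterations (", nrow(states), " nodes)")
    d <- hamming(states)
    cost <- mst_cost(d)
    edges <- msn_edges(d, epsilon)
    adj <- matrix(FALSE, nrow(states), nrow(states))
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj <- adj | t(adj)
    cand <- candidate_medians(states, adj)
    best <- NULL; best_delta <- 0; best_vec <- NULL
    for (key in names(cand)) {
      v <- cand[[key]]
      d2 <- rbind(cbind(d, apply(states, 1L, function(r) sum(r != v))),
                  c(apply(states, 1L, function(r) sum(r != v)), 0L))
      delta <- mst_cost(d2) - cost
      if (delta < best_delta ||
          (delta == best_delta && !is.null(best) && key < best)) {
        best <- key; best_delta <- delta; best_vec <- v
      }
    }
    if (!is.null(best)) {
      states <- rbind(states, best_vec)
      rownames(states)[nrow(states)] <- paste0("mv", iter)
      observed <- c(observed, FALSE)
      next
    }
    ## prune: drop inferred medians whose removal does not lengthen the net
    pruned <- FALSE
    for (i in rev(which(!observed))) {
      if (mst_cost(hamming(states[-i, , drop = FALSE])) <= cost) {
        states <- states[-i, , drop = FALSE]
        observed <- observed[-i]
        pruned <- TRUE
        break
      }
    }
    if (!pruned) break
  }
  mult <- integer(nrow(states))
  mult[observed] <- hs$multiplicity
  gc <- hs$group_counts
  structure(list(states = states, observed = observed, multiplicity = mult,
                 edges = msn_edges(hamming(states), epsilon),
                 group_counts = gc),
            class = "haplotype_network")
}

## median vectors of all triples with >= 2 adjacent pairs, keyed by vector
candidate_medians <- function(states, adj) {
  n <- nrow(states)
  out <- list()
  existing <- apply(states, 1L, paste, collapse = "")
  if (n < 3L) return(out)
  for (u in seq_len(n - 2L)) for (v in (u + 1L):(n - 1L)) for (w in (v + 1L):n) {
    if (adj[u, v] + adj[u, w] + adj[v, w] < 2L) next
    tri <- states[c(u, v, w), , drop = FALSE]
    med <- apply(tri, 2L, function(col) {
      tab <- table(col)
      if (max(tab) >= 2L) names(tab)[which.max(tab)] else col[1L]
    })
    key <- paste(med, collapse = "")
    if (key %in% existing) next
    out[[key]] <- med
  }
  out
}
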