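## Independent oracles used by the property tests. Each is a brute-force
## or closed-form computation sharing no code with the package internals
## it checks.

## --- minimum Steiner-tree cost in Hamming space (Dreyfus-Wagner) ---------

## terminals: k x p character matrix; the optimum is searched over the
## product space of the states observed per position
steiner_cost_oracle <- function(terminals) {
  k <- nrow(terminals)
  state_sets <- lapply(seq_len(ncol(terminals)), function(j)
    unique(terminals[, j]))
  grid <- expand.grid(state_sets, stringsAsFactors = FALSE)
  V <- nrow(grid)
  gm <- as.matrix(grid)
  d <- matrix(0L, V, V)
  for (i in seq_len(V)) for (j in seq_len(V))
    d[i, j] <- sum(gm[i, ] != gm[j, ])
  term_idx <- vapply(seq_len(k), function(i) {
    which(apply(gm, 1L, function(r) all(r == terminals[i, ])))[1L]
  }, 1L)
  full <- bitwShiftL(1L, k) - 1L
  dp <- matrix(Inf, full, V)
  for (i in seq_len(k)) dp[bitwShiftL(1L, i - 1L), ] <- d[term_idx[i], ]
  for (S in seq_len(full)) {
    if (sum(bitwAnd(S, bitwShiftL(1L, seq_len(k) - 1L)) > 0L) < 2L) next
    ## merge two sub-terminal-sets at each vertex
    sub <- S - 1L
    while (sub > 0L) {
      if (bitwAnd(sub, S) == sub) {
        oth <- S - sub
        if (sub < oth)
          dp[S, ] <- pmin(dp[S, ], dp[sub, ] + dp[oth, ])
      }
      sub <- sub - 1L
    }
    ## propagate along the graph (uniform weights: |V| relax rounds max,
    ## min-plus with the exact metric d does it in one)
    dp[S, ] <- apply(dp[S, ] + d, 2L, min)
  }
  min(dp[full, ])
}

## --- brute-force small parsimony ----------------------------------------

## minimum changes of one column over a tree by enumerating all internal
## state assignments
fitch_brute_column <- function(phy, states) {
  n <- length(phy$tip.label)
  m <- phy$Nnode
  alphabet <- c("A", "C", "G", "T")
  leaf_sets <- lapply(states, function(s)
    if (s %in% alphabet) s else alphabet)
  combos <- as.matrix(expand.grid(rep(list(alphabet), m),
                                  stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    assign_ <- combos[r, ]
    cost_tree <- 0L
    ok <- TRUE
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      ps <- assign_[p - n]
      if (ch <= n) {
        if (!(ps %in% leaf_sets[[ch]])) cost_tree <- cost_tree + 1L
      } else if (ps != assign_[ch - n]) cost_tree <- cost_tree + 1L
    }
    if (ok && cost_tree < best) best <- cost_tree
  }
  best
}

fitch_brute <- function(phy, aln) {
  m <- unclass(aln)
  sum(vapply(seq_len(ncol(m)), function(j)
    fitch_brute_column(phy, m[phy$tip.label, j]), 1L))
}

## --- four-gamete test on two binary columns ------------------------------

four_gamete_incompatible <- function(col1, col2) {
  ok <- col1 %in% c("A", "C", "G", "T", "-") & col2 %in% c("A", "C", "G", "T", "-")
  g <- unique(paste(col1[ok], col2[ok]))
  length(g) == 4L
}

## --- exhaustive acyclic-agreement-forest search --------------------------

## all set partitions of a vector (restricted-growth enumeration)
all_set_partitions <- function(x) {
  n <- length(x)
  out <- list()
  rec <- function(i, assign_, nblk) {
    if (i > n) {
      out[[length(out) + 1L]] <<- unname(split(x, assign_[seq_len(n)]))
      return(invisible())
    }
    for (b in seq_len(nblk + 1L)) {
      assign_[i] <- b
      rec(i + 1L, assign_, max(nblk, b))
    }
  }
  rec(1L, integer(n), 0L)
  out
}

## attach a root leaf via newick text (independent of package internals)
with_rho <- function(phy, rho = ".rho") {
  txt <- ape::write.tree(phy)
  ape::read.tree(text = paste0("(", sub(";$", "", txt), ",", rho, ");"))
}

## sorted nontrivial cluster keys of phy restricted to X, via ape
restricted_cluster_keys <- function(phy, X) {
  if (length(X) < 3L) return(character())
  sub <- ape::keep.tip(phy, X)
  pp <- ape::prop.part(sub)
  keys <- vapply(pp, function(idx)
    paste(sort(attr(pp, "labels")[idx]), collapse = ","), "")
  keys <- keys[vapply(pp, length, 1L) < length(X)]
  sort(unique(keys[keys != ""]))
}

## Steiner span (node ids) of leaf set X in phy, via ape::nodepath
span_nodes <- function(phy, X) {
  ids <- match(X, phy$tip.label)
  if (length(ids) == 1L) return(ids)
  nodes <- integer()
  for (i in seq_along(ids)[-1L])
    nodes <- union(nodes, ape::nodepath(phy, ids[1L], ids[i]))
  ## nodepath covers pairwise paths through the first leaf's route; add the
  ## remaining pairwise paths for completeness
  for (i in seq_along(ids)) for (j in seq_along(ids))
    if (j > i) nodes <- union(nodes, ape::nodepath(phy, ids[i], ids[j]))
  nodes
}

is_aaf_oracle <- function(t1r, t2r, parts) {
  for (X in parts) {
    if (!identical(restricted_cluster_keys(t1r, X),
                   restricted_cluster_keys(t2r, X))) return(FALSE)
  }
  for (phy in list(t1r, t2r)) {
    spans <- lapply(parts, span_nodes, phy = phy)
    if (anyDuplicated(unlist(spans))) return(FALSE)
  }
  k <- length(parts)
  if (k > 1L) {
    adj <- matrix(FALSE, k, k)
    for (phy in list(t1r, t2r)) {
      n <- length(phy$tip.label)
      root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
      roots <- vapply(parts, function(X) {
        ids <- match(X, phy$tip.label)
        if (length(ids) == 1L) ids else ape::getMRCA(phy, ids)
      }, 1L)
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i == j) next
        path <- ape::nodepath(phy, root, roots[j])
        if (roots[i] %in% path && roots[i] != roots[j]) adj[i, j] <- TRUE
      }
    }
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

## exhaustive minimum-hybridization oracle over all leaf partitions
min_hyb_oracle <- function(t1, t2) {
  common <- intersect(t1$tip.label, t2$tip.label)
  t1r <- with_rho(ape::keep.tip(t1, common))
  t2r <- with_rho(ape::keep.tip(t2, common))
  leaves <- c(common, ".rho")
  best <- Inf
  for (parts in all_set_partitions(leaves)) {
    if (length(parts) - 1L >= best) next
    if (is_aaf_oracle(t1r, t2r, parts)) best <- min(best, length(parts) - 1L)
  }
  as.integer(best)
}

## random rooted binary tree over given labels
rand_rooted <- function(labels) {
  tr <- ape::rtree(length(labels), rooted = TRUE, br = NULL)
  tr$tip.label <- sample(labels)
  tr
}
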