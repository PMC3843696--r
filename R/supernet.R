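## Filtered supernetworks from partial trees or raw splits: Z-closure
## extension of partial splits to the full taxon set, support counting
## against the inputs, minSupportingTrees-style filtering, and construction
## of the abstract splits graph in which retained incompatibilities appear
## as boxes (reticulations).

#' Filtering parameters for supernetworks
#'
#' @param min_supporting threshold m: a nontrivial split is retained when
#'   supported by more than m inputs (or at least m with
#'   `strict_greater = FALSE`).
#' @param strict_greater logical, default `TRUE` (the "> m" reading).
#' @return a `filter_params` object.
#' @export
filter_params <- function(min_supporting = 0L, strict_greater = TRUE) {
  stopifnot(min_supporting >= 0L)
  structure(list(min_supporting = as.integer(min_supporting),
                 strict_greater = isTRUE(strict_greater)),
            class = "filter_params")
}

## pull a plain list of taxon_split objects out of trees/systems/splits
input_splits <- function(x) {
  if (inherits(x, "phylo")) return(splits_from_tree(x)$splits)
  if (inherits(x, "split_system")) return(x$splits)
  if (inherits(x, "taxon_split")) return(list(x))
  if (is.list(x)) return(unlist(lapply(x, input_splits), recursive = FALSE))
  stop("unsupported input type")
}

input_taxa <- function(x) {
  if (inherits(x, "phylo")) return(x$tip.label)
  if (inherits(x, "split_system")) return(x$taxa)
  if (inherits(x, "taxon_split")) return(split_domain(x))
  stop("unsupported input type")
}

## one application of the Z extension rule to partial splits s1 = A1|B1,
## s2 = A2|B2 (trying all side orientations): when A1 and A2 overlap, B1
## and B2 overlap, and A2 avoids B1, the pair is replaced by
## (A1 u A2)|B1 and A2|(B1 u B2). Returns NULL when no orientation fires
## or when firing would change nothing.
zrule <- function(s1, s2) {
  for (o1 in 1:2) for (o2 in 1:2) {
    A1 <- if (o1 == 1L) s1$a else s1$b; B1 <- if (o1 == 1L) s1$b else s1$a
    A2 <- if (o2 == 1L) s2$a else s2$b; B2 <- if (o2 == 1L) s2$b else s2$a
    if (length(intersect(A1, A2)) && length(intersect(B1, B2)) &&
        !length(intersect(A2, B1))) {
      n1 <- taxon_split(union(A1, A2), B1)
      n2 <- taxon_split(A2, union(B1, B2))
      if (split_key(n1) == split_key(s1) && split_key(n2) == split_key(s2))
        next
      return(list(n1, n2))
    }
  }
  NULL
}

#' Z-closure supernetwork splits
#'
#' Extends a collection of partial splits toward the full taxon set by
#' repeatedly applying the pairwise Z extension rule in randomized sweep
#' order until a fixed point, then completes any still-partial split by
#' assigning the absent taxa to its canonical second side (or discarding
#' the split, per `complete`). The union of distinct full splits over
#' `runs` randomized orderings is returned, plus all trivial splits.
#'
#' @param inputs list of `phylo` trees, [split_system()]s and/or
#'   [taxon_split()]s; the union of their taxa is the full set.
#' @param runs number of randomized sweep orderings (default 5).
#' @param seed RNG seed.
#' @param complete `"side_b"` (default) or `"discard"` for splits still
#'   partial at the fixed point.
#' @return a [split_system()] over the full taxon set.
#' @export
zclosure <- function(inputs, runs = 5L, seed = 1L,
                     complete = c("side_b", "discard")) {
  complete <- match.arg(complete)
  pool0 <- input_splits(inputs)
  taxa <- sort(unique(unlist(lapply(pool0, split_domain))))
  if (!length(pool0)) return(split_system(character()))
  ## singleton-side partial splits are kept: their extensions need not be
  ## trivial (a full split is trivial only if a side stays a singleton)
  set.seed(seed)
  full <- list()
  for (run in seq_len(max(1L, runs))) {
    pool <- pool0
    keys <- vapply(pool, split_key, "")
    repeat {
      fired <- FALSE
      idx <- sample(seq_along(pool))
      for (i in idx) for (j in idx) {
        if (i == j) next
        upd <- zrule(pool[[i]], pool[[j]])
        if (!is.null(upd)) {
          pool[[i]] <- upd[[1L]]; pool[[j]] <- upd[[2L]]
          fired <- TRUE
        }
      }
      keys2 <- vapply(pool, split_key, "")
      if (!fired || identical(sort(keys2), sort(keys))) break
      keys <- keys2
    }
    for (s in pool) {
      absent <- setdiff(taxa, split_domain(s))
      if (length(absent)) {
        if (complete == "discard") next
        s <- taxon_split(s$a, c(s$b, absent))
      }
      full[[split_key(s)]] <- s
    }
  }
  for (x in taxa) {
    s <- taxon_split(x, setdiff(taxa, x))
    full[[split_key(s)]] <- s
  }
  split_system(taxa, unname(full))
}

#' Count the inputs supporting a split
#'
#' An input supports a full split when the split restricted to the input's
#' taxa is empty (the input is silent: vacuous support, counted by default),
#' trivial, or identical to one of the input's own splits. A nontrivial
#' restriction the input does not display contributes nothing, whether
#' incompatible (a contradiction) or merely absent.
#'
#' @param s a full [taxon_split()].
#' @param inputs list of `phylo` trees, [split_system()]s and/or single
#'   [taxon_split()]s (a raw input split is a one-split input).
#' @param count_vacuous count inputs whose taxa miss the split entirely.
#' @return integer support count.
#' @export
support_count <- function(s, inputs, count_vacuous = TRUE) {
  if (inherits(inputs, c("phylo", "split_system", "taxon_split")))
    inputs <- list(inputs)
  n <- 0L
  for (T_ in inputs) {
    r <- restrict_split(s, input_taxa(T_))
    if (is.null(r) || is_trivial_split(r)) {
      if (count_vacuous) n <- n + 1L
      next
    }
    rk <- split_key(r)
    keys <- vapply(input_splits(T_), split_key, "")
    if (rk %in% keys) n <- n + 1L
  }
  n
}

#' Filter a split system by input support
#'
#' Retains the nontrivial splits whose [support_count()] exceeds (or, with
#' `strict_greater = FALSE`, reaches) `min_supporting`; trivial splits are
#' always retained. The computed counts are stored on each retained split
#' as attribute `support_count`.
#'
#' @param system a [split_system()].
#' @param inputs the supporting inputs (see [support_count()]).
#' @param params a [filter_params()].
#' @param count_vacuous passed to [support_count()].
#' @return the filtered [split_system()].
#' @export
filter_splits <- function(system, inputs, params = filter_params(),
                          count_vacuous = TRUE) {
  keep <- list()
  for (s in system$splits) {
    if (is_trivial_split(s)) { keep[[split_key(s)]] <- s; next }
    n <- support_count(s, inputs, count_vacuous)
    ok <- if (params$strict_greater) n > params$min_supporting
          else n >= params$min_supporting
    if (ok) {
      attr(s, "support_count") <- n
      keep[[split_key(s)]] <- s
    }
  }
  split_system(system$taxa, unname(keep))
}

#' Abstract splits graph (Buneman construction)
#'
#' Builds the canonical splits graph of a full split system: vertices are
#' the coherent side assignments (one side per split, all chosen sides
#' pairwise intersecting), edges join assignments differing in exactly one
#' split and carry that split's id. Pairwise-compatible systems yield their
#' tree; k mutually incompatible splits yield a 2^k hypercube face (boxes =
#' reticulations). Deleting all edges of one split disconnects the graph
#' into the split's two sides.
#'
#' @param system a full [split_system()].
#' @param node_cap abort with an error when the vertex count would exceed
#'   this (advice: filter more strongly).
#' @return object of class `splits_graph`: list with `sides` (vertex x
#'   split matrix of 1/2), `edges` (data.frame `from`, `to`, `split`),
#'   `taxon_node` (named vertex index per taxon), `splits`, `taxa`.
#' @export
build_splits_graph <- function(system, node_cap = 10000L) {
  splits <- system$splits
  k <- length(splits)
  taxa <- system$taxa
  if (!k) stop("empty split system")
  ## DFS over side choices; sides[i] in {1 (side a), 2 (side b)}
  verts <- list()
  rec <- function(choice, sets) {
    i <- length(choice) + 1L
    if (i > k) {
      verts[[length(verts) + 1L]] <<- choice
      if (length(verts) > node_cap)
        stop("splits graph exceeds node_cap (", node_cap,
             "); apply stronger filtering")
      return(invisible())
    }
    for (side in 1:2) {
      sd <- if (side == 1L) splits[[i]]$a else splits[[i]]$b
      ok <- all(vapply(sets, function(x) length(intersect(x, sd)) > 0L, TRUE))
      if (ok) rec(c(choice, side), c(sets, list(sd)))
    }
  }
  rec(integer(), list())
  V <- do.call(rbind, verts)
  nv <- nrow(V)
  from <- integer(); to <- integer(); esp <- integer()
  for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
    dif <- which(V[i, ] != V[j, ])
    if (length(dif) == 1L) {
      from <- c(from, i); to <- c(to, j); esp <- c(esp, dif)
    }
  }
  tn <- vapply(taxa, function(x) {
    sig <- vapply(splits, function(s) if (x %in% s$a) 1L else
      if (x %in% s$b) 2L else NA_integer_, 1L)
    hit <- which(apply(V, 1L, function(v) all(v == sig, na.rm = TRUE)))
    hit[1L]
  }, 1L)
  structure(list(sides = V,
                 edges = data.frame(from = from, to = to, split = esp),
                 taxon_node = tn, splits = splits, taxa = taxa),
            class = "splits_graph")
}

#' @export
print.splits_graph <- function(x, ...) {
  cat(sprintf("splits_graph: %d vertices, %d edges, %d splits, %d taxa\n",
              nrow(x$sides), nrow(x$edges), length(x$splits), length(x$taxa)))
  invisible(x)
}

#' Incompatible split pairs of a system
#'
#' The boxes of the splits graph correspond to pairs of retained mutually
#' incompatible splits; this helper lists them.
#'
#' @param system a [split_system()].
#' @return data.frame with indices `i`, `j` of incompatible pairs.
#' @export
incompatible_pairs <- function(system) {
  sp <- system$splits
  out <- NULL
  if (length(sp) >= 2L)
    for (i in seq_len(length(sp) - 1L)) for (j in (i + 1L):length(sp))
      if (!are_compatible(sp[[i]], sp[[j]]))
        out <- rbind(out, data.frame(i = i, j = j))
  if (is.null(out)) data.frame(i = integer(), j = integer()) else out
}
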