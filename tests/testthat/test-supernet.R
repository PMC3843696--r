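test_that("the Z extension rule fires as specified on partial splits", {
  ## {a,b}|{c} with {b}|{c,d} must yield the full split {a,b}|{c,d}
  z <- zclosure(list(taxon_split(c("a", "b"), "c"),
                     taxon_split("b", c("c", "d"))), runs = 3, seed = 1)
  keys <- vapply(z$splits, split_key, "")
  expect_true("a,b|c,d" %in% keys)

  ## full inputs pass through unchanged
  full <- list(taxon_split(c("a", "b"), c("c", "d")))
  z2 <- zclosure(full, runs = 2, seed = 1)
  nontriv <- Filter(Negate(is_trivial_split), z2$splits)
  expect_equal(vapply(nontriv, split_key, ""), "a,b|c,d")

  ## disjoint-taxa inputs cannot interact; completion fills side b
  z3 <- zclosure(list(taxon_split(c("a", "b"), c("c", "d")),
                      taxon_split(c("e", "f"), c("g", "h"))),
                 runs = 2, seed = 1)
  k3 <- vapply(Filter(Negate(is_trivial_split), z3$splits), split_key, "")
  expect_true("a,b|c,d,e,f,g,h" %in% k3)
  expect_true(any(grepl("e,f", k3)))
})

test_that("no signal is lost on mutually compatible partial trees", {
  set.seed(12)
  big <- ape::rtree(8)
  subs <- lapply(1:4, function(i)
    ape::keep.tip(big, sort(sample(big$tip.label, 6))))
  z <- zclosure(subs, runs = 5, seed = 3)
  for (tr in subs) {
    want <- vapply(splits_from_tree(tr)$splits, split_key, "")
    got <- vapply(z$splits, function(s) {
      r <- restrict_split(s, tr$tip.label)
      if (is.null(r)) NA_character_ else split_key(r)
    }, "")
    expect_true(all(want %in% got))
  }
})

test_that("support counting follows the contain / silent / contradict rules", {
  t1 <- read_trees("((a,b),(c,d));")[[1]]
  t2 <- read_trees("((a,b),(c,e));")[[1]]
  s <- taxon_split(c("a", "b"), c("c", "d", "e"))
  ## both trees display the restriction of s
  expect_equal(support_count(s, list(t1, t2)), 2L)

  ## vacuous support: split nontrivial only outside the input's taxa
  s_out <- taxon_split(c("x", "y"), c("z", "w"))
  expect_equal(support_count(s_out, list(t1)), 1L)
  expect_equal(support_count(s_out, list(t1), count_vacuous = FALSE), 0L)

  ## conflict with the input's only nontrivial split counts zero
  s_conf <- taxon_split(c("a", "c"), c("b", "d"))
  expect_equal(support_count(s_conf, list(t1)), 0L)
})

test_that("filtering is correct at the boundaries and antitone in m", {
  gen <- gen_hybrid_markers(seed = 4)
  inputs <- splits_from_markers(gen$markers)
  z <- zclosure(inputs, runs = 2, seed = 2)
  f0 <- filter_splits(z, inputs, filter_params(0, strict_greater = FALSE))
  expect_length(f0$splits, length(z$splits))   # m = 0, >= : identity

  counts <- vapply(Filter(Negate(is_trivial_split), z$splits),
                   support_count, 1L, inputs = inputs)
  f_all <- filter_splits(z, inputs,
                         filter_params(length(inputs), strict_greater = FALSE))
  nt_all <- Filter(Negate(is_trivial_split), f_all$splits)
  expect_equal(length(nt_all), sum(counts >= length(inputs)))

  ## antitone: larger m keeps a subset
  prev <- NULL
  for (m in c(0L, 2L, 4L, 6L)) {
    f <- filter_splits(z, inputs, filter_params(m))
    k <- sort(vapply(f$splits, split_key, ""))
    if (!is.null(prev)) expect_true(all(k %in% prev))
    prev <- k
  }
})

test_that("low-support noise splits are filtered out, planted signal kept", {
  ## consensus splits supported by many identical inputs, noise by one
  taxa <- letters[1:8]
  signal <- taxon_split(letters[1:4], letters[5:8])
  noise <- taxon_split(c("a", "e"), c("b", "f"))
  inputs <- c(rep(list(signal), 5), list(noise))
  z <- zclosure(inputs, runs = 3, seed = 9)
  f <- filter_splits(z, inputs, filter_params(4))
  nt <- Filter(Negate(is_trivial_split), f$splits)
  expect_equal(vapply(nt, split_key, ""), split_key(signal))
})

test_that("splits graphs realize trees, boxes and hypercubes", {
  ## pairwise compatible: the graph is the tree, one edge per split
  tr <- read_trees("((a,b),(c,d),e);")[[1]]
  sys <- splits_from_tree(tr, include_trivial = TRUE)
  g <- build_splits_graph(sys)
  expect_equal(nrow(g$edges), length(sys$splits))
  expect_equal(nrow(g$sides), length(sys$splits) + 1L)  # tree: V = E + 1

  ## two incompatible splits on four taxa: a box
  sys2 <- split_system(letters[1:4],
                       list(taxon_split(c("a", "b"), c("c", "d")),
                            taxon_split(c("a", "c"), c("b", "d"))))
  g2 <- build_splits_graph(sys2)
  expect_equal(nrow(g2$sides), 4L)
  expect_equal(nrow(g2$edges), 4L)

  ## k mutually incompatible splits: 2^k hypercube
  for (k in 2:4) {
    sp <- lapply(seq_len(k), function(i)
      taxon_split(c("a", letters[1 + i]), setdiff(letters[1:(k + 2)],
                                                  c("a", letters[1 + i]))))
    ## use crossing splits instead: {a,x_i} vs rest are pairwise incompatible
    sysk <- split_system(letters[1:(k + 2)], sp)
    ok <- all(vapply(seq_len(k - 1), function(i) all(vapply((i + 1):k,
      function(j) !are_compatible(sp[[i]], sp[[j]]), TRUE)), TRUE))
    expect_true(ok)
    gk <- build_splits_graph(sysk)
    expect_equal(nrow(gk$sides), 2L^k)
    expect_equal(nrow(gk$edges), k * 2L^(k - 1L))
  }
})

test_that("deleting one split's edge class bipartitions the graph by that split", {
  sys <- split_system(letters[1:5],
                      list(taxon_split(c("a", "b"), c("c", "d", "e")),
                           taxon_split(c("a", "c"), c("b", "d", "e")),
                           taxon_split(c("d", "e"), c("a", "b", "c"))))
  g <- build_splits_graph(sys)
  for (si in seq_along(g$splits)) {
    keep <- g$edges[g$edges$split != si, ]
    comp <- seq_len(nrow(g$sides))
    for (r in seq_len(nrow(keep))) {
      a <- comp[keep$from[r]]; b <- comp[keep$to[r]]
      comp[comp == b] <- a
    }
    expect_equal(length(unique(comp)), 2L)
    sidecomp <- split(g$taxa, comp[g$taxon_node])
    got <- sort(vapply(sidecomp, function(x) paste(sort(x), collapse = ","), ""))
    s <- g$splits[[si]]
    expect_setequal(unname(got), c(paste(s$a, collapse = ","),
                                   paste(s$b, collapse = ",")))
  }
})

test_that("a planted hybrid's two marker classes display as a box", {
  gen <- gen_hybrid_markers(seed = 42)
  inputs <- splits_from_markers(gen$markers)
  z <- zclosure(inputs, runs = 2, seed = 1)
  f <- filter_splits(z, inputs, filter_params(1, strict_greater = FALSE))
  keys <- vapply(f$splits, split_key, "")
  hs <- gen$truth$hybrid_splits[[1]]
  expect_true(all(hs %in% keys))
  ia <- f$splits[[match(hs["with_a"], keys)]]
  ib <- f$splits[[match(hs["with_b"], keys)]]
  expect_false(are_compatible(ia, ib))
  ## and the graph realizes both split classes as parallel edge pairs
  ## (each class of an incompatible pair traverses the box twice)
  g <- build_splits_graph(f)
  gkeys <- vapply(g$splits, split_key, "")
  for (k in hs) {
    si <- match(k, gkeys)
    expect_gte(sum(g$edges$split == si), 2L)
  }
})
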