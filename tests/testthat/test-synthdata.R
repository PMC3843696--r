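test_that("infinite-sites alignments carry only tree splits", {
  set.seed(14)
  tr <- ape::rtree(7)
  g <- gen_alignment_on_tree(tr, L = 25, seed = 6)
  tree_keys <- vapply(splits_from_tree(ape::unroot(tr))$splits, split_key, "")
  for (j in seq_len(ncol(g$alignment))) {
    sp <- tryCatch(split_from_column(g$alignment, j),
                   error = function(e) NULL)
    if (is.null(sp)) next
    for (s in sp) {
      if (is_trivial_split(s)) next
      expect_true(split_key(s) %in% tree_keys)
    }
  }
  expect_true(all(g$truth$splits %in% tree_keys))
})

test_that("a star tree yields only singleton-state columns", {
  star <- read_trees("(a,b,c,d,e);", rooted = TRUE)[[1]]
  g <- gen_alignment_on_tree(star, L = 15, seed = 2)
  for (j in seq_len(ncol(g$alignment))) {
    col <- unclass(g$alignment)[, j]
    minority <- min(table(col))
    expect_lte(minority, 1L)
  }
})

test_that("parsimony search recovers the generating topology on clean data", {
  set.seed(9)
  for (trial in 1:3) {
    tr <- ape::rtree(6)
    g <- gen_alignment_on_tree(tr, L = 30, seed = trial, distinct_sites = FALSE)
    mp <- mp_search(g$alignment)
    true_keys <- sort(vapply(splits_from_tree(ape::unroot(tr))$splits,
                             split_key, ""))
    found <- vapply(mp$trees, function(t)
      identical(sort(vapply(splits_from_tree(t)$splits, split_key, "")),
                true_keys), TRUE)
    expect_true(any(found))
  }
})

test_that("distinct-site generation errors when patterns run out", {
  tr <- ape::rtree(5)
  expect_error(gen_alignment_on_tree(tr, L = 50, seed = 1,
                                     distinct_sites = TRUE),
               "distinct patterns")
})

test_that("marker generation plants population blocks and mosaics", {
  clean <- gen_hybrid_markers(n_per_pop = c(3, 3), n_markers = 8,
                              hybrid_spec = list(), seed = 5)
  m <- unclass(clean$markers)
  ## without hybrids every marker is fixed within its population block
  for (j in seq_len(ncol(m))) {
    pops <- clean$truth$populations[rownames(m)]
    expect_true(all(tapply(m[, j], pops, function(x) length(unique(x))) == 1))
  }

  gh <- gen_hybrid_markers(seed = 8)
  mh <- unclass(gh$markers)
  hyb <- gh$truth$hybrids$hybrid[1]
  pa_m <- names(gh$truth$blocks)[gh$truth$blocks == gh$truth$hybrids$parent_a[1]]
  pb_m <- names(gh$truth$blocks)[gh$truth$blocks == gh$truth$hybrids$parent_b[1]]
  ## the hybrid carries markers from both parental blocks
  ja <- pa_m[mh[hyb, pa_m] == 1L][1]
  jb <- pb_m[mh[hyb, pb_m] == 1L][1]
  expect_false(is.na(ja)); expect_false(is.na(jb))
  ## and that pair co-occurs in no non-hybrid accession
  co <- rownames(mh)[mh[, ja] == 1L & mh[, jb] == 1L]
  expect_identical(co, hyb)
  ## while each individual marker exists in a parental population
  expect_gt(sum(mh[setdiff(rownames(mh), hyb), ja]), 0)
  expect_gt(sum(mh[setdiff(rownames(mh), hyb), jb]), 0)
})

test_that("generators are deterministic under a fixed seed", {
  a1 <- gen_alignment_on_tree(ape::rtree(6), L = 10, seed = 3)
  set.seed(123)  # perturb global RNG state
  a2 <- gen_alignment_on_tree(ape::rtree(6), L = 10, seed = 3)
  ## the tree argument differs (rtree uses global RNG), so compare via
  ## marker/tree generators with fixed inputs instead
  g1 <- gen_hybrid_markers(seed = 7); g2 <- gen_hybrid_markers(seed = 7)
  expect_identical(unclass(g1$markers)[, ], unclass(g2$markers)[, ])
  sp <- read_trees("(((a,b),(c,d)),(e,f));", rooted = TRUE)[[1]]
  d1 <- gen_discordant_trees(sp, 4, hybrid_edges = 1, taxon_dropout = 0.2,
                             seed = 9)
  d2 <- gen_discordant_trees(sp, 4, hybrid_edges = 1, taxon_dropout = 0.2,
                             seed = 9)
  expect_identical(lapply(d1$trees, ape::write.tree),
                   lapply(d2$trees, ape::write.tree))
  expect_identical(d1$truth$moves, d2$truth$moves)
})

test_that("discordant-tree generation scales conflict with planted events", {
  sp <- read_trees("((((a,b),c),((d,e),f)),(g,h));", rooted = TRUE)[[1]]
  g0 <- gen_discordant_trees(sp, n_loci = 4, hybrid_edges = 0, seed = 2)
  expect_equal(pairwise_report(g0$trees)$n_conflicting, 0L)
  sp_key <- paste(sort(vapply(emmernet:::tree_clusters(sp), paste, "",
                              collapse = ",")), collapse = ";")
  for (tr in g0$trees)
    expect_equal(paste(sort(vapply(emmernet:::tree_clusters(tr), paste, "",
                                   collapse = ",")), collapse = ";"), sp_key)

  ## mean pairwise h vs the species tree grows with the event count
  means <- vapply(c(0L, 2L), function(he) {
    hs <- vapply(1:4, function(s) {
      g <- gen_discordant_trees(sp, n_loci = 1, hybrid_edges = he, seed = s)
      min_hybridization(g$trees[[1]], sp, cap = 5L)
    }, 1L)
    mean(hs)
  }, 1)
  expect_gt(means[2], means[1])
})
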