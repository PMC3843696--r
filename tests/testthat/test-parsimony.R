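quartet_aln <- function(cols) {
  ## cols: character vector like c("AACC", "ACAC") -> one column each
  m <- do.call(cbind, lapply(cols, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- letters[1:nrow(m)]
  seq_alignment(m)
}

test_that("Fitch scores match hand counts and a brute-force oracle", {
  t_abcd <- read_trees("((a,b),(c,d));")[[1]]
  t_acbd <- read_trees("((a,c),(b,d));")[[1]]
  a <- quartet_aln("AACC")
  expect_equal(fitch_score(t_abcd, a), 1L)
  expect_equal(fitch_score(t_acbd, a), 2L)

  set.seed(31)
  tr <- ape::rtree(6)
  m <- matrix(sample(c("A", "C", "G", "T", "N"), 6 * 10, replace = TRUE,
                     prob = c(.23, .23, .23, .23, .08)), 6, 10,
              dimnames = list(tr$tip.label, NULL))
  aln <- seq_alignment(m)
  expect_equal(fitch_score(tr, aln), fitch_brute(tr, aln))

  ## cross-check against an independent implementation
  ph <- phangorn::as.phyDat(m)
  expect_equal(fitch_score(tr, aln),
               as.integer(phangorn::parsimony(tr, ph)))
})

test_that("Fitch score is invariant under re-rooting and linear in columns", {
  set.seed(8)
  tr <- ape::rtree(7)
  g <- gen_alignment_on_tree(tr, L = 15, seed = 2)
  s0 <- fitch_score(tr, g$alignment)
  for (tip in c(2, 5)) {
    rr <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[tip],
                    resolve.root = TRUE)
    expect_equal(fitch_score(rr, g$alignment), s0)
  }
  doubled <- seq_alignment(cbind(unclass(g$alignment), unclass(g$alignment)))
  expect_equal(fitch_score(tr, doubled), 2L * s0)
})

test_that("multifurcating trees are scored as given (Hartigan)", {
  star <- read_trees("(a,b,c,d);")[[1]]
  a <- quartet_aln(c("AACC", "ACGT"))
  ## star: col1 needs 2 changes (no internal edge to separate the pairs),
  ## col2 needs 3
  expect_equal(fitch_score(star, a), 5L)
  ## resolving the star can only reduce the count
  expect_equal(fitch_score(read_trees("((a,b),(c,d));")[[1]], a), 4L)
})

test_that("exact search finds the supported quartet and all co-optima", {
  a <- quartet_aln(c("AACC", "AACC", "AACC"))
  mp <- mp_search(a)
  expect_equal(mp$method, "exhaustive")
  expect_equal(mp$score, 3L)
  expect_length(mp$trees, 1L)
  key <- vapply(splits_from_tree(mp$trees[[1]])$splits, split_key, "")
  expect_equal(key, "a,b|c,d")

  ## perfectly conflicting signal: every quartet is co-optimal
  conf <- quartet_aln(c("AACC", "ACAC", "ACCA"))
  mpc <- mp_search(conf)
  expect_length(mpc$trees, 3L)
})

test_that("heuristic search usually matches the exhaustive optimum", {
  set.seed(91)
  hits <- 0L
  n_fix <- 20L
  for (i in seq_len(n_fix)) {
    tr <- ape::rtree(7)
    m <- matrix(sample(c("A", "C", "G", "T"), 7 * 12, replace = TRUE), 7, 12,
                dimnames = list(tr$tip.label, NULL))
    aln <- seq_alignment(m)
    exact <- mp_search(aln, exhaustive_limit = 9L)
    heur <- mp_search(aln, n_jumbles = 10L, seed = i, exhaustive_limit = 4L)
    expect_gte(heur$score, exact$score)
    if (heur$score == exact$score) hits <- hits + 1L
  }
  expect_gte(hits / n_fix, 0.95)
})

test_that("consensus trees retain exactly the shared structure", {
  t1 <- read_trees("((a,b),(c,d),e);")[[1]]
  t2 <- read_trees("((a,b),c,(d,e));")[[1]]
  t3 <- read_trees("((a,c),b,(d,e));")[[1]]

  sc <- strict_consensus(list(t1, t1, t1))
  expect_setequal(vapply(splits_from_tree(sc)$splits, split_key, ""),
                  vapply(splits_from_tree(t1)$splits, split_key, ""))

  ## total conflict collapses to a star
  ta <- read_trees("((a,b),(c,d));")[[1]]
  tb <- read_trees("((a,c),(b,d));")[[1]]
  tc <- read_trees("((a,d),(b,c));")[[1]]
  expect_length(splits_from_tree(strict_consensus(list(ta, tb, tc)))$splits, 0L)

  ## consensus splits are a subset of every input's splits
  scx <- strict_consensus(list(t1, t2))
  kx <- vapply(splits_from_tree(scx)$splits, split_key, "")
  for (t in list(t1, t2))
    expect_true(all(kx %in% vapply(splits_from_tree(t)$splits, split_key, "")))

  mc <- majority_consensus(list(t1, t2, t3))
  expect_equal(mc$supports$pct[mc$supports$split == "a,b|c,d,e"], 66.7)
  expect_false("a,c|b,d,e" %in% mc$supports$split)  # 1 of 3 only
  expect_error(strict_consensus(list(t1, ta)), "differing leaf sets")

  ## cross-check split sets against ape::consensus
  ac <- ape::consensus(c(t1, t2, t3), p = 0.5)
  k_ape <- vapply(splits_from_tree(ac)$splits, split_key, "")
  expect_setequal(mc$supports$split, k_ape)
})

test_that("bootstrap is seed-deterministic and tracks signal strength", {
  set.seed(2)
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  strong <- quartet_aln(rep("AACC", 12))
  b1 <- bootstrap_support(strong, replicates = 80, seed = 5)
  b2 <- bootstrap_support(strong, replicates = 80, seed = 5)
  expect_identical(b1$supports, b2$supports)
  expect_equal(b1$supports$pct[b1$supports$split == "a,b|c,d"], 100)

  ## two equally frequent conflicting patterns: each resolution near 50%
  half <- quartet_aln(c(rep("AACC", 10), rep("ACAC", 10)))
  bh <- bootstrap_support(half, replicates = 400, seed = 9)
  p1 <- bh$supports$pct[bh$supports$split == "a,b|c,d"]
  if (length(p1)) expect_lt(abs(p1 - 50), 15)
})

test_that("bootstrap supports converge between 500 and 1000 replicates", {
  set.seed(6)
  tr <- ape::rtree(6)
  g <- gen_alignment_on_tree(tr, L = 30, seed = 13)
  b500 <- bootstrap_support(g$alignment, replicates = 500, seed = 21)
  b1000 <- bootstrap_support(g$alignment, replicates = 1000, seed = 22)
  shared <- intersect(b500$supports$split, b1000$supports$split)
  expect_gt(length(shared), 0L)
  for (k in shared) {
    d <- abs(b500$supports$pct[b500$supports$split == k] -
               b1000$supports$pct[b1000$supports$split == k])
    expect_lte(d, 3)
  }
})

test_that("incongruence ratio reproduces the diagnostic arithmetic", {
  expect_equal(round(incongruence_ratio(652L, c(377L)), 2), 1.73)
  expect_equal(incongruence_ratio(100L, c(60L, 40L)), 1)
  expect_error(incongruence_ratio(5L, c(0L)), "undefined-ratio")

  ## two perfectly conflicting binary loci on 4 taxa, checked by enumeration
  l1 <- quartet_aln(c("AACC", "AACC"))
  l2 <- quartet_aln(c("ACAC", "ACAC"))
  concat <- seq_alignment(cbind(unclass(l1), unclass(l2)))
  s1 <- mp_search(l1)$score; s2 <- mp_search(l2)$score
  sc <- mp_search(concat)$score
  expect_equal(s1, 2L); expect_equal(s2, 2L); expect_equal(sc, 6L)
  expect_gt(incongruence_ratio(sc, c(s1, s2)), 1)
})

test_that("concatenated MP score is superadditive over loci", {
  set.seed(77)
  for (trial in 1:5) {
    tr1 <- ape::rtree(6); tr2 <- ape::rtree(6)
    tr2$tip.label <- tr1$tip.label
    g1 <- gen_alignment_on_tree(tr1, L = 8, seed = trial)
    g2 <- gen_alignment_on_tree(tr2, L = 8, seed = trial + 100)
    m2 <- unclass(g2$alignment)[rownames(g1$alignment), ]
    concat <- seq_alignment(cbind(unclass(g1$alignment), m2))
    s_c <- mp_search(concat)$score
    s_1 <- mp_search(g1$alignment)$score
    s_2 <- mp_search(seq_alignment(m2))$score
    expect_gte(s_c, s_1 + s_2)
  }
})
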