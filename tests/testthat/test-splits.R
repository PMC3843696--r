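test_that("alignment columns dissolve into splits with missing-taxon exclusion", {
  a <- seq_alignment(c(w = "AAA", x = "ANC", y = "CCG", z = "CCG"))
  ## col 1: A,A,C,C -> {w,x}|{y,z}
  s1 <- split_from_column(a, 1)
  expect_length(s1, 1L)
  expect_equal(split_key(s1[[1]]), "w,x|y,z")
  ## col 2: A,N,C,C -> {w}|{y,z}, x excluded
  s2 <- split_from_column(a, 2)
  expect_equal(split_key(s2[[1]]), "w|y,z")
  ## col 3: A,C,G,G -> state-vs-rest decomposition, canonical + deduplicated
  s3 <- split_from_column(a, 3)
  keys <- vapply(s3, split_key, "")
  expect_true("w|x,y,z" %in% keys)
  expect_true("w,y,z|x" %in% keys)
  expect_true("w,x|y,z" %in% keys)
  expect_equal(anyDuplicated(keys), 0L)

  mono <- seq_alignment(c(w = "A", x = "A"))
  expect_error(split_from_column(mono, 1), "monomorphic")
})

test_that("marker splits flag single-sample insertions as uninformative", {
  m <- matrix(c(1L, 1L, 0L, 0L,
                1L, 0L, 0L, 0L,
                1L, NA, 0L, 0L), 4, 3,
              dimnames = list(letters[1:4], c("m1", "m2", "m3")))
  mm <- marker_matrix(m)
  expect_equal(split_key(split_from_marker(mm, "m1")), "a,b|c,d")
  expect_true(isTRUE(attr(split_from_marker(mm, "m2"), "uninformative")))
  ## missing call excluded; the remaining singleton side is uninformative
  s3 <- split_from_marker(mm, "m3")
  expect_equal(split_key(s3), "a|c,d")
  expect_true(isTRUE(attr(s3, "uninformative")))
  expect_error(split_from_marker(marker_matrix(
    matrix(1L, 2, 1, dimnames = list(c("a", "b"), "mc"))), "mc"), "constant")
  ## single-sample insertions dropped from the bulk extractor
  expect_named(splits_from_markers(mm), "m1")
})

test_that("tree splits come from internal edges only", {
  q <- read_trees("((a,b),(c,d));")[[1]]
  ss <- splits_from_tree(q)
  expect_equal(vapply(ss$splits, split_key, ""), "a,b|c,d")

  star <- read_trees("(a,b,c,d);")[[1]]
  expect_length(splits_from_tree(star)$splits, 0L)

  cat5 <- read_trees("((((a,b),c),d),e);", rooted = TRUE)[[1]]
  un <- ape::unroot(cat5)
  expect_length(splits_from_tree(un)$splits, 2L)
})

test_that("compatibility follows the four-point criterion, with restriction", {
  ab_cd <- taxon_split(c("a", "b"), c("c", "d"))
  ac_bd <- taxon_split(c("a", "c"), c("b", "d"))
  a_bcd <- taxon_split("a", c("b", "c", "d"))
  expect_false(are_compatible(ab_cd, ac_bd))
  expect_true(are_compatible(ab_cd, a_bcd))
  ## partial splits: common domain {a,d} < 4 taxa -> compatible
  ae_df <- taxon_split(c("a", "e"), c("d", "f"))
  expect_true(are_compatible(ab_cd, ae_df))
  ## symmetric and reflexive
  expect_equal(are_compatible(ab_cd, ac_bd), are_compatible(ac_bd, ab_cd))
  expect_true(are_compatible(ab_cd, ab_cd))
})

test_that("restriction intersects sides and composes", {
  s <- taxon_split(c("a", "b"), c("c", "d"))
  expect_equal(split_key(restrict_split(s, c("a", "c"))), "a|c")
  expect_null(restrict_split(s, c("a", "b")))
  r1 <- restrict_split(restrict_split(s, c("a", "b", "c")), c("a", "c"))
  expect_equal(split_key(r1), split_key(restrict_split(s, c("a", "c"))))
})

test_that("column-split compatibility reproduces the four-gamete test", {
  set.seed(42)
  for (trial in 1:25) {
    m <- matrix(sample(c("A", "C"), 6 * 2, replace = TRUE), 6, 2,
                dimnames = list(paste0("t", 1:6), NULL))
    a <- seq_alignment(m)
    s1 <- tryCatch(split_from_column(a, 1)[[1]], error = function(e) NULL)
    s2 <- tryCatch(split_from_column(a, 2)[[1]], error = function(e) NULL)
    if (is.null(s1) || is.null(s2)) next
    expect_equal(!are_compatible(s1, s2),
                 four_gamete_incompatible(m[, 1], m[, 2]))
  }
})

test_that("tree split systems are pairwise compatible and bounded in size", {
  set.seed(7)
  for (n in c(5, 7, 9)) {
    tr <- ape::unroot(ape::rtree(n))
    ss <- splits_from_tree(tr, include_trivial = TRUE)
    sp <- ss$splits
    for (i in seq_along(sp)) for (j in seq_along(sp))
      if (j > i) expect_true(are_compatible(sp[[i]], sp[[j]]))
    expect_lte(length(sp), 2 * n - 3)
  }
})
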