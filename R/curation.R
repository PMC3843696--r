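## Alignment curation applied before tree/network building: extraction of
## polymorphic positions, collapsing of multi-base indels to single
## positions, removal of sequences/columns riddled with unrecognized bases,
## and the diversity/informativeness statistics reported for curated data.

## symbols treated as determined for polymorphism decisions (gap is a state)
is_state <- function(ch) ch %in% STATE_SYMBOLS

#' Keep only polymorphic columns
#'
#' Retains exactly the columns showing at least two distinct determined
#' states (gap counts as a state; ambiguity codes and `N`/`?` do not).
#' Original column indices are carried in the `orig_cols` attribute.
#'
#' @param aln a [seq_alignment()].
#' @return the filtered [seq_alignment()] (possibly with zero columns).
#' @export
extract_polymorphic_columns <- function(aln) {
  if (ncol(aln) == 0L) return(aln)
  keep <- vapply(seq_len(ncol(aln)), function(j) {
    col <- unclass(aln)[, j]
    length(unique(col[is_state(col)])) >= 2L
  }, TRUE)
  aln[, keep]
}

#' Collapse multi-base indels to single positions
#'
#' Every maximal run of length > 1 of adjacent columns sharing an identical,
#' nonempty gap pattern (the same set of gapped taxa) is replaced by its
#' first column, so a k-bp indel contributes one position rather than k.
#' Runs of length 1 and gapless columns are untouched.
#'
#' @param aln a [seq_alignment()].
#' @return the reduced [seq_alignment()].
#' @export
reduce_indels <- function(aln) {
  L <- ncol(aln)
  if (L < 2L) return(aln)
  pat <- vapply(seq_len(L), function(j)
    paste(which(unclass(aln)[, j] == "-"), collapse = ","), "")
  keep <- rep(TRUE, L)
  j <- 1L
  while (j <= L) {
    if (pat[j] != "") {
      k <- j
      while (k < L && pat[k + 1L] == pat[j]) k <- k + 1L
      if (k > j) keep[(j + 1L):k] <- FALSE
      j <- k + 1L
    } else j <- j + 1L
  }
  aln[, keep]
}

#' Drop sequences, then columns, with many unrecognized bases
#'
#' A symbol is unrecognized if outside `A`, `C`, `G`, `T`, `-`. First every
#' sequence with more than `max_unrecognized` such symbols is removed, then
#' every column with more than `max_unrecognized` of them among the
#' remaining sequences. The sequence-first order is fixed: a bad sequence
#' should not drag whole columns down with it.
#'
#' @param aln a [seq_alignment()].
#' @param max_unrecognized maximum tolerated count (default 1, i.e.
#'   "multiple" read as two or more).
#' @return the filtered [seq_alignment()].
#' @export
drop_ambiguous <- function(aln, max_unrecognized = 1L) {
  stopifnot(max_unrecognized >= 1L)
  m <- unclass(aln)
  bad <- !matrix(is_state(m), nrow(m), ncol(m))
  keep_seq <- rowSums(bad) <= max_unrecognized
  if (!any(keep_seq)) stop("empty-alignment error: all sequences removed")
  aln <- aln[keep_seq, ]
  bad <- bad[keep_seq, , drop = FALSE]
  keep_col <- colSums(bad) <= max_unrecognized
  aln[, keep_col]
}

#' Nucleotide diversity (pi) and allele count
#'
#' Average pairwise proportion of differing sites, with pairwise deletion
#' (a site enters a pair's comparison only when both sequences carry a
#' determined base there; gaps are excluded from diversity) and the
#' n/(n-1) small-sample correction:
#' \deqn{\hat\pi = \frac{n}{n-1}\,\binom{n}{2}^{-1} \sum_{i<j} d_{ij}}
#' where d_ij is the per-site Hamming proportion for pair (i, j). Pairs with
#' no comparable sites are excluded with a warning.
#'
#' @param aln a [seq_alignment()] with >= 2 sequences.
#' @return object of class `diversity_result`: list with `pi`,
#'   `n_sequences`, `n_sites`, `n_alleles`.
#' @export
nucleotide_diversity <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("need >= 2 sequences")
  m <- unclass(aln)
  ok <- matrix(m %in% c("A", "C", "G", "T"), n, ncol(m))
  dsum <- 0; npairs <- 0L; dropped <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    L <- sum(comp)
    if (L == 0L) { dropped <- dropped + 1L; next }
    dsum <- dsum + sum(m[i, comp] != m[j, comp]) / L
    npairs <- npairs + 1L
  }
  if (dropped) warning(dropped, " pair(s) with no comparable sites excluded")
  if (npairs == 0L) stop("no comparable sequence pairs")
  pi <- (n / (n - 1)) * dsum / npairs
  structure(list(pi = pi, n_sequences = n, n_sites = ncol(aln),
                 n_alleles = length(unique(apply(m, 1L, paste, collapse = "")))),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("nucleotide diversity: pi = %.4g (%d sequences, %d sites, %d alleles)\n",
              x$pi, x$n_sequences, x$n_sites, x$n_alleles))
  invisible(x)
}

#' Count parsimony-informative columns
#'
#' A column is parsimony-informative when at least two states are each
#' carried by at least two sequences. By default gaps are treated as
#' missing, matching the default gap handling of the parsimony functions;
#' `gap_as_state = TRUE` scores `-` as a 5th state.
#'
#' @param aln a [seq_alignment()].
#' @param gap_as_state logical.
#' @return integer count.
#' @export
count_parsimony_informative <- function(aln, gap_as_state = FALSE) {
  states <- if (gap_as_state) STATE_SYMBOLS else c("A", "C", "G", "T")
  if (ncol(aln) == 0L) return(0L)
  sum(vapply(seq_len(ncol(aln)), function(j) {
    col <- unclass(aln)[, j]
    tab <- table(col[col %in% states])
    sum(tab >= 2L) >= 2L
  }, TRUE))
}

#' One-call curation mirroring the published editing recipe
#'
#' Applies, in order: [drop_ambiguous()], [extract_polymorphic_columns()],
#' [reduce_indels()].
#'
#' @param aln a [seq_alignment()].
#' @param polymorphic_only,reduce,max_unrecognized stage switches.
#' @return the curated [seq_alignment()].
#' @export
curate_alignment <- function(aln, polymorphic_only = TRUE, reduce = TRUE,
                             max_unrecognized = 1L) {
  aln <- drop_ambiguous(aln, max_unrecognized)
  if (polymorphic_only) aln <- extract_polymorphic_columns(aln)
  if (reduce) aln <- reduce_indels(aln)
  aln
}
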