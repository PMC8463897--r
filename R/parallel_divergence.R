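#' Is a tree resolved (nonpolytomous)?
#'
#' Internal branches shorter than `eps` are collapsed first, so a tree is
#' "resolved" only when its signal-bearing structure is fully bifurcating —
#' a formal surrogate for screening topologies by eye for polytomies.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param eps collapse threshold in substitutions/site (default 1e-6).
#' @return logical.
#' @export
is_resolved <- function(tree, eps = 1e-6) {
  tr <- ape::unroot(tree)
  tr <- ape::di2multi(tr, tol = eps)
  tr$Nnode == length(tr$tip.label) - 2L
}

#' Does a tree separate haplotypes A and B at one edge?
#'
#' TRUE when some edge's bipartition is exactly \{all `_A` leaves\} vs
#' \{all `_B` leaves\} — the hallmark of haplotype divergence predating all
#' within-lineage splits.
#'
#' @param tree an `ape::phylo` whose tips end in `_A` or `_B`, one of each
#'   per individual.
#' @return list with `separating` (logical) and, when found, `edge` (row
#'   index into `tree$edge`).
#' @export
is_haplotype_separating <- function(tree) {
  tips <- tree$tip.label
  a_set <- sort(tips[grepl("_A$", tips)])
  b_set <- sort(tips[grepl("_B$", tips)])
  if (length(a_set) + length(b_set) != length(tips) ||
      !identical(sort(sub("_A$", "", a_set)), sort(sub("_B$", "", b_set)))) {
    stop("tips must be a balanced set of _A/_B labels, one of each per individual")
  }
  bp <- edge_bipartitions(tree)
  for (e in seq_along(bp)) {
    side <- sort(bp[[e]])
    if (identical(side, a_set) || identical(side, b_set)) {
      return(list(separating = TRUE, edge = e))
    }
  }
  list(separating = FALSE, edge = NA_integer_)
}

# leaf set below the child node of every edge
edge_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2]]])
}

#' Do the two haplotype subtrees match?
#'
#' Splits the tree at the haplotype-separating edge, roots each side there,
#' strips the `_A`/`_B` suffixes, and tests whether the two rooted
#' leaf-labeled topologies are isomorphic (branch lengths ignored): the
#' operational definition of parallel divergence. Rooted topologies are
#' compared as clade sets, so the test is invariant to leaf order and to a
#' global A/B swap.
#'
#' @param tree an `ape::phylo` for which [is_haplotype_separating()] is TRUE.
#' @return logical.
#' @export
subtrees_match <- function(tree) {
  sep <- is_haplotype_separating(tree)
  if (!sep$separating) stop("tree does not separate haplotypes")
  tips <- tree$tip.label
  a_set <- tips[grepl("_A$", tips)]
  b_set <- tips[grepl("_B$", tips)]
  key_a <- rooted_clade_keys(side_subtree(tree, a_set, b_set))
  key_b <- rooted_clade_keys(side_subtree(tree, b_set, a_set))
  setequal(key_a, key_b)
}

# extract one side of the separating edge as a rooted subtree
side_subtree <- function(tree, side_tips, other_tips) {
  if (length(side_tips) == 1) {
    return(side_tips)
  }
  rt <- ape::root(tree, outgroup = other_tips, resolve.root = TRUE)
  ape::keep.tip(rt, side_tips)
}

# clade keys of a rooted tree, with haplotype suffixes stripped
rooted_clade_keys <- function(tr) {
  strip <- function(x) sub("_(A|B)$", "", x)
  if (is.character(tr)) return(paste(sort(strip(tr)), collapse = "|"))
  labs <- strip(tr$tip.label)
  n_tip <- length(labs)
  below <- vector("list", n_tip + tr$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- labs[i]
  ord <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  keys <- vapply(below, function(x) paste(sort(x), collapse = "|"), character(1))
  unique(keys[nzchar(keys)])
}

#' Number of rooted leaf-labeled topologies on k taxa
#'
#' `(2k - 3)!!` — the null universe for the parallel-divergence chance
#' probability `x = 1 / n_rooted_topologies(k)`.
#'
#' @param k number of taxa (>= 2).
#' @return count (numeric, exact for the k used here).
#' @export
n_rooted_topologies <- function(k) {
  if (k < 2) stop("k must be >= 2")
  if (k == 2) return(1)
  prod(seq(3, 2 * k - 3, by = 2))
}

#' Upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, x)`, by direct term summation
#' `sum_{i=k}^{n} C(n,i) x^i (1-x)^(n-i)` in log space.
#'
#' @param n number of trials.
#' @param k threshold count (0 <= k <= n).
#' @param x success probability in (0, 1).
#' @return probability.
#' @export
binomial_tail <- function(n, k, x) {
  stopifnot(k >= 0, k <= n, x > 0, x < 1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(x) + (n - i) * log1p(-x)))
}

#' Parallel-divergence test over a set of region trees
#'
#' For one lineage's per-region best ML trees: counts trees that are
#' resolved ([is_resolved()]), that fully separate haplotypes A and B
#' ([is_haplotype_separating()]), and whose two haplotype subtrees match
#' ([subtrees_match()]); then tests whether matching is more frequent than
#' the uniform-topology chance probability `x = 1/(2k-3)!!` with the exact
#' upper-tail binomial probability
#' `P(X >= n_matching | n_separating, x)`.
#'
#' @param trees list of `ape::phylo` trees sharing the lineage's leaf set.
#' @param eps polytomy-collapse threshold for [is_resolved()].
#' @return object of class `parallel_result`: `n_trees`, `n_resolved`,
#'   `n_separating`, `n_matching`, `k_taxa`, `x_null`, `fold`
#'   (matching frequency over chance), `p_value` (NA when nothing
#'   separates).
#' @export
parallel_divergence_test <- function(trees, eps = 1e-6) {
  stopifnot(length(trees) > 0)
  k <- length(trees[[1]]$tip.label) / 2
  resolved <- vapply(trees, is_resolved, logical(1), eps = eps)
  separating <- logical(length(trees))
  matching <- logical(length(trees))
  for (i in which(resolved)) {
    sep <- is_haplotype_separating(trees[[i]])
    separating[i] <- sep$separating
    if (sep$separating) matching[i] <- subtrees_match(trees[[i]])
  }
  n_sep <- sum(separating); n_match <- sum(matching)
  x <- 1 / n_rooted_topologies(k)
  structure(
    list(
      n_trees = length(trees), n_resolved = sum(resolved),
      n_separating = n_sep, n_matching = n_match, k_taxa = k, x_null = x,
      fold = if (n_sep > 0) n_match / (n_sep * x) else NA_real_,
      p_value = if (n_sep > 0) binomial_tail(n_sep, n_match, x) else NA_real_
    ),
    class = "parallel_result"
  )
}

#' @export
print.parallel_result <- function(x, ...) {
  cat(sprintf(
    "parallel divergence: %d/%d resolved, %d separating, %d matching (k=%g, x=%.4g)\n",
    x$n_resolved, x$n_trees, x$n_separating, x$n_matching, x$k_taxa, x$x_null
  ))
  cat(sprintf("fold over chance = %.3g, binomial P = %.4g\n", x$fold, x$p_value))
  invisible(x)
}
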