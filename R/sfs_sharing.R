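#' Nonreference site frequency spectrum
#'
#' Counts sites by the total nonreference allele dosage `j` over the `m`
#' individuals: `m` diploids can display between 0 and `2m` nonreference
#' alleles at a site.
#'
#' @param gm a complete, biallelic [genotype_matrix()]
#' @return data.frame with columns `j` (0..2m) and `n_sites`.
#' @export
nonreference_sfs <- function(gm) {
  if (anyNA(gm$calls)) stop("SFS requires a complete genotype matrix")
  m <- n_individuals(gm)
  j <- rowSums(gm$calls)
  counts <- tabulate(j + 1L, nbins = 2L * m + 1L)
  data.frame(j = 0:(2 * m), n_sites = counts)
}

#' Probability of a genotype profile under HWE, conditional on allele count
#'
#' Exact finite-sample Hardy-Weinberg null: given that `j` nonreference and
#' `2m - j` reference alleles are assigned uniformly at random to the `2m`
#' allele slots of `m` diploid individuals, the probability of one ordered
#' genotype configuration is
#' \deqn{\prod_i w(g_i) / \binom{2m}{j}, \quad w(het) = 2,\; w(hom) = 1,}
#' because a heterozygote can carry its nonreference allele on either copy.
#' Conditioning on the observed allele count (rather than an estimated
#' allele frequency) keeps the null exact at any sample size. Probabilities
#' over all ordered profiles with a fixed `j` sum to one.
#'
#' @param profile integer dosage vector of length m (0 = hom-ref, 1 = het,
#'   2 = hom-alt).
#' @param j nonreference allele count; must equal `sum(profile)`.
#' @return probability in \[0, 1\].
#' @export
profile_probability_given_j <- function(profile, j = sum(profile)) {
  stopifnot(all(profile %in% 0:2))
  if (j != sum(profile)) stop("j inconsistent with profile")
  m <- length(profile)
  prod(ifelse(profile == 1L, 2, 1)) / choose(2 * m, j)
}

#' Fold excess of a genotype profile over its HWE expectation
#'
#' Restricted to sites carrying the profile's allele count `j`, compares the
#' observed proportion of sites matching the profile (heterozygous in every
#' individual of `het_set`, homozygous reference elsewhere) against the
#' exact HWE-conditional probability from
#' [profile_probability_given_j()].
#'
#' @param gm a complete, biallelic [genotype_matrix()]
#' @param het_set individuals required to be heterozygous; all others must
#'   be homozygous reference.
#' @return list: `fold` (NA when no site has the required `j`; 0 when the
#'   profile is never observed), `observed`, `n_sites_with_j`,
#'   `expected_probability`, `expected_count`, `j`.
#' @export
fold_excess <- function(gm, het_set) {
  if (!all(het_set %in% gm$individuals)) stop("het_set individuals not in matrix")
  if (anyNA(gm$calls)) stop("fold_excess requires a complete genotype matrix")
  m <- n_individuals(gm)
  jt <- rowSums(gm$calls)
  j <- length(het_set)
  in_set <- gm$individuals %in% het_set
  target <- as.integer(in_set) # het in set, hom-ref elsewhere
  with_j <- jt == j
  matches <- with_j & rowSums(gm$calls == rep(target, each = n_sites(gm))) == m
  n_j <- sum(with_j)
  obs <- sum(matches)
  p_exp <- profile_probability_given_j(target, j)
  fold <- if (n_j == 0) NA_real_ else (obs / n_j) / p_exp
  list(fold = fold, observed = obs, n_sites_with_j = n_j,
       expected_probability = p_exp, expected_count = n_j * p_exp, j = j)
}

#' Fold-excess table for the shared-heterozygote categories
#'
#' The grouped categories used to summarise heterozygote sharing on the
#' nonreference SFS: heterozygous in all individuals, heterozygous privately
#' in each lineage (all lineage members het, everyone else homozygous
#' reference).
#'
#' @param gm a complete, biallelic [genotype_matrix()]
#' @param metadata data.frame with individual and lineage columns; only
#'   individuals present in `gm` are considered.
#' @return data.frame with one row per category.
#' @export
fold_excess_table <- function(gm, metadata) {
  lin <- metadata$lineage[match(gm$individuals, metadata$individual)]
  cats <- list(all_het = gm$individuals)
  for (l in unique(lin[!is.na(lin)])) {
    cats[[paste0("private_", l)]] <- gm$individuals[!is.na(lin) & lin == l]
  }
  rows <- lapply(names(cats), function(nm) {
    fe <- fold_excess(gm, cats[[nm]])
    data.frame(category = nm, j = fe$j, observed = fe$observed,
               n_sites_with_j = fe$n_sites_with_j,
               expected_probability = fe$expected_probability,
               expected_count = fe$expected_count, fold = fe$fold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shared-heterozygote counts on the lineage tree branches
#'
#' Counts sites whose heterozygous genotypes map onto a branch of the
#' lineage tree: shared by every individual (root branch), or private to one
#' lineage (all its members het and nobody else het). Sites where any
#' individual is homozygous alternate belong to none of these categories
#' (they are neither shared-het nor private-het), though they remain in the
#' SFS. The categories are disjoint.
#'
#' @param gm a complete, biallelic [genotype_matrix()]
#' @param lineages named character vector mapping every individual to a
#'   lineage.
#' @return named integer vector: `all` plus one entry per lineage.
#' @export
shared_het_branch_counts <- function(gm, lineages) {
  if (!all(gm$individuals %in% names(lineages))) {
    stop("lineage map must cover all individuals")
  }
  lin <- lineages[gm$individuals]
  g <- gm$calls
  no_homalt <- rowSums(g == 2L) == 0L
  is_het <- g == 1L
  out <- c(all = sum(no_homalt & rowSums(is_het) == ncol(g)))
  for (l in unique(lin)) {
    inl <- lin == l
    cnt <- sum(no_homalt &
                 rowSums(is_het[, inl, drop = FALSE]) == sum(inl) &
                 rowSums(is_het[, !inl, drop = FALSE]) == 0L)
    out[l] <- cnt
  }
  out
}
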