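#' Per-individual heterozygosity
#'
#' Percentage of heterozygous genotypes per individual over all retained
#' sites, monomorphic sites included (so the denominator reflects every site
#' with an available genotype, and is identical across individuals when the
#' completeness filter was applied).
#'
#' @param gm a [genotype_matrix()] filtered with the heterozygosity recipe
#'   (depth mask + completeness, monomorphic sites retained).
#' @return data.frame with columns individual, n_sites_used, n_het, pct_het.
#' @export
individual_heterozygosity <- function(gm) {
  n_used <- colSums(!is.na(gm$calls))
  if (any(n_used == 0)) stop("individual(s) with zero usable sites")
  n_het <- colSums(gm$calls == 1L, na.rm = TRUE)
  data.frame(
    individual = gm$individuals,
    n_sites_used = as.integer(n_used),
    n_het = as.integer(n_het),
    pct_het = 100 * n_het / n_used,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Per-individual inbreeding coefficient within a group
#'
#' Method-of-moments estimator of F for one individual against the allele
#' frequencies of its (sub)population or lineage, matching the classical
#' per-individual heterozygosity-excess estimator of standard VCF toolkits:
#' \deqn{F = (O_{hom} - E_{hom}) / (N - E_{hom})}
#' with per-site expected homozygosity
#' \eqn{1 - 2 p (1-p) \cdot 2n/(2n-1)} (small-sample HWE correction), where
#' `p` is the nonreference allele frequency in the group (focal individual
#' included) and `n` the number of diploid individuals. Sites monomorphic
#' within the group carry no information and are excluded; the reported
#' `n_sites` is post-exclusion, which is why different groups report
#' different site counts.
#'
#' @param gm_group [genotype_matrix()] restricted to the focal individual's
#'   group, fully filtered (complete, biallelic SNPs).
#' @param focal identifier of the focal individual.
#' @return list with `fis` and `n_sites`.
#' @export
fis_per_individual <- function(gm_group, focal) {
  if (n_individuals(gm_group) < 2) {
    stop("estimating F requires a (sub)population context of at least two individuals")
  }
  if (!focal %in% gm_group$individuals) stop("focal individual not in group")
  g <- gm_group$calls
  if (anyNA(g)) stop("group matrix contains missing calls; filter first")
  n <- n_individuals(gm_group)
  p <- rowSums(g) / (2 * n)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no sites polymorphic within the group; F undefined")
  p <- p[poly]
  e_hom <- 1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  o_hom <- sum(g[poly, focal] != 1L)
  E <- sum(e_hom)
  N <- sum(poly)
  list(fis = (o_hom - E) / (N - E), n_sites = as.integer(N))
}

#' Inbreeding coefficients for all individuals, grouped
#'
#' Convenience wrapper: partitions the matrix at the requested level and
#' estimates F for every labeled individual within its group. Individuals
#' without a group label, or in singleton groups, get `NA` (no
#' subpopulation context).
#'
#' @param gm a fully filtered [genotype_matrix()]
#' @param metadata data.frame with individual/population/lineage columns
#' @param level `"lineage"` (for clonal species with divergent lineages) or
#'   `"population"`.
#' @return data.frame with columns individual, group, fis, n_sites.
#' @export
fis_table <- function(gm, metadata, level = c("lineage", "population")) {
  level <- match.arg(level)
  lab <- metadata[[level]][match(gm$individuals, metadata$individual)]
  out <- data.frame(
    individual = gm$individuals, group = lab,
    fis = NA_real_, n_sites = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (grp in unique(lab[!is.na(lab)])) {
    ids <- gm$individuals[!is.na(lab) & lab == grp]
    if (length(ids) < 2) next
    sub <- subset_gm(gm, individuals = ids)
    # re-filter within the group: complete already; restrict to biallelic SNPs
    sub <- filter_sites(sub, min_depth = 0, require_complete = TRUE,
                        biallelic_snps_only = TRUE, drop_monomorphic = TRUE)
    for (id in ids) {
      res <- tryCatch(fis_per_individual(sub, id), error = function(e) NULL)
      if (!is.null(res)) {
        out$fis[out$individual == id] <- res$fis
        out$n_sites[out$individual == id] <- res$n_sites
      }
    }
  }
  out
}

#' Exact Wilcoxon rank-sum test by complete enumeration
#'
#' Mann-Whitney statistic `W` counting pairs (a, b), a from `group_a`, with
#' a > b (ties contribute 1/2, i.e. mid-ranks), and a two-sided p-value by
#' complete enumeration of all `choose(nA + nB, nA)` label assignments. The
#' two-sided p doubles the smaller tail and is capped at 1. Exact
#' enumeration is restricted to 25 values total.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @return list with `W`, `p_value`, `n_assignments`.
#' @export
rank_sum_exact <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b)
  if (na + nb > 25) stop("exact enumeration limited to 25 values total")
  x <- c(group_a, group_b)
  r <- rank(x) # mid-ranks for ties
  w_from_ranks <- function(ra) sum(ra) - na * (na + 1) / 2
  W_obs <- w_from_ranks(r[seq_len(na)])
  combos <- utils::combn(na + nb, na)
  Ws <- apply(combos, 2, function(idx) w_from_ranks(r[idx]))
  eps <- 1e-9
  p_lo <- mean(Ws <= W_obs + eps)
  p_hi <- mean(Ws >= W_obs - eps)
  list(W = W_obs, p_value = min(1, 2 * min(p_lo, p_hi)),
       n_assignments = ncol(combos))
}
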