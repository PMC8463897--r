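#' Allele-sharing (Hamming) distance between individuals
#'
#' The raw genotype distance used for ordination: the L1 distance between
#' nonreference allele dosages, `d(i, j) = sum over sites |g_i - g_j|` with
#' `g` in 0/1/2. For biallelic sites this equals the identity-by-state
#' mismatch count over the two allele copies, i.e. the "raw Hamming
#' distance" of standard genotype toolkits. A strict genotype-mismatch
#' variant (counting 1 per differing genotype regardless of dosage) is
#' available behind `strict`.
#'
#' @param gm a complete, biallelic [genotype_matrix()] (filter first).
#' @param normalize divide by the number of sites (per-site distance).
#' @param strict count genotype mismatches instead of dosage differences.
#' @return symmetric numeric matrix with individuals as dimnames.
#' @export
allele_hamming_distance <- function(gm, normalize = FALSE, strict = FALSE) {
  if (anyNA(gm$calls)) {
    stop("genotype matrix contains missing calls; run filter_sites() with require_complete = TRUE first")
  }
  if (strict) {
    n <- n_individuals(gm)
    d <- matrix(0, n, n, dimnames = list(gm$individuals, gm$individuals))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- sum(gm$calls[, i] != gm$calls[, j])
      }
    }
  } else {
    d <- as.matrix(stats::dist(t(gm$calls), method = "manhattan"))
    dimnames(d) <- list(gm$individuals, gm$individuals)
  }
  if (normalize && n_sites(gm) > 0) d <- d / n_sites(gm)
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and returns the leading
#' principal coordinates. Axes with non-positive eigenvalues are dropped
#' with a warning; all eigenvalues are reported so the user can judge how
#' Euclidean the input was.
#'
#' @param dm symmetric distance matrix (zero diagonal).
#' @param dims number of coordinates requested (default 2, the conventional
#'   two-scale representation).
#' @return list with `points` (n x k coordinate matrix, k <= dims),
#'   `eigenvalues` (all n of them, descending).
#' @export
classical_mds <- function(dm, dims = 2) {
  stopifnot(dims >= 1)
  dm <- as.matrix(dm)
  res <- stats::cmdscale(dm, k = min(dims, nrow(dm) - 1), eig = TRUE)
  pos <- sum(res$eig > sqrt(.Machine$double.eps) * max(abs(res$eig), 1))
  k <- min(dims, pos)
  if (k < dims) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axes", pos, k))
  }
  pts <- res$points[, seq_len(k), drop = FALSE]
  list(points = pts, eigenvalues = res$eig)
}

# Per-individual-pair allele-level distance sums, the sufficient statistics
# for the hierarchical AMOVA. For dosages g, h the sum of Hamming distances
# over the 4 cross pairings of allele copies is g*(2-h) + h*(2-g); within an
# individual the two copies differ exactly at heterozygous sites. Both are
# invariant to phase, which makes every AMOVA quantity phase-invariant.
amova_sufficient_stats <- function(gm) {
  if (anyNA(gm$calls)) stop("AMOVA requires a complete genotype matrix")
  n <- n_individuals(gm)
  C <- matrix(0, n, n, dimnames = list(gm$individuals, gm$individuals))
  g <- gm$calls
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      C[i, j] <- C[j, i] <- sum(g[, i] * (2 - g[, j]) + g[, j] * (2 - g[, i]))
    }
  }
  w <- colSums(g == 1L)
  list(C = C, w = w)
}

amova_components <- function(C, w, pop) {
  pop <- as.character(pop)
  n_ind <- length(w)
  pops <- unique(pop)
  P <- length(pops)
  if (P < 2) stop("AMOVA needs at least two populations")
  Th <- 2 * n_ind # total haplotypes

  pair_sum <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(C[idx, idx][upper.tri(C[idx, idx])])
  }
  ssd_total <- (sum(C[upper.tri(C)]) + sum(w)) / Th
  ssd_wp <- sum(vapply(pops, function(p) {
    idx <- which(pop == p)
    (pair_sum(idx) + sum(w[idx])) / (2 * length(idx))
  }, numeric(1)))
  ssd_wi <- sum(w) / 2
  ssd_ai <- ssd_wp - ssd_wi
  ssd_ap <- ssd_total - ssd_wp

  df_ap <- P - 1
  df_ai <- n_ind - P
  df_wi <- n_ind
  ms_wi <- ssd_wi / df_wi
  ms_ai <- if (df_ai > 0) ssd_ai / df_ai else NA_real_
  ms_ap <- ssd_ap / df_ap

  t_p <- 2 * as.numeric(table(pop)[pops])
  n_c <- (Th - sum(t_p^2) / Th) / (P - 1)

  s2_wi <- ms_wi
  s2_ai <- if (is.na(ms_ai)) 0 else (ms_ai - s2_wi) / 2
  s2_ap <- (ms_ap - s2_wi - 2 * s2_ai) / n_c
  list(
    ssd = c(among_pop = ssd_ap, among_ind = ssd_ai, within_ind = ssd_wi, total = ssd_total),
    df = c(among_pop = df_ap, among_ind = df_ai, within_ind = df_wi),
    sigma2 = c(among_pop = s2_ap, among_ind = s2_ai, within_ind = s2_wi)
  )
}

#' Hierarchical AMOVA on allele-level distances
#'
#' Three-level analysis of molecular variance in the Excoffier
#' sums-of-squares framework: among populations, among individuals within
#' populations, and within individuals. Each diploid individual contributes
#' two allele copies; all sums run over every pairing of allele copies, so
#' the result does not depend on phase. Squared inter-haplotype distances
#' are allele Hamming distances (number of differing sites), the standard
#' choice for sequence-type AMOVA. Negative method-of-moments components are
#' truncated to zero (and flagged) before percentages are computed.
#'
#' @param gm a complete, biallelic [genotype_matrix()]
#' @param populations named character vector (names = individuals) or a
#'   metadata data.frame with columns `individual` and `population`.
#' @return object of class `amova_result`: variance components, percentages,
#'   phi statistics, degrees of freedom, sums of squares.
#' @export
amova <- function(gm, populations) {
  pop <- resolve_populations(gm, populations)
  st <- amova_sufficient_stats(gm)
  comp <- amova_components(st$C, st$w, pop)
  s2 <- comp$sigma2
  truncated <- s2 < 0
  s2t <- pmax(s2, 0)
  total <- sum(s2t)
  pct <- if (total > 0) 100 * s2t / total else rep(NA_real_, 3)
  names(pct) <- names(s2)
  phi <- c(
    phi_st = if (total > 0) (s2t[["among_pop"]] + s2t[["among_ind"]]) / total else NA_real_,
    phi_ct = if (total > 0) s2t[["among_pop"]] / total else NA_real_,
    phi_is = if (s2t[["among_ind"]] + s2t[["within_ind"]] > 0)
      s2t[["among_ind"]] / (s2t[["among_ind"]] + s2t[["within_ind"]]) else NA_real_
  )
  structure(
    list(sigma2 = s2, sigma2_truncated = s2t, pct = pct, phi = phi,
         ssd = comp$ssd, df = comp$df, truncated = truncated,
         populations = pop),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (allele level)\n")
  tab <- data.frame(
    level = names(x$sigma2),
    sigma2 = round(x$sigma2, 4),
    pct = round(x$pct, 2)
  )
  print(tab, row.names = FALSE)
  if (!is.null(x$p_value)) cat(sprintf("permutation p (among populations): %.4g\n", x$p_value))
  invisible(x)
}

resolve_populations <- function(gm, populations) {
  if (is.data.frame(populations)) {
    pop <- populations$population[match(gm$individuals, populations$individual)]
  } else {
    pop <- populations[gm$individuals]
  }
  if (anyNA(pop)) stop("every individual needs a population label")
  as.character(pop)
}

#' Permutation test for the among-population variance component
#'
#' Permutes whole individuals (both allele copies together) across
#' populations and recomputes the among-population component. The p-value
#' uses the add-one estimator `(1 + #perm >= observed) / (n_perm + 1)`,
#' which never returns zero.
#'
#' @param gm a complete, biallelic [genotype_matrix()]
#' @param populations as in [amova()]
#' @param n_perm number of permutations (>= 99; default 999)
#' @param seed optional integer seed for a reproducible permutation stream
#' @return the [amova()] result with `p_value` and `n_perm` added.
#' @export
amova_permutation_test <- function(gm, populations, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99 (p-value resolution too coarse)")
  if (!is.null(seed)) set.seed(seed)
  pop <- resolve_populations(gm, populations)
  st <- amova_sufficient_stats(gm)
  obs <- amova_components(st$C, st$w, pop)$sigma2[["among_pop"]]
  perm <- vapply(seq_len(n_perm), function(i) {
    amova_components(st$C, st$w, sample(pop))$sigma2[["among_pop"]]
  }, numeric(1))
  res <- amova(gm, populations)
  res$p_value <- (1 + sum(perm >= obs)) / (n_perm + 1)
  res$n_perm <- n_perm
  res
}
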