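#' Jukes-Cantor (JC69) pairwise distance
#'
#' Pairwise-deletion distance between two aligned sequences: columns where
#' either sequence is not an unambiguous nucleotide are excluded, the
#' mismatch proportion `p` is computed over the rest, and
#' `d = -(3/4) log(1 - (4/3) p)`. Saturated pairs (`p >= 0.75`) get an
#' infinite-distance sentinel with a warning.
#'
#' @param seq_a,seq_b aligned sequences (equal-length strings or character
#'   vectors).
#' @return distance in expected substitutions per site.
#' @export
jc69_pairwise_distance <- function(seq_a, seq_b) {
  a <- to_chars(seq_a); b <- to_chars(seq_b)
  stopifnot(length(a) == length(b))
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  if (!any(use)) stop("no usable columns (all masked or ambiguous)")
  p <- mean(a[use] != b[use])
  if (p >= 0.75) {
    warning("mismatch proportion >= 0.75: JC69 distance saturated")
    return(Inf)
  }
  -0.75 * log(1 - 4 * p / 3)
}

to_chars <- function(s) {
  if (length(s) == 1L && nchar(s[1]) > 1L) strsplit(toupper(s), "")[[1]] else toupper(s)
}

#' JC69 distance matrix for a set of aligned sequences
#' @param seqs named character vector (or list) of aligned sequences.
#' @return symmetric numeric matrix.
#' @export
jc69_distance_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      # pairs sharing no usable column get the saturation sentinel
      d[i, j] <- d[j, i] <- tryCatch(
        suppressWarnings(jc69_pairwise_distance(seqs[[i]], seqs[[j]])),
        error = function(e) Inf
      )
    }
  }
  d
}

#' Neighbor-joining starting tree
#'
#' Standard neighbor joining with negative branch lengths clamped to zero,
#' the deficit being moved to the adjacent branch toward the root of the
#' edge so path lengths are approximately preserved.
#'
#' @param dm symmetric distance matrix with >= 3 labels and finite entries.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 labels")
  if (any(!is.finite(dm))) {
    stop("infinite distances present; exclude this region (saturated haplotypes)")
  }
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    up <- which(tr$edge[, 2] == parent)
    if (length(up)) tr$edge.length[up] <- tr$edge.length[up] + deficit
  }
  tr
}

# character sequences -> phangorn phyDat (N, - treated as ambiguity)
aln_to_phydat <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(unlist(seqs)), ""))
  rownames(m) <- names(seqs)
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-", "?"))
  if (length(bad)) stop("non-nucleotide symbols in alignment: ", paste(bad, collapse = ","))
  m[m == "-"] <- "N"
  phangorn::phyDat(m, type = "DNA")
}

#' Maximum-likelihood branch lengths on a fixed topology (JC69)
#'
#' Optimises branch lengths by maximum likelihood under JC69 on the given
#' topology (multifurcations are resolved deterministically first; the
#' resolving branches simply fit to near-zero length when unsupported).
#' Also returns the per-site log-likelihood vector needed for
#' resampling-based topology tests.
#'
#' @param topology an `ape::phylo` whose tip set equals the alignment rows.
#' @param aln named character vector of aligned sequences.
#' @return list with `tree` (optimised), `log_lik`, `site_lnl` (length =
#'   alignment columns).
#' @export
fit_branch_lengths <- function(topology, aln) {
  dat <- aln_to_phydat(aln)
  if (!setequal(names(aln), topology$tip.label)) {
    stop("topology tips must match alignment rows")
  }
  tr <- topology
  # two taxa: the JC69 pairwise distance is the exact ML branch length and
  # the site likelihoods have a closed form
  if (length(tr$tip.label) == 2) {
    return(fit_two_taxa(tr, aln))
  }
  if (!ape::is.binary(tr)) tr <- ape::multi2di(tr, random = FALSE)
  tr <- ape::unroot(tr)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.01, nrow(tr$edge))
  tr$edge.length[tr$edge.length <= 0] <- 1e-6
  fit <- phangorn::pml(tr, dat)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  list(tree = fit$tree, log_lik = as.numeric(fit$logLik),
       site_lnl = site_lnl_from_fit(fit, dat))
}

site_lnl_from_fit <- function(fit, dat) {
  as.numeric(fit$siteLik)[attr(dat, "index")]
}

fit_two_taxa <- function(tr, aln) {
  a <- to_chars(aln[[tr$tip.label[1]]])
  b <- to_chars(aln[[tr$tip.label[2]]])
  d <- jc69_pairwise_distance(a, b)
  if (!is.finite(d)) stop("saturated two-taxon alignment")
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  e <- exp(-4 * d / 3)
  site_lnl <- ifelse(!use, log(1 / 4),
                     ifelse(a == b, log(1 / 4 * (1 / 4 + 3 / 4 * e)),
                            log(1 / 4 * (1 / 4 - 1 / 4 * e))))
  out <- tr
  out$edge.length <- rep(d / 2, nrow(tr$edge))
  list(tree = out, log_lik = sum(site_lnl), site_lnl = site_lnl)
}

#' Unconstrained ML tree search (NJ start + NNI hill-climbing)
#'
#' Deterministic search for the best-fitting ML tree under JC69:
#' neighbor-joining on JC69 distances as the starting tree, then
#' nearest-neighbor-interchange hill-climbing with branch-length
#' re-optimisation until no interchange improves the log-likelihood.
#'
#' @param aln named character vector of aligned sequences (>= 3 unique
#'   names).
#' @param start optional starting `phylo`; default NJ on JC69 distances.
#' @return list with `tree`, `log_lik`, `site_lnl`.
#' @export
nni_search <- function(aln, start = NULL) {
  dat <- aln_to_phydat(aln)
  if (is.null(start)) {
    dm <- jc69_distance_matrix(aln)
    # saturated pairs cannot seed NJ; fall back to a fixed ladder start
    if (any(!is.finite(dm))) {
      start <- ape::unroot(ape::stree(length(aln), type = "right", tip.label = names(aln)))
      start$edge.length <- rep(0.05, nrow(start$edge))
    } else {
      start <- nj_tree(dm)
    }
  }
  start <- ape::unroot(start)
  start$edge.length[start$edge.length <= 0] <- 1e-6
  fit <- phangorn::pml(start, dat)
  fit <- phangorn::optim.pml(fit, optNni = TRUE, optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  list(tree = fit$tree, log_lik = as.numeric(fit$logLik),
       site_lnl = site_lnl_from_fit(fit, dat))
}

#' Constraint topology templates for the asexual / sexual hypotheses
#'
#' Builds the multifurcating constraint topology for one phased region. In
#' `asex` mode haplotypes A and B are separated at the base; within each
#' haplotype clade, lineages (two-lineage template), then populations, then
#' individuals nest as polytomies. In `sex` mode there is no haplotype
#' separation: the base separates lineages (two-lineage template) or
#' populations (single-species template), with both haplotypes of an
#' individual sitting in its population clade. For the single-species asex
#' template, `most_divergent_population` optionally splits that
#' population's B haplotypes from the other B haplotypes so the unrooted
#' constraint contains a trichotomy.
#'
#' @param mode `"asex"` or `"sex"`.
#' @param participants individuals present in the region.
#' @param metadata data.frame with individual/population/lineage columns.
#' @param template `"two-lineage"` (clonal species with divergent lineages;
#'   requires lineage labels) or `"single-species"`.
#' @param most_divergent_population optional population name (single-species
#'   asex template only).
#' @return an `ape::phylo` constraint topology with tips `<ind>_A`, `<ind>_B`.
#' @export
build_constraint_topology <- function(mode = c("asex", "sex"), participants,
                                      metadata,
                                      template = c("two-lineage", "single-species"),
                                      most_divergent_population = NULL) {
  mode <- match.arg(mode)
  template <- match.arg(template)
  md <- metadata[match(participants, metadata$individual), , drop = FALSE]
  if (anyNA(md$population)) stop("participant missing population label")
  if (template == "two-lineage" && anyNA(md$lineage)) {
    stop("participant missing lineage label in two-lineage mode")
  }

  clade <- function(children) {
    children <- children[nzchar(children)]
    if (length(children) == 1) children else paste0("(", paste(children, collapse = ","), ")")
  }
  pops_clade <- function(ids, suffix) {
    # group individuals by population; each pop clade is a polytomy of tips
    by_pop <- split(ids, md$population[match(ids, md$individual)])
    clade(vapply(by_pop, function(x) clade(paste0(x, "_", suffix)), character(1)))
  }
  hap_clade <- function(suffix) {
    if (template == "two-lineage") {
      by_lin <- split(participants, md$lineage)
      clade(vapply(by_lin, pops_clade, character(1), suffix = suffix))
    } else {
      pops_clade(participants, suffix)
    }
  }

  nwk <- if (mode == "asex") {
    if (template == "single-species" && !is.null(most_divergent_population)) {
      mdp <- participants[md$population == most_divergent_population]
      rest <- setdiff(participants, mdp)
      if (!length(mdp) || !length(rest)) stop("bad most_divergent_population")
      paste0("(", hap_clade("A"), ",",
             clade(paste0(mdp, "_B")), ",",
             pops_clade_subset(rest, md, clade), ");")
    } else {
      paste0("(", hap_clade("A"), ",", hap_clade("B"), ");")
    }
  } else {
    if (template == "two-lineage") {
      by_lin <- split(participants, md$lineage)
      paste0("(", paste(vapply(by_lin, function(ids) {
        by_pop <- split(ids, md$population[match(ids, md$individual)])
        clade(vapply(by_pop, function(x) clade(c(paste0(x, "_A"), paste0(x, "_B"))),
                     character(1)))
      }, character(1)), collapse = ","), ");")
    } else {
      by_pop <- split(participants, md$population)
      paste0("(", paste(vapply(by_pop, function(x) {
        clade(c(paste0(x, "_A"), paste0(x, "_B")))
      }, character(1)), collapse = ","), ");")
    }
  }
  ape::read.tree(text = nwk)
}

# B-haplotype clade over a subset, grouped by population (single-species
# asex template with the most divergent population's B haplotypes split off)
pops_clade_subset <- function(ids, md, clade) {
  by_pop <- split(ids, md$population[match(ids, md$individual)])
  clade(vapply(by_pop, function(x) clade(paste0(x, "_B")), character(1)))
}

#' Branch-score (Kuhner-Felsenstein) distance between two trees
#'
#' Square root of the sum, over the union of bipartitions of the two
#' (unrooted) trees, of squared branch-length differences; a bipartition
#' absent from one tree contributes its full length in the other. External
#' branches are included. Zero-length branches count as present.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return nonnegative distance.
#' @export
branch_score_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("trees must share a leaf set")
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "score"))
}

#' Per-region Delta statistic
#'
#' Fits the unconstrained best ML tree and the two constrained trees to a
#' region alignment and returns
#' `Delta = d(best, asex) - d(best, sex)` in branch-score distance:
#' negative means the region's best tree resembles the haplotype-separating
#' (asexual) constraint more than the population-separating (sexual) one.
#' Regions with fewer than four unique aligned sequences are untestable
#' (the constrained fits are not identifiable).
#'
#' @param aln named character vector of aligned sequences.
#' @param asex_topo,sex_topo constraint topologies from
#'   [build_constraint_topology()].
#' @return list with `delta`, `untestable`, fitted `best`, `asex`, `sex`
#'   (each tree + log_lik + site_lnl).
#' @export
delta_statistic <- function(aln, asex_topo, sex_topo) {
  if (n_unique_sequences(aln) < 4) {
    return(list(untestable = TRUE, reason = "fewer than four unique sequences",
                delta = NA_real_))
  }
  best <- nni_search(aln)
  fa <- fit_branch_lengths(asex_topo, aln)
  fs <- fit_branch_lengths(sex_topo, aln)
  delta <- branch_score_distance(best$tree, fa$tree) -
    branch_score_distance(best$tree, fs$tree)
  list(untestable = FALSE, delta = delta, best = best, asex = fa, sex = fs)
}

n_unique_sequences <- function(aln) {
  length(unique(toupper(vapply(aln, paste, character(1), collapse = ""))))
}

#' RELL multiscale-bootstrap AU test for a pair of trees
#'
#' Resamples site log-likelihood vectors (no refitting) at bootstrap scales
#' `r`, computes per-scale bootstrap proportions for each tree, and fits the
#' signed-distance / curvature model of the approximately unbiased (AU)
#' test by weighted least squares on the normal-quantile transform:
#' `qnorm(1 - BP_r) ~ d*sqrt(r) + c/sqrt(r)`, giving `p_AU = 1 - pnorm(d - c)`
#' for each tree. Ties in replicate sums count one half to each side. When
#' every informative scale is degenerate (all bootstrap proportions 0 or 1)
#' the p-value collapses to 0/1 and is flagged.
#'
#' @param site_lnl_1,site_lnl_2 per-site log-likelihood vectors of the two
#'   trees (equal length >= 2).
#' @param n_rell bootstrap replicates per scale (default 10000).
#' @param scales bootstrap scale factors (default 0.5..1.4 by 0.1).
#' @param seed optional seed; same seed, same data give identical p-values.
#' @return list with `p1`, `p2` (AU p-values of tree 1 / tree 2),
#'   `untestable` (TRUE when the vectors are identical: no variation to
#'   test), `degenerate`.
#' @export
rell_au_pair <- function(site_lnl_1, site_lnl_2, n_rell = 10000,
                         scales = seq(0.5, 1.4, by = 0.1), seed = NULL) {
  stopifnot(length(site_lnl_1) == length(site_lnl_2), length(site_lnl_1) >= 2)
  if (!is.null(seed)) set.seed(seed)
  d <- site_lnl_1 - site_lnl_2
  # differences at optimizer-tolerance level are numerical noise, not signal
  if (max(abs(d)) < 1e-6) {
    return(list(untestable = TRUE, p1 = NA_real_, p2 = NA_real_, degenerate = FALSE))
  }
  L <- length(d)
  bp1 <- numeric(length(scales))
  for (k in seq_along(scales)) {
    n_k <- max(1L, ceiling(scales[k] * L))
    counts <- stats::rmultinom(n_rell, n_k, rep(1 / L, L))
    sums <- as.numeric(crossprod(counts, d))
    bp1[k] <- mean((sums > 0) + 0.5 * (sums == 0))
  }
  p1 <- au_from_bp(bp1, scales, n_rell)
  p2 <- au_from_bp(1 - bp1, scales, n_rell)
  list(untestable = FALSE, p1 = p1$p, p2 = p2$p,
       degenerate = p1$degenerate || p2$degenerate, bp1 = bp1)
}

au_from_bp <- function(bp, scales, B) {
  usable <- bp > 0 & bp < 1
  if (sum(usable) < 2) {
    # all-or-nothing bootstrap support: p collapses to the majority side
    return(list(p = if (mean(bp) >= 0.5) 1 else 0, degenerate = TRUE))
  }
  s <- scales[usable]
  z <- stats::qnorm(1 - bp[usable])
  w <- B * stats::dnorm(stats::qnorm(bp[usable]))^2 / (bp[usable] * (1 - bp[usable]))
  X <- cbind(sqrt(s), 1 / sqrt(s))
  fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(list(p = if (mean(bp) >= 0.5) 1 else 0, degenerate = TRUE))
  }
  dd <- fit$coefficients[1]; cc <- fit$coefficients[2]
  list(p = as.numeric(1 - stats::pnorm(dd - cc)), degenerate = FALSE)
}

#' AU tests for the unconstrained/asexual/sexual tree triple
#'
#' Runs [rell_au_pair()] for the three pairwise comparisons used to
#' classify a region: asex vs sex, asex vs unconstrained, sex vs
#' unconstrained.
#'
#' @param site_lnl named list with elements `unconstrained`, `asex`, `sex`
#'   (per-site log-likelihood vectors of equal length).
#' @param n_rell,scales,seed passed to [rell_au_pair()].
#' @return list of pairwise results plus the flattened p-values
#'   `p_sex_vs_asex`, `p_asex_vs_sex`, `p_asex_vs_unconstrained`,
#'   `p_sex_vs_unconstrained`, and `untestable`.
#' @export
rell_au_tests <- function(site_lnl, n_rell = 10000,
                          scales = seq(0.5, 1.4, by = 0.1), seed = NULL) {
  stopifnot(all(c("unconstrained", "asex", "sex") %in% names(site_lnl)))
  if (!is.null(seed)) set.seed(seed)
  # one set of bootstrap weights per scale, shared by all three pairwise
  # comparisons: cheaper, and the comparisons see identical replicates
  L <- length(site_lnl$unconstrained)
  lnl_mat <- cbind(unconstrained = site_lnl$unconstrained,
                   asex = site_lnl$asex, sex = site_lnl$sex)
  sums <- lapply(scales, function(s) {
    counts <- stats::rmultinom(n_rell, max(1L, ceiling(s * L)), rep(1 / L, L))
    crossprod(counts, lnl_mat) # n_rell x 3 totals
  })
  pair_from_sums <- function(i, j) {
    d <- lnl_mat[, i] - lnl_mat[, j]
    if (max(abs(d)) < 1e-6) {
      return(list(untestable = TRUE, p1 = NA_real_, p2 = NA_real_, degenerate = FALSE))
    }
    bp1 <- vapply(sums, function(ss) {
      dd <- ss[, i] - ss[, j]
      mean((dd > 0) + 0.5 * (dd == 0))
    }, numeric(1))
    p1 <- au_from_bp(bp1, scales, n_rell)
    p2 <- au_from_bp(1 - bp1, scales, n_rell)
    list(untestable = FALSE, p1 = p1$p, p2 = p2$p,
         degenerate = p1$degenerate || p2$degenerate, bp1 = bp1)
  }
  as_ <- pair_from_sums("asex", "sex")
  au_ <- pair_from_sums("asex", "unconstrained")
  su_ <- pair_from_sums("sex", "unconstrained")
  # a constrained tree indistinguishable from the unconstrained fit cannot
  # be rejected against it
  list(
    asex_sex = as_, asex_unconstrained = au_, sex_unconstrained = su_,
    p_asex_vs_sex = as_$p1, p_sex_vs_asex = as_$p2,
    p_asex_vs_unconstrained = if (au_$untestable) 1 else au_$p1,
    p_sex_vs_unconstrained = if (su_$untestable) 1 else su_$p1,
    untestable = as_$untestable
  )
}

#' Five-way topology-fit category for a region
#'
#' Classification used for the per-region summary, evaluated in fixed
#' order: rejection of the sex-tree with the asex-tree matching the
#' unconstrained fit (`unconst=asex>sex`); rejection of the sex-tree
#' against the asex-tree only (`asex>sex`); the symmetric sex-side
#' categories (`unconst=sex>asex`, `sex>asex`); otherwise `no-difference`.
#' Regions whose site log-likelihood vectors carry no variation are
#' `untestable`.
#'
#' @param au result of [rell_au_tests()].
#' @param alpha significance level (default 0.05).
#' @return one of `"unconst=asex>sex"`, `"asex>sex"`, `"no-difference"`,
#'   `"sex>asex"`, `"unconst=sex>asex"`, `"untestable"`.
#' @export
classify_topology <- function(au, alpha = 0.05) {
  if (isTRUE(au$untestable)) return("untestable")
  p_sex <- au$p_sex_vs_asex
  p_asex <- au$p_asex_vs_sex
  if (!is.na(p_sex) && p_sex < alpha) {
    if (!is.na(au$p_asex_vs_unconstrained) && au$p_asex_vs_unconstrained >= alpha) {
      return("unconst=asex>sex")
    }
    return("asex>sex")
  }
  if (!is.na(p_asex) && p_asex < alpha) {
    if (!is.na(au$p_sex_vs_unconstrained) && au$p_sex_vs_unconstrained >= alpha) {
      return("unconst=sex>asex")
    }
    return("sex>asex")
  }
  "no-difference"
}

#' Full topology test for one region
#'
#' Convenience wrapper: Delta statistic, AU tests and category for one
#' region alignment.
#'
#' @param aln named character vector of aligned sequences.
#' @param asex_topo,sex_topo constraint topologies.
#' @param alpha significance level for classification.
#' @param n_rell RELL replicates.
#' @param seed seed for the RELL resampling stream.
#' @return list with `delta`, `category`, `au`, `fits`.
#' @export
region_topology_test <- function(aln, asex_topo, sex_topo, alpha = 0.05,
                                 n_rell = 10000, seed = NULL) {
  ds <- delta_statistic(aln, asex_topo, sex_topo)
  if (isTRUE(ds$untestable)) {
    return(list(delta = NA_real_, category = "untestable", au = NULL, fits = ds))
  }
  au <- rell_au_tests(
    list(unconstrained = ds$best$site_lnl, asex = ds$asex$site_lnl,
         sex = ds$sex$site_lnl),
    n_rell = n_rell, seed = seed
  )
  list(delta = ds$delta, category = classify_topology(au, alpha), au = au, fits = ds)
}
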