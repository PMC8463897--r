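rand_aln <- function(tree, l, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- evolve_sequences(tree, l)
  ev$tips
}

test_that("JC69 distances follow the closed form and saturate properly", {
  expect_equal(jc69_pairwise_distance("ACGT", "ACGT"), 0)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90)) # p = 0.1
  expect_equal(jc69_pairwise_distance(a, b), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12)
  sat <- paste0(strrep("G", 75), strrep("A", 25))
  expect_warning(d <- jc69_pairwise_distance(a, sat), "saturated")
  expect_identical(d, Inf)
  expect_error(jc69_pairwise_distance("NNN", "ACG"), "usable")
  # masked columns are excluded pairwise
  expect_equal(jc69_pairwise_distance("NACG", "TACG"), 0)
})

test_that("JC69 matrix agrees with the reference distance implementation", {
  set.seed(101)
  tr <- ape::rtree(5)
  tr$edge.length <- tr$edge.length * 0.05
  tips <- rand_aln(tr, 2000)
  mine <- jc69_distance_matrix(tips)
  dna <- ape::as.DNAbin(strsplit(tolower(tips), ""))
  ref <- as.matrix(ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("neighbor joining recovers additive trees exactly", {
  nwk <- "((a:0.1,b:0.2):0.05,c:0.3,d:0.15);"
  tr <- ape::read.tree(text = nwk)
  dm <- ape::cophenetic.phylo(tr)
  est <- nj_tree(dm)
  expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-10)
  # three taxa: unique star with closed-form lengths
  dm3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  est3 <- nj_tree(dm3)
  cp <- ape::cophenetic.phylo(est3)[letters[1:3], letters[1:3]]
  expect_equal(cp, dm3, tolerance = 1e-10)
  expect_error(nj_tree(matrix(c(0, Inf, Inf, 0), 2)), "at least 3")
  dmI <- dm3; dmI[1, 2] <- dmI[2, 1] <- Inf
  expect_error(nj_tree(dmI), "exclude")
  # clamped output never carries negative branch lengths
  set.seed(5)
  noisy <- as.matrix(dist(matrix(rnorm(12), 6)))
  expect_true(all(nj_tree(noisy)$edge.length >= 0))
})

test_that("two-sequence ML branch length equals the JC69 closed form", {
  a <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  av <- strsplit(a, "")[[1]]
  idx <- 1:40
  bv <- av
  bv[idx] <- c("A", "C", "G", "T")[(match(av[idx], c("A", "C", "G", "T")) %% 4) + 1]
  aln <- c(x = a, y = paste(bv, collapse = ""))
  topo <- ape::read.tree(text = "(x:0.05,y:0.05);")
  fit <- fit_branch_lengths(topo, aln)
  expect_equal(sum(fit$tree$edge.length), jc69_pairwise_distance(aln[1], aln[2]),
               tolerance = 1e-6)
  # per-site log-likelihoods sum to the total
  expect_equal(sum(fit$site_lnl), fit$log_lik, tolerance = 1e-6)
})

test_that("an invariant alignment fits to zero branch lengths", {
  aln <- stats::setNames(rep(strrep("A", 120), 4), letters[1:4])
  topo <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  fit <- fit_branch_lengths(topo, aln)
  expect_lt(max(fit$tree$edge.length), 1e-4)
  expect_equal(fit$log_lik, 120 * log(1 / 4), tolerance = 1e-3)
})

test_that("branch lengths are recovered from long simulated alignments", {
  set.seed(71)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.12)
  aln <- rand_aln(tr, 10000)
  fit <- fit_branch_lengths(tr, aln)
  expect_equal(sum(fit$tree$edge.length), sum(tr$edge.length), tolerance = 0.1)
  # per-edge comparison via shared bipartitions (same topology)
  expect_lt(branch_score_distance(fit$tree, tr), 0.05)
})

test_that("NNI search recovers strong-signal topologies", {
  set.seed(83)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.15)
  aln <- rand_aln(tr, 3000)
  best <- nni_search(aln)
  expect_equal(ape::dist.topo(best$tree, tr), 0, ignore_attr = TRUE)
  # matches exhaustive search over the three quartet topologies
  tq <- ape::read.tree(text = "((a:0.08,b:0.08):0.04,(c:0.08,d:0.08):0.04);")
  alnq <- rand_aln(tq, 2000)
  topos <- list(
    ape::read.tree(text = "(a:0.1,b:0.1,(c:0.1,d:0.1):0.1);"),
    ape::read.tree(text = "(a:0.1,c:0.1,(b:0.1,d:0.1):0.1);"),
    ape::read.tree(text = "(a:0.1,d:0.1,(b:0.1,c:0.1):0.1);")
  )
  lnls <- vapply(topos, function(t) fit_branch_lengths(t, alnq)$log_lik, numeric(1))
  best_q <- nni_search(alnq)
  expect_equal(best_q$log_lik, max(lnls), tolerance = 1e-4)
})

test_that("constraint templates encode the asexual and sexual hypotheses", {
  md <- data.frame(
    individual = c("H1", "H2", "SA1", "SA3", "H3", "KF1", "KF2"),
    population = c("H", "H", "SA", "SA", "H", "KF", "KF"),
    lineage = c("I", "I", "I", "I", "II", "II", "II")
  )
  at <- build_constraint_topology("asex", md$individual, md, "two-lineage")
  # the deepest split separates all _A from all _B
  sep <- is_haplotype_separating(at)
  expect_true(sep$separating)
  st <- build_constraint_topology("sex", md$individual, md, "two-lineage")
  expect_false(is_haplotype_separating(st)$separating)
  expect_setequal(at$tip.label, st$tip.label)
  # two populations only: sex tree is the single population bipartition
  md2 <- data.frame(individual = c("a", "b", "c", "d"),
                    population = c("P1", "P1", "P2", "P2"),
                    lineage = NA_character_)
  st2 <- build_constraint_topology("sex", md2$individual, md2, "single-species")
  expect_equal(ape::Ntip(st2), 8)
  expect_false(is_haplotype_separating(st2)$separating)
  # single-species asex with the most divergent population's B split off
  at2 <- build_constraint_topology("asex", md2$individual, md2, "single-species",
                                   most_divergent_population = "P2")
  expect_equal(ape::Ntip(at2), 8)
  md$lineage <- NA_character_
  expect_error(build_constraint_topology("asex", md$individual, md, "two-lineage"),
               "lineage")
})

test_that("branch-score distance follows the bipartition-union definition", {
  t1 <- ape::read.tree(text = "(a:0.1,b:0.1,(c:0.1,d:0.1):0.1);")
  expect_equal(branch_score_distance(t1, t1), 0)
  t2 <- ape::read.tree(text = "(a:0.1,b:0.1,(c:0.1,d:0.1):0.2);")
  expect_equal(branch_score_distance(t1, t2), 0.1, tolerance = 1e-10)
  t3 <- ape::read.tree(text = "(a:0.1,c:0.1,(b:0.1,d:0.1):0.1);")
  expect_equal(branch_score_distance(t1, t3), sqrt(0.02), tolerance = 1e-10)
  expect_error(branch_score_distance(t1, ape::rtree(5)), "leaf set")
})

test_that("branch-score distance is a pseudometric on random trees", {
  set.seed(59)
  for (r in 1:10) {
    ts <- lapply(1:3, function(i) {
      t <- ape::rtree(7)
      t$tip.label <- paste0("t", 1:7)
      t
    })
    d12 <- branch_score_distance(ts[[1]], ts[[2]])
    d21 <- branch_score_distance(ts[[2]], ts[[1]])
    d13 <- branch_score_distance(ts[[1]], ts[[3]])
    d23 <- branch_score_distance(ts[[2]], ts[[3]])
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_gte(d12, 0)
    expect_lte(d13, d12 + d23 + 1e-12)
    expect_equal(branch_score_distance(ts[[1]], ts[[1]]), 0)
  }
})

test_that("regions with fewer than four unique sequences are untestable", {
  md <- data.frame(individual = c("x", "y"), population = c("P", "P"),
                   lineage = NA_character_)
  at <- build_constraint_topology("asex", md$individual, md, "single-species")
  st <- build_constraint_topology("sex", md$individual, md, "single-species")
  s <- strrep("A", 100)
  aln <- stats::setNames(c(s, s, s, s), c("x_A", "x_B", "y_A", "y_B"))
  res <- delta_statistic(aln, at, st)
  expect_true(res$untestable)
})

test_that("Delta is negative when the best tree equals the asexual constraint", {
  md <- data.frame(
    individual = c("H1", "H2", "KF1", "KF2"),
    population = c("H", "H", "KF", "KF"),
    lineage = c("I", "I", "II", "II")
  )
  at <- build_constraint_topology("asex", md$individual, md, "two-lineage")
  st <- build_constraint_topology("sex", md$individual, md, "two-lineage")
  truth <- ape::multi2di(at, random = FALSE)
  truth$edge.length <- rep(0.02, nrow(truth$edge))
  set.seed(61)
  aln <- rand_aln(truth, 2000)
  res <- delta_statistic(aln, at, st)
  expect_false(res$untestable)
  expect_lt(res$delta, 0)
})

test_that("Delta recovers the generating regime on simulated regions", {
  md <- data.frame(
    individual = c("H1", "H2", "KF1"),
    population = c("H", "H", "KF"),
    lineage = NA_character_
  )
  at <- build_constraint_topology("asex", md$individual, md, "single-species")
  st <- build_constraint_topology("sex", md$individual, md, "single-species")
  # asexual-style genealogy: deep haplotype split, shallow population splits
  asex_truth <- ape::read.tree(text = paste0(
    "(((H1_A:0.004,H2_A:0.004):0.004,KF1_A:0.008):0.012,",
    "((H1_B:0.004,H2_B:0.004):0.004,KF1_B:0.008):0.012);"
  ))
  # sexual-style genealogy: haplotypes follow populations
  sex_truth <- ape::read.tree(text = paste0(
    "(((H1_A:0.002,H1_B:0.002):0.002,(H2_A:0.002,H2_B:0.002):0.002):0.006,",
    "(KF1_A:0.004,KF1_B:0.004):0.006);"
  ))
  set.seed(67)
  n <- 30
  d_asex <- vapply(seq_len(n), function(i) {
    delta_statistic(rand_aln(asex_truth, 600), at, st)$delta
  }, numeric(1))
  d_sex <- vapply(seq_len(n), function(i) {
    delta_statistic(rand_aln(sex_truth, 600), at, st)$delta
  }, numeric(1))
  expect_gt(mean(d_asex < 0, na.rm = TRUE), 0.8)
  expect_gt(mean(d_sex > 0, na.rm = TRUE), 0.8)
})

test_that("RELL AU tests refuse identical fits and are seed-reproducible", {
  l1 <- rnorm(200, -3)
  res <- rell_au_pair(l1, l1 + 1e-9, n_rell = 500, seed = 1)
  expect_true(res$untestable)
  # a uniformly dominating tree drives the loser's p toward zero
  l2 <- l1 - 0.08
  res <- rell_au_pair(l1, l2, n_rell = 2000, seed = 2)
  expect_lt(res$p2, 0.01)
  expect_gt(res$p1, 0.5)
  res_b <- rell_au_pair(l1, l2, n_rell = 2000, seed = 2)
  expect_identical(res$p1, res_b$p1)
  expect_identical(res$p2, res_b$p2)
})

test_that("topology categories follow the published decision order", {
  mk <- function(psa, pas, pau, psu, unt = FALSE) {
    list(untestable = unt, p_sex_vs_asex = psa, p_asex_vs_sex = pas,
         p_asex_vs_unconstrained = pau, p_sex_vs_unconstrained = psu)
  }
  expect_equal(classify_topology(mk(0.01, 0.9, 0.5, 0.5)), "unconst=asex>sex")
  expect_equal(classify_topology(mk(0.01, 0.9, 0.01, 0.5)), "asex>sex")
  expect_equal(classify_topology(mk(0.5, 0.5, 0.5, 0.5)), "no-difference")
  expect_equal(classify_topology(mk(0.9, 0.01, 0.01, 0.01)), "sex>asex")
  expect_equal(classify_topology(mk(0.9, 0.01, 0.01, 0.5)), "unconst=sex>asex")
  expect_equal(classify_topology(mk(0.5, 0.5, 0.5, 0.5, unt = TRUE)), "untestable")
})
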