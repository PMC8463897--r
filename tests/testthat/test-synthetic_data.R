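test_that("configuration validation enforces time ordering and probabilities", {
  expect_error(sim_config("asexual", T_pop = 0.01, T_lin = 0.001), "T_hap >= T_lin")
  expect_error(sim_config("asexual", loh_rate = 1.5), "loh_rate")
  expect_error(sim_config("asexual", region_length_bp = 50), "region_length")
  cfg <- sim_config("asexual")
  expect_s3_class(cfg, "sim_config")
  expect_equal(length(cfg$individuals), 9)
})

test_that("clonal genealogies separate haplotypes; sexual ones rarely do", {
  cfg <- oppiella_like_config("asexual", n_regions = 1, seed = 1)
  expect_true(is_haplotype_separating(simulate_genealogy(cfg))$separating)
  cfg_s <- oppiella_like_config("sexual", n_regions = 1, seed = 1)
  set.seed(2)
  sep <- vapply(1:25, function(i) {
    is_haplotype_separating(simulate_genealogy(cfg_s))$separating
  }, logical(1))
  expect_lt(mean(sep), 0.2)
})

test_that("sequence evolution follows JC69 expectations and is seed-stable", {
  tr <- ape::read.tree(text = "(a:0,b:0.02);")
  set.seed(3)
  ev <- evolve_sequences(tr, 20000)
  # zero branch: child equals root
  expect_equal(ev$tips[["a"]], ev$root)
  p_exp <- 0.75 * (1 - exp(-4 * 0.02 / 3))
  p_obs <- mean(strsplit(ev$tips[["a"]], "")[[1]] != strsplit(ev$tips[["b"]], "")[[1]])
  se <- sqrt(p_exp * (1 - p_exp) / 20000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
  set.seed(9); e1 <- evolve_sequences(tr, 500)
  set.seed(9); e2 <- evolve_sequences(tr, 500)
  expect_identical(e1$tips, e2$tips)
})

test_that("homogenization tracts remove heterozygosity at the configured rate", {
  set.seed(13)
  L <- 40000
  a <- paste(sample(c("A", "C"), L, TRUE), collapse = "")
  b <- paste(sample(c("G", "T"), L, TRUE), collapse = "")
  # rate 0: identity
  same <- apply_loh(a, b, rate = 0)
  expect_identical(same$hap_a, a)
  expect_identical(same$hap_b, b)
  # saturation: heterozygosity nearly gone
  sat <- apply_loh(a, b, rate = 0.99, tract_mean = 500)
  expect_lt(sat$het_after / sat$het_before, 0.08)
  # intermediate rate: realized loss close to the per-site probability
  mid <- apply_loh(a, b, rate = 0.4, tract_mean = 400)
  expect_lt(abs(1 - mid$het_after / mid$het_before - 0.4), 0.08)
})

test_that("emitted genotypes are consistent with the truth haplotypes", {
  sim <- simulate_dataset(oppiella_like_config("asexual", n_regions = 4, seed = 21))
  for (nm in names(sim$truth$regions)) {
    tr <- sim$truth$regions[[nm]]
    ref <- strsplit(sim$reference[[nm]], "")[[1]]
    idx <- which(sim$gm$sites$scaffold == nm)
    for (ind in sim$metadata$individual) {
      a <- strsplit(tr$haplotypes[[ind]][["A"]], "")[[1]]
      b <- strsplit(tr$haplotypes[[ind]][["B"]], "")[[1]]
      expect_equal(unname(sim$gm$calls[idx, ind]),
                   as.integer(a != ref) + as.integer(b != ref))
    }
  }
})

test_that("paralogous regions double coverage and are flagged by the screen", {
  sim <- simulate_dataset(oppiella_like_config("asexual", n_regions = 25, seed = 31,
                                               paralog_fraction = 0.2,
                                               phase_dropout = 0))
  truth_flags <- vapply(sim$truth$regions, `[[`, logical(1), "paralog")
  expect_gt(sum(truth_flags), 0)
  regions <- build_regions(sim$blocks)
  for (rg in regions) {
    rg <- paralog_flag(rg, sim$genome_coverage, sim$baseline_median)
    expect_equal(rg$paralog$flag, truth_flags[[rg$scaffold]])
  }
})

test_that("clonal heterozygosity tracks twice the haplotype split time", {
  cfg <- oppiella_like_config("asexual", n_regions = 20, seed = 41,
                              loh_rate = 0, loh_rate_high = 0,
                              low_coverage_rate = 0, paralog_fraction = 0)
  sim <- simulate_dataset(cfg)
  het <- individual_heterozygosity(
    filter_sites(sim$gm, drop_monomorphic = FALSE)
  )
  p_exp <- 0.75 * (1 - exp(-4 * 2 * cfg$T_hap / 3))
  n_tot <- sum(het$n_sites_used)
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  # reference individual's A haplotype is the reference: its het unaffected
  expect_lt(abs(mean(het$pct_het) / 100 - p_exp), 3 * se + 2e-4)
})

test_that("identical seeds give bit-identical datasets", {
  s1 <- simulate_dataset(oppiella_like_config("asexual", n_regions = 3, seed = 99))
  s2 <- simulate_dataset(oppiella_like_config("asexual", n_regions = 3, seed = 99))
  expect_identical(s1$gm$calls, s2$gm$calls)
  expect_identical(s1$gm$depth, s2$gm$depth)
  expect_identical(s1$blocks, s2$blocks)
  expect_identical(s1$reference, s2$reference)
  s3 <- simulate_dataset(oppiella_like_config("asexual", n_regions = 3, seed = 100))
  expect_false(identical(s1$gm$calls, s3$gm$calls))
})

test_that("sexual datasets carry near-zero inbreeding coefficients", {
  sim <- simulate_dataset(oppiella_like_config("sexual", n_regions = 60, seed = 51))
  gmf <- filter_sites(sim$gm, drop_monomorphic = FALSE)
  fis <- fis_table(gmf, sim$metadata, level = "population")
  expect_lt(abs(mean(fis$fis, na.rm = TRUE)), 0.05)
})

test_that("a dataset round-trips through standard file formats", {
  sim <- simulate_dataset(oppiella_like_config("asexual", n_regions = 3, seed = 61))
  dir <- tempfile()
  write_dataset(sim, dir)
  gm <- read_genotypes(file.path(dir, "genotypes.vcf.gz"))
  expect_equal(unname(gm$calls), unname(sim$gm$calls))
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$individual, sim$metadata$individual)
  blocks <- read_phase_blocks(file.path(dir, "blocks"))
  expect_equal(nrow(blocks), nrow(sim$blocks))
  ref <- read_fasta(file.path(dir, "reference.fa"))
  expect_equal(unname(nchar(ref)), rep(sim$config$region_length_bp, 3))
})
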