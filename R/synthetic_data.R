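#' Simulation configuration for clonal / sexual datasets
#'
#' Parameters of the synthetic-data generator. All divergence times are in
#' expected substitutions per site (no calendar dating is attempted, since
#' per-generation mutation rates for the organisms emulated here are
#' unknown). In `asexual` mode the per-region genealogy separates the two
#' haplotypes at its base (depth `T_hap`), then lineages (`T_lin`),
#' populations (`T_pop`) and individuals (`T_tip`), identically in both
#' haplotype clades — parallel divergence by construction. In `sexual` mode
#' populations split at `T_pop` (the most divergent population at `T_lin`)
#' and the two allele copies of each individual coalesce within its
#' population by a Kingman process with mean pairwise coalescent time
#' `coal_scale` (alleles paired into individuals at random, so genotypes are
#' in Hardy-Weinberg proportions within populations).
#'
#' @param mode `"asexual"` or `"sexual"`.
#' @param populations population labels.
#' @param individuals_per_population individuals sampled per population.
#' @param lineages named list mapping lineage labels to individual ids
#'   (asexual mode); individuals in no lineage are treated as divergent
#'   singletons.
#' @param high_loh_individuals individuals subject to the elevated
#'   loss-of-heterozygosity rate (emulating near-homozygous clonal
#'   sublineages).
#' @param T_hap,T_lin,T_pop,T_tip divergence times (substitutions/site);
#'   must be non-increasing in that order.
#' @param coal_scale sexual mode: mean within-population pairwise coalescent
#'   time (half the expected within-individual heterozygosity).
#' @param n_regions number of independent regions (transcript-like loci).
#' @param region_length_bp region length (>= 100).
#' @param loh_rate expected fraction of sites covered by homogenizing
#'   (gene-conversion-like) tracts per haplotype pair.
#' @param loh_rate_high same, for `high_loh_individuals`.
#' @param loh_tract_mean_bp mean homogenizing tract length.
#' @param coverage_mean mean per-genotype read depth (RNA coverage).
#' @param low_coverage_rate probability a genotype's depth is drawn from a
#'   low-coverage component (mean 5) instead, exercising the depth filter.
#' @param genome_coverage_mean mean genomic read coverage used by the
#'   paralog screen; paralogous regions double it.
#' @param paralog_fraction fraction of regions emitted at doubled coverage.
#' @param phase_block_mean_bp mean phase-block length.
#' @param phase_dropout probability an individual contributes no phase
#'   block in a region.
#' @param reference_individual individual whose (post-homogenization) A
#'   haplotype serves as the reference sequence, emulating a reference
#'   genome assembled from a single individual; default the first
#'   individual. With a single-haplotype reference, every individual's
#'   closer haplotype belongs to the same clade, so per-region A/B labels
#'   are mutually consistent.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(mode = c("asexual", "sexual"),
                       populations = c("H", "KF", "SA"),
                       individuals_per_population = 3,
                       lineages = NULL,
                       high_loh_individuals = character(0),
                       T_hap = 0.0065, T_lin = 0.003, T_pop = 0.0022,
                       T_tip = 6e-4, coal_scale = 0.00325,
                       n_regions = 40, region_length_bp = 600,
                       loh_rate = 0.05, loh_rate_high = 0.7,
                       loh_tract_mean_bp = 300,
                       coverage_mean = 60, low_coverage_rate = 0.02,
                       genome_coverage_mean = 126, paralog_fraction = 0.05,
                       phase_block_mean_bp = 550, phase_dropout = 0.1,
                       reference_individual = NULL, seed = 1) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  stopifnot(
    region_length_bp >= 100, n_regions >= 1,
    all(c(T_hap, T_lin, T_pop, T_tip, coal_scale) >= 0, na.rm = TRUE),
    loh_rate >= 0, loh_rate <= 1, loh_rate_high >= 0, loh_rate_high <= 1,
    paralog_fraction >= 0, paralog_fraction <= 1,
    phase_dropout >= 0, phase_dropout <= 1,
    low_coverage_rate >= 0, low_coverage_rate <= 1
  )
  if (mode == "asexual") {
    if (!(T_hap >= T_lin && T_lin >= T_pop && T_pop >= T_tip)) {
      stop("divergence times must satisfy T_hap >= T_lin >= T_pop >= T_tip")
    }
  } else {
    if (!(T_lin >= T_pop)) stop("T_lin (deepest population split) must be >= T_pop")
  }
  cfg$individuals <- unlist(lapply(populations, function(p) {
    paste0(p, seq_len(individuals_per_population))
  }))
  if (is.null(cfg$reference_individual)) cfg$reference_individual <- cfg$individuals[1]
  stopifnot(cfg$reference_individual %in% cfg$individuals)
  structure(cfg, class = "sim_config")
}

#' Preset emulating the study structure of a clonal oribatid-mite dataset
#'
#' Nine individuals in three populations (H, KF, SA). The asexual preset
#' carries two divergent lineages (I: H1, H2, SA1, SA3; II: H3, KF1, KF2)
#' plus two near-homozygous singletons (KF3, SA2) with a high
#' loss-of-heterozygosity rate; haplotype divergence targets roughly 1%
#' heterozygous sites. The sexual preset targets roughly 0.65%
#' heterozygosity within populations that are clearly differentiated from
#' each other (SA the most divergent).
#'
#' @param mode `"asexual"` or `"sexual"`.
#' @param n_regions,seed passed through.
#' @param ... overrides for any [sim_config()] field.
#' @return a [sim_config()].
#' @export
oppiella_like_config <- function(mode = c("asexual", "sexual"), n_regions = 150,
                                 seed = 1, ...) {
  mode <- match.arg(mode)
  base <- if (mode == "asexual") {
    list(
      mode = "asexual",
      lineages = list(I = c("H1", "H2", "SA1", "SA3"), II = c("H3", "KF1", "KF2")),
      high_loh_individuals = c("KF3", "SA2"),
      T_hap = 0.0065, T_lin = 0.003, T_pop = 0.0022, T_tip = 6e-4
    )
  } else {
    list(
      mode = "sexual",
      lineages = NULL, high_loh_individuals = character(0),
      T_hap = NA_real_, T_lin = 0.007, T_pop = 0.004, T_tip = NA_real_,
      coal_scale = 0.00325, loh_rate = 0
    )
  }
  args <- utils::modifyList(c(base, list(n_regions = n_regions, seed = seed)),
                            list(...))
  do.call(sim_config, args)
}

#' Simulate the true genealogy of one region
#'
#' Asexual mode is deterministic (clonal genomes share one genealogy across
#' regions): the root splits haplotype clades A and B at depth `T_hap`;
#' within each clade, lineages split at `T_lin` (divergent singletons
#' joining the same polytomy), populations at `T_pop`, individuals at
#' `T_tip`; both clades have identical shape. Sexual mode draws a fresh
#' within-population Kingman coalescent per region (compressed, if needed,
#' to finish before the population split) and joins populations at
#' `T_pop` / `T_lin` (last population listed = most divergent).
#'
#' @param config a [sim_config()].
#' @return an `ape::phylo` with tips `<individual>_A` / `<individual>_B`.
#' @export
simulate_genealogy <- function(config) {
  if (config$mode == "asexual") asex_genealogy(config) else sex_genealogy(config)
}

asex_genealogy <- function(cfg) {
  md <- sim_metadata(cfg)
  clade <- function(suffix) {
    groups <- split(md$individual, ifelse(is.na(md$lineage),
                                          paste0("singleton_", md$individual),
                                          md$lineage))
    gstr <- vapply(groups, function(ids) {
      if (length(ids) == 1) {
        return(sprintf("%s_%s:%g", ids, suffix, cfg$T_lin))
      }
      by_pop <- split(ids, md$population[match(ids, md$individual)])
      pstr <- vapply(by_pop, function(x) {
        if (length(x) == 1) {
          sprintf("%s_%s:%g", x, suffix, cfg$T_pop)
        } else {
          inner <- paste(sprintf("%s_%s:%g", x, suffix, cfg$T_tip), collapse = ",")
          sprintf("(%s):%g", inner, cfg$T_pop - cfg$T_tip)
        }
      }, character(1))
      sprintf("(%s):%g", paste(pstr, collapse = ","), cfg$T_lin - cfg$T_pop)
    }, character(1))
    sprintf("(%s):%g", paste(gstr, collapse = ","), cfg$T_hap - cfg$T_lin)
  }
  ape::read.tree(text = paste0("(", clade("A"), ",", clade("B"), ");"))
}

# Kingman coalescent on the 2n allele copies of one population, mean
# pairwise coalescent time = scale, compressed to finish by 0.9 * limit.
kingman_newick <- function(tip_labels, scale, limit) {
  k <- length(tip_labels)
  if (k == 1) return(list(nwk = tip_labels, height = 0))
  nodes <- as.list(tip_labels)
  heights <- rep(0, k)
  t <- 0
  while (length(nodes) > 1) {
    kk <- length(nodes)
    t <- t + stats::rexp(1, rate = choose(kk, 2) / scale)
    pair <- sample(kk, 2)
    nwk <- sprintf("(%s:%g,%s:%g)", nodes[[pair[1]]], t - heights[pair[1]],
                   nodes[[pair[2]]], t - heights[pair[2]])
    nodes <- c(nodes[-pair], nwk)
    heights <- c(heights[-pair], t)
  }
  if (t > 0.9 * limit) {
    # rescale node times so the subtree finishes below the population split
    tr <- ape::read.tree(text = paste0(nodes[[1]], ";"))
    tr$edge.length <- tr$edge.length * (0.9 * limit / t)
    str <- ape::write.tree(tr)
    return(list(nwk = sub(";$", "", str), height = 0.9 * limit))
  }
  list(nwk = nodes[[1]], height = t)
}

sex_genealogy <- function(cfg) {
  md <- sim_metadata(cfg)
  pops <- cfg$populations
  sub <- lapply(pops, function(p) {
    ids <- md$individual[md$population == p]
    labs <- sample(c(paste0(ids, "_A"), paste0(ids, "_B"))) # random allele pairing
    kingman_newick(labs, cfg$coal_scale, cfg$T_pop)
  })
  names(sub) <- pops
  stem <- function(p, depth) sprintf("%s:%g", sub[[p]]$nwk, depth - sub[[p]]$height)
  if (length(pops) == 2) {
    nwk <- sprintf("(%s,%s);", stem(pops[1], cfg$T_pop), stem(pops[2], cfg$T_pop))
  } else {
    divergent <- pops[length(pops)]
    rest <- pops[-length(pops)]
    inner <- paste(vapply(rest, stem, character(1), depth = cfg$T_pop), collapse = ",")
    nwk <- sprintf("((%s):%g,%s);", inner, cfg$T_lin - cfg$T_pop,
                   stem(divergent, cfg$T_lin))
  }
  ape::read.tree(text = nwk)
}

sim_metadata <- function(cfg) {
  lin <- rep(NA_character_, length(cfg$individuals))
  if (!is.null(cfg$lineages)) {
    for (l in names(cfg$lineages)) lin[cfg$individuals %in% cfg$lineages[[l]]] <- l
  }
  data.frame(
    individual = cfg$individuals,
    population = rep(cfg$populations, each = cfg$individuals_per_population),
    lineage = lin,
    stringsAsFactors = FALSE
  )
}

#' Evolve sequences along a genealogy under JC69
#'
#' Root sequence uniform over A/C/G/T (or given), substitutions per branch
#' under the Jukes-Cantor model with independent sites.
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param length_bp sequence length.
#' @param rootseq optional root sequence (character vector of bases).
#' @return list with `tips` (named character vector of sequences) and
#'   `root` (root sequence string).
#' @export
evolve_sequences <- function(tree, length_bp, rootseq = NULL) {
  if (is.null(rootseq)) rootseq <- sample(c("a", "c", "g", "t"), length_bp, replace = TRUE)
  rootseq <- tolower(rootseq)
  dat <- phangorn::simSeq(tree, l = length_bp, rootseq = rootseq, type = "DNA")
  m <- toupper(as.character(dat))
  tips <- apply(m, 1, paste, collapse = "")
  list(tips = tips[tree$tip.label], root = toupper(paste(rootseq, collapse = "")))
}

#' Apply loss-of-heterozygosity tracts to a haplotype pair
#'
#' Phenomenological model of gene conversion and other homogenizing
#' mechanisms: geometric-length tracts seeded uniformly, each overwriting
#' one haplotype with the other (donor chosen at random per tract). `rate`
#' is the per-site probability of being covered by at least one tract;
#' because tracts land as a Poisson coverage process, the tract intensity
#' used internally is `-log(1 - rate)`.
#'
#' @param hap_a,hap_b equal-length haplotype strings.
#' @param rate per-site homogenization probability in \[0, 1).
#' @param tract_mean mean tract length in bp.
#' @return list with `hap_a`, `hap_b`, `n_tracts`, `het_before`, `het_after`.
#' @export
apply_loh <- function(hap_a, hap_b, rate, tract_mean = 300) {
  stopifnot(rate >= 0, rate < 1)
  a <- strsplit(toupper(hap_a), "")[[1]]
  b <- strsplit(toupper(hap_b), "")[[1]]
  stopifnot(length(a) == length(b))
  L <- length(a)
  het_before <- sum(a != b)
  intensity <- -log1p(-rate)
  n_tracts <- if (rate > 0) stats::rpois(1, intensity * L / tract_mean) else 0L
  for (i in seq_len(n_tracts)) {
    len <- stats::rgeom(1, 1 / tract_mean) + 1L
    start <- sample.int(L, 1)
    idx <- start:min(L, start + len - 1L)
    if (stats::runif(1) < 0.5) a[idx] <- b[idx] else b[idx] <- a[idx]
  }
  list(hap_a = paste(a, collapse = ""), hap_b = paste(b, collapse = ""),
       n_tracts = n_tracts, het_before = het_before, het_after = sum(a != b))
}

#' Simulate a full multi-individual dataset with known truth
#'
#' Generates, per region: the true genealogy, haplotype sequences (after
#' loss-of-heterozygosity), an all-sites genotype matrix with simulated
#' depths (reference = the region's root sequence), per-individual phase
#' blocks with random within-block orientation and dropout, per-individual
#' RNA coverage tracks, a genomic read-coverage track (doubled in
#' paralogous regions), and sample metadata. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return object of class `meselson_sim`: `config`, `metadata`, `gm`
#'   (genotype matrix), `blocks`, `coverage` (per-individual tracks),
#'   `genome_coverage`, `baseline_median`, `reference` (named scaffold
#'   sequences) and `truth` (per-region genealogies, haplotypes, paralog
#'   flags).
#' @export
simulate_dataset <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  md <- sim_metadata(cfg)
  inds <- md$individual
  n_ind <- length(inds)

  region_names <- sprintf("region_%03d", seq_len(cfg$n_regions))
  paralog <- stats::runif(cfg$n_regions) < cfg$paralog_fraction

  sites_l <- list(); calls_l <- list(); depth_l <- list()
  blocks_l <- list(); cov_runs <- stats::setNames(vector("list", n_ind), inds)
  gcov_l <- list(); reference <- character(0)
  truth <- list(regions = list())

  loh_of <- function(id) {
    if (id %in% cfg$high_loh_individuals) cfg$loh_rate_high else cfg$loh_rate
  }

  for (r in seq_len(cfg$n_regions)) {
    nm <- region_names[r]
    L <- cfg$region_length_bp
    tree <- simulate_genealogy(cfg)
    ev <- evolve_sequences(tree, L)
    haps <- lapply(inds, function(id) {
      pair <- apply_loh(ev$tips[paste0(id, "_A")], ev$tips[paste0(id, "_B")],
                        rate = loh_of(id), tract_mean = cfg$loh_tract_mean_bp)
      c(A = pair$hap_a, B = pair$hap_b)
    })
    names(haps) <- inds
    ref <- haps[[cfg$reference_individual]][["A"]]

    ref_v <- strsplit(ref, "")[[1]]
    hapm_a <- do.call(cbind, lapply(haps, function(h) strsplit(h[["A"]], "")[[1]]))
    hapm_b <- do.call(cbind, lapply(haps, function(h) strsplit(h[["B"]], "")[[1]]))
    dosage <- (hapm_a != ref_v) + (hapm_b != ref_v)
    alt <- vapply(seq_len(L), function(i) {
      nr <- unique(c(hapm_a[i, ], hapm_b[i, ]))
      nr <- sort(setdiff(nr, ref_v[i]))
      if (length(nr)) paste(nr, collapse = ",") else NA_character_
    }, character(1))
    n_alleles <- 1L + ifelse(is.na(alt), 0L, nchar(gsub("[^,]", "", alt)) + 1L)

    lam <- cfg$coverage_mean * (if (paralog[r]) 2 else 1)
    low <- matrix(stats::runif(L * n_ind) < cfg$low_coverage_rate, L, n_ind)
    depth <- matrix(stats::rpois(L * n_ind, lam), L, n_ind)
    depth[low] <- stats::rpois(sum(low), 5)

    sites_l[[r]] <- data.frame(
      scaffold = nm, pos = 0:(L - 1L), ref = ref_v, alt = alt,
      is_indel = FALSE, n_alleles = n_alleles, stringsAsFactors = FALSE
    )
    calls_l[[r]] <- dosage
    depth_l[[r]] <- depth

    # phase blocks: one block per individual per region, with dropout and
    # random within-block haplotype orientation (the phaser knows no A/B)
    for (i in seq_len(n_ind)) {
      if (stats::runif(1) < cfg$phase_dropout) next
      len <- min(L, max(100L, round(stats::rexp(1, 1 / cfg$phase_block_mean_bp))))
      start <- sample.int(L - len + 1L, 1) - 1L
      h <- haps[[inds[i]]]
      sub <- substring(h, start + 1L, start + len)
      flip <- stats::runif(1) < 0.5
      blocks_l[[length(blocks_l) + 1L]] <- data.frame(
        individual = inds[i], scaffold = nm, start = start, end = start + len,
        hap1 = if (flip) sub[2] else sub[1],
        hap2 = if (flip) sub[1] else sub[2],
        truth_hap1 = if (flip) "B" else "A",
        stringsAsFactors = FALSE
      )
    }

    for (i in seq_len(n_ind)) {
      cov_runs[[inds[i]]][[length(cov_runs[[inds[i]]]) + 1L]] <-
        rle_track(nm, depth[, i])
    }
    gdepth <- stats::rpois(L, cfg$genome_coverage_mean * (if (paralog[r]) 2 else 1))
    gcov_l[[r]] <- rle_track(nm, gdepth)

    reference[nm] <- ref
    truth$regions[[nm]] <- list(
      genealogy = ape::write.tree(tree), haplotypes = haps, paralog = paralog[r]
    )
  }

  gm <- genotype_matrix(
    sites = do.call(rbind, sites_l),
    individuals = inds,
    calls = do.call(rbind, calls_l),
    depth = do.call(rbind, depth_l)
  )
  blocks_df <- do.call(rbind, blocks_l)
  truth$block_orientation <- blocks_df$truth_hap1
  blocks <- phase_blocks(blocks_df$individual, blocks_df$scaffold,
                         blocks_df$start, blocks_df$end,
                         blocks_df$hap1, blocks_df$hap2)

  coverage <- lapply(cov_runs, function(runs) {
    ct <- do.call(rbind, runs)
    class(ct) <- c("coverage_track", "data.frame")
    ct
  })
  genome_coverage <- do.call(rbind, gcov_l)
  class(genome_coverage) <- c("coverage_track", "data.frame")

  structure(
    list(config = cfg, metadata = md, gm = gm, blocks = blocks,
         coverage = coverage, genome_coverage = genome_coverage,
         baseline_median = cfg$genome_coverage_mean,
         reference = reference, truth = truth),
    class = "meselson_sim"
  )
}

rle_track <- function(scaffold, depth) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  coverage_track(scaffold, ends - r$lengths, ends, r$values)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits `genotypes.vcf.gz`, `metadata.tsv`, `blocks/` (per-individual
#' BED + FASTA), `coverage/` (per-individual bedGraph),
#' `genome_coverage.bedGraph`, `reference.fa` and `truth/`
#' (genealogies as Newick, per-region paralog flags as TSV).
#'
#' @param sim a `meselson_sim` from [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$gm, file.path(dir, "genotypes.vcf.gz"))
  write_sample_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_phase_blocks(sim$blocks, file.path(dir, "blocks"))
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  for (ind in names(sim$coverage)) {
    write_coverage(sim$coverage[[ind]],
                   file.path(dir, "coverage", paste0(ind, ".bedGraph")))
  }
  write_coverage(sim$genome_coverage, file.path(dir, "genome_coverage.bedGraph"))
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  writeLines(
    vapply(sim$truth$regions, `[[`, character(1), "genealogy"),
    file.path(dir, "truth", "genealogies.nwk")
  )
  utils::write.table(
    data.frame(region = names(sim$truth$regions),
               paralog = vapply(sim$truth$regions, `[[`, logical(1), "paralog")),
    file.path(dir, "truth", "regions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
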