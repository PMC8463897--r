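mkseq <- function(n, base = "A") strrep(base, n)

test_that("regions chain blocks by cross-individual overlap of >= 100 bp", {
  b <- phase_blocks(
    individual = c("i1", "i2"), scaffold = "s1",
    start = c(100, 250), end = c(400, 600),
    hap1 = c(mkseq(300), mkseq(350, "C")), hap2 = c(mkseq(300, "G"), mkseq(350, "T"))
  )
  regions <- build_regions(b)
  expect_length(regions, 1)
  expect_equal(c(regions[[1]]$start, regions[[1]]$end), c(100, 600))
  expect_equal(regions[[1]]$participants, c("i1", "i2"))
  # individual 1 masked outside its own block
  expect_true(all(regions[[1]]$seqs[["i1"]][, 301:500] == "N"))
  expect_true(all(regions[[1]]$seqs[["i1"]][, 1:300] != "N"))

  # 50 bp overlap does not chain
  b50 <- phase_blocks(c("i1", "i2"), "s1", c(100, 350), c(400, 600),
                      c(mkseq(300), mkseq(250)), c(mkseq(300), mkseq(250)))
  expect_length(build_regions(b50), 0)

  # a lone block never forms a region
  b1 <- phase_blocks("i1", "s1", 0, 500, mkseq(500), mkseq(500))
  expect_length(build_regions(b1), 0)
})

test_that("region construction is independent of block input order", {
  set.seed(17)
  b <- phase_blocks(
    individual = c("i1", "i2", "i3", "i1", "i2"),
    scaffold = c("s1", "s1", "s1", "s1", "s1"),
    start = c(0, 150, 320, 900, 1000),
    end = c(300, 500, 700, 1200, 1350),
    hap1 = c(mkseq(300), mkseq(350), mkseq(380), mkseq(300), mkseq(350)),
    hap2 = c(mkseq(300), mkseq(350), mkseq(380), mkseq(300), mkseq(350))
  )
  r1 <- build_regions(b)
  r2 <- build_regions(b[sample(nrow(b)), ])
  expect_equal(length(r1), length(r2))
  expect_equal(lapply(r1, `[[`, "start"), lapply(r2, `[[`, "start"))
  expect_equal(lapply(r1, `[[`, "seqs"), lapply(r2, `[[`, "seqs"))
  # every emitted region satisfies the span and participant invariants
  for (rg in r1) {
    expect_gte(rg$end - rg$start, 100)
    expect_gte(length(rg$participants), 2)
  }
})

test_that("overlapping blocks of one individual are a phasing inconsistency", {
  b <- phase_blocks(c("i1", "i1"), "s1", c(0, 100), c(200, 300),
                    c(mkseq(200), mkseq(200)), c(mkseq(200), mkseq(200)))
  expect_error(build_regions(b), "overlapping blocks")
})

test_that("low-coverage masking hits both rows and drops dead participants", {
  b <- phase_blocks(c("i1", "i2"), "s1", c(0, 0), c(200, 200),
                    c(mkseq(200), mkseq(200, "C")), c(mkseq(200, "G"), mkseq(200, "T")))
  rg <- build_regions(b)[[1]]
  cov <- list(
    i1 = coverage_track("s1", c(0, 50), c(50, 200), c(9, 30)),
    i2 = coverage_track("s1", 0, 200, 40)
  )
  masked <- mask_low_coverage(rg, cov, min_depth = 10)
  expect_true(all(masked$seqs[["i1"]][, 1:50] == "N"))
  expect_true(all(masked$seqs[["i1"]][, 51:200] != "N"))
  expect_identical(masked$seqs[["i2"]], rg$seqs[["i2"]])
  # uniformly adequate coverage changes nothing
  cov$i1 <- coverage_track("s1", 0, 200, 30)
  expect_identical(mask_low_coverage(rg, cov, 10)$seqs, rg$seqs)
  # a fully masked individual invalidates the two-participant region
  cov$i1 <- coverage_track("s1", 0, 200, 3)
  expect_null(mask_low_coverage(rg, cov, 10))
})

test_that("haplotype A is the reference-proximal sequence, ties flagged", {
  ref <- strrep("A", 300)
  h_near <- paste0(strrep("A", 295), strrep("G", 5))   # 5 mismatches
  h_far <- paste0(strrep("C", 20), strrep("A", 280))   # 20 mismatches
  b <- phase_blocks(c("i1", "i2"), "s1", c(0, 0), c(300, 300),
                    c(h_far, h_near), c(h_near, h_far))
  rg <- label_haplotypes(build_regions(b)[[1]], ref)
  expect_equal(unname(rg$labels[c("i1", "i2")]), c(2L, 1L))
  expect_false(any(rg$label_ties))
  # masked columns do not count toward the distance
  h_masked <- paste0(strrep("N", 250), strrep("G", 50))  # 50 visible mismatches
  b2 <- phase_blocks("i1", "s1", 0, 300, h_masked, paste0(strrep("T", 40), strrep("A", 260)))
  b2 <- rbind(b2, phase_blocks("i2", "s1", 0, 300, mkseq(300), mkseq(300)))
  class(b2) <- c("phase_blocks", "data.frame")
  rg2 <- label_haplotypes(build_regions(b2)[[1]], ref)
  expect_equal(unname(rg2$labels[["i1"]]), 2L)
  # exact tie: lexicographically smaller sequence becomes A, flagged
  b3 <- phase_blocks(c("i1", "i2"), "s1", c(0, 0), c(300, 300),
                     c(paste0("G", substr(ref, 2, 300)), mkseq(300)),
                     c(paste0("C", substr(ref, 2, 300)), mkseq(300)))
  rg3 <- label_haplotypes(build_regions(b3)[[1]], ref)
  expect_equal(unname(rg3$labels[["i1"]]), 2L) # "C..." < "G..."
  expect_true(rg3$label_ties[["i1"]])
})

test_that("paralog screen flags regions at and above the coverage ratio threshold", {
  b <- phase_blocks(c("i1", "i2"), "s1", c(0, 0), c(200, 200),
                    c(mkseq(200), mkseq(200)), c(mkseq(200), mkseq(200)))
  rg <- build_regions(b)[[1]]
  flag_of <- function(med) {
    paralog_flag(rg, coverage_track("s1", 0, 200, med), 126)$paralog
  }
  expect_false(flag_of(101)$flag)
  expect_equal(flag_of(101)$ratio, 101 / 126, tolerance = 1e-12)
  expect_true(flag_of(207)$flag)
  expect_true(flag_of(1.5 * 126)$flag) # boundary flags
  expect_error(paralog_flag(rg, coverage_track("s1", 0, 200, 100), 0), "> 0")
})

test_that("exported alignments are deterministic, labeled and rectangular", {
  ref <- strrep("A", 200)
  b <- phase_blocks(c("b_ind", "a_ind"), "s1", c(0, 0), c(200, 200),
                    c(mkseq(200), mkseq(200)),
                    c(mkseq(200, "G"), mkseq(200, "G")))
  rg <- label_haplotypes(build_regions(b)[[1]], ref)
  aln <- export_alignment(rg)
  expect_equal(names(aln), c("a_ind_A", "a_ind_B", "b_ind_A", "b_ind_B"))
  expect_equal(unique(nchar(aln)), 200L)
  expect_error(export_alignment(build_regions(b)[[1]]), "label")
})

test_that("phase blocks and coverage tracks round-trip through disk", {
  set.seed(29)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  b <- phase_blocks(
    individual = c("i1", "i1", "i2"), scaffold = c("s1", "s2", "s1"),
    start = c(10, 0, 50), end = c(210, 150, 400),
    hap1 = c(rand_seq(200), rand_seq(150), rand_seq(350)),
    hap2 = c(rand_seq(200), rand_seq(150), rand_seq(350))
  )
  dir <- tempfile(); write_phase_blocks(b, dir)
  back <- read_phase_blocks(dir)
  ord <- order(b$individual, b$scaffold, b$start)
  bo <- b[ord, ]; rownames(bo) <- NULL
  back <- back[order(back$individual, back$scaffold, back$start), ]
  rownames(back) <- NULL
  expect_equal(back, bo)

  ct <- coverage_track("s1", c(0, 100, 250), c(100, 250, 300), c(12, 40, 9))
  f <- tempfile(fileext = ".bedGraph")
  write_coverage(ct, f)
  ct2 <- read_coverage(f)
  expect_equal(ct2$depth, ct$depth)
  expect_equal(ct2$start, ct$start)
  expect_equal(depth_vector(ct2, "s1", 95, 105), c(rep(12, 5), rep(40, 5)))
})

test_that("emitted regions account for exactly the in-block bases", {
  sim <- simulate_dataset(oppiella_like_config("asexual", n_regions = 6, seed = 5))
  regions <- build_regions(sim$blocks)
  # per individual, unmasked bases across regions equal that individual's
  # total block length inside those regions
  for (ind in sim$metadata$individual) {
    unmasked <- sum(vapply(regions, function(rg) {
      if (!ind %in% rg$participants) return(0L)
      sum(rg$seqs[[ind]][1, ] != "N")
    }, integer(1)))
    in_regions <- sum(vapply(regions, function(rg) {
      b <- sim$blocks[sim$blocks$individual == ind &
                        sim$blocks$scaffold == rg$scaffold, , drop = FALSE]
      if (!nrow(b)) return(0L)
      sum(pmax(0L, pmin(b$end, rg$end) - pmax(b$start, rg$start)))
    }, integer(1)))
    expect_equal(unmasked, in_regions)
  }
})
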