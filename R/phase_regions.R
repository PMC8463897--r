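#' Phase blocks: container and I/O
#'
#' A phase block is one individual's pair of read-backed haplotype sequences
#' over a contiguous genomic interval (0-based half-open internally). Blocks
#' are stored as a data.frame with columns `individual`, `scaffold`,
#' `start`, `end`, `hap1`, `hap2`; the two sequences have exactly the
#' interval length (blocks whose haplotypes differ in length, e.g. through
#' indels, are rejected). The 1/2 orientation within a block is as produced
#' by the phaser and carries no meaning; A/B labels are assigned per region
#' against the reference by [label_haplotypes()].
#'
#' @param individual,scaffold,start,end,hap1,hap2 vectors of equal length.
#' @return data.frame of class `phase_blocks`.
#' @export
phase_blocks <- function(individual, scaffold, start, end, hap1, hap2) {
  hap1 <- toupper(hap1); hap2 <- toupper(hap2)
  b <- data.frame(individual = individual, scaffold = scaffold,
                  start = as.integer(start), end = as.integer(end),
                  hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)
  len <- b$end - b$start
  if (any(len < 1)) stop("blocks must have length >= 1")
  if (any(nchar(b$hap1) != len | nchar(b$hap2) != len)) {
    stop("haplotype sequence length must equal block interval length")
  }
  class(b) <- c("phase_blocks", "data.frame")
  b
}

#' Write phase blocks as per-individual BED + FASTA pairs
#'
#' For each individual, emits `<ind>.blocks.bed` (block intervals) and
#' `<ind>.blocks.fa` with two records per block named
#' `<scaffold>:<start>-<end>_1` and `_2`.
#'
#' @param blocks a [phase_blocks()] data.frame
#' @param dir output directory (created if absent)
#' @export
write_phase_blocks <- function(blocks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ind in unique(blocks$individual)) {
    b <- blocks[blocks$individual == ind, , drop = FALSE]
    id <- sprintf("%s:%d-%d", b$scaffold, b$start, b$end)
    gr <- GenomicRanges::GRanges(
      b$scaffold, IRanges::IRanges(start = b$start + 1L, end = b$end),
      name = id
    )
    rtracklayer::export(gr, file.path(dir, paste0(ind, ".blocks.bed")), format = "BED")
    seqs <- stats::setNames(
      lapply(seq_len(nrow(b)), function(i) c(b$hap1[i], b$hap2[i])),
      id
    )
    fa <- unlist(lapply(names(seqs), function(nm) {
      stats::setNames(seqs[[nm]], paste0(nm, c("_1", "_2")))
    }))
    write_fasta(fa, file.path(dir, paste0(ind, ".blocks.fa")))
  }
  invisible(dir)
}

#' Read phase blocks from per-individual BED + FASTA pairs
#'
#' @param dir directory containing `<ind>.blocks.bed` / `<ind>.blocks.fa`
#'   pairs as written by [write_phase_blocks()]
#' @return a [phase_blocks()] data.frame
#' @export
read_phase_blocks <- function(dir) {
  beds <- list.files(dir, pattern = "\\.blocks\\.bed$", full.names = TRUE)
  if (!length(beds)) stop("no .blocks.bed files in ", dir)
  out <- lapply(beds, function(bed) {
    ind <- sub("\\.blocks\\.bed$", "", basename(bed))
    gr <- rtracklayer::import(bed, format = "BED")
    fa <- read_fasta(file.path(dir, paste0(ind, ".blocks.fa")))
    id <- gr$name
    phase_blocks(
      individual = rep(ind, length(gr)),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      hap1 = unname(fa[paste0(id, "_1")]),
      hap2 = unname(fa[paste0(id, "_2")])
    )
  })
  b <- do.call(rbind, out)
  class(b) <- c("phase_blocks", "data.frame")
  b
}

#' FASTA I/O on plain character vectors of sequences
#'
#' Thin wrappers around the standard DNAbin readers/writers, converting to
#' and from named character vectors of uppercase sequence strings.
#'
#' @param seqs named character vector of sequences
#' @param path FASTA file path
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  ape::write.FASTA(ape::as.DNAbin(strsplit(tolower(seqs), "")), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  vapply(as.character(dna), function(s) toupper(paste(s, collapse = "")), character(1))
}

#' Per-base coverage tracks
#'
#' Run-length coverage as a data.frame with columns `scaffold`, `start`,
#' `end` (0-based half-open) and `depth`; serialised as bedGraph.
#'
#' @param scaffold,start,end,depth equal-length vectors
#' @return data.frame of class `coverage_track`
#' @export
coverage_track <- function(scaffold, start, end, depth) {
  stopifnot(all(depth >= 0))
  ct <- data.frame(scaffold = scaffold, start = as.integer(start),
                   end = as.integer(end), depth = as.numeric(depth),
                   stringsAsFactors = FALSE)
  class(ct) <- c("coverage_track", "data.frame")
  ct
}

#' @rdname coverage_track
#' @param ct a coverage_track
#' @param path bedGraph path
#' @export
write_coverage <- function(ct, path) {
  gr <- GenomicRanges::GRanges(ct$scaffold,
                               IRanges::IRanges(start = ct$start + 1L, end = ct$end),
                               score = ct$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname coverage_track
#' @export
read_coverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                 gr$score)
}

#' Per-base depth over an interval
#' @param ct a [coverage_track()]
#' @param scaffold,start,end interval (0-based half-open)
#' @return numeric vector of length `end - start` (0 where uncovered)
#' @export
depth_vector <- function(ct, scaffold, start, end) {
  dv <- numeric(end - start)
  rows <- which(ct$scaffold == scaffold & ct$end > start & ct$start < end)
  for (r in rows) {
    lo <- max(ct$start[r], start); hi <- min(ct$end[r], end)
    dv[(lo - start + 1):(hi - start)] <- ct$depth[r]
  }
  dv
}

#' Assemble phaseable regions from phase blocks
#'
#' A phaseable region is a maximal union of phase blocks chained by
#' pairwise cross-individual overlaps of at least `min_overlap` bp. Regions
#' involving fewer than `min_individuals` individuals or spanning fewer than
#' `min_region_len` bp are discarded. The region interval is the union of
#' the chained blocks (chaining guarantees contiguity); each participant's
#' two haplotype rows carry `N` outside that individual's own blocks.
#' Construction is independent of block input order.
#'
#' @param blocks a [phase_blocks()] data.frame; overlapping blocks of the
#'   same individual on one scaffold are a phasing inconsistency and raise
#'   an error.
#' @param min_overlap minimum cross-individual overlap in bp (default 100).
#' @param min_individuals minimum number of participating individuals
#'   (default 2).
#' @param min_region_len minimum region span in bp (default 100).
#' @return list of `phased_region` objects, sorted by (scaffold, start).
#' @export
build_regions <- function(blocks, min_overlap = 100, min_individuals = 2,
                          min_region_len = 100) {
  blocks <- blocks[order(blocks$scaffold, blocks$start, blocks$individual), , drop = FALSE]
  # same-individual overlap check
  for (key in unique(paste(blocks$individual, blocks$scaffold))) {
    b <- blocks[paste(blocks$individual, blocks$scaffold) == key, , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping blocks of the same individual on one scaffold: ", key)
    }
  }
  regions <- list()
  for (sc in unique(blocks$scaffold)) {
    b <- blocks[blocks$scaffold == sc, , drop = FALSE]
    nb <- nrow(b)
    parent <- seq_len(nb)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(max(nb - 1, 0))) {
      for (j in (i + 1):nb) {
        if (b$individual[i] == b$individual[j]) next
        ov <- min(b$end[i], b$end[j]) - max(b$start[i], b$start[j])
        if (ov >= min_overlap) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    comp <- vapply(seq_len(nb), find, integer(1))
    for (cp in unique(comp)) {
      idx <- which(comp == cp)
      participants <- sort(unique(b$individual[idx]))
      lo <- min(b$start[idx]); hi <- max(b$end[idx])
      if (length(participants) < min_individuals) next
      if (hi - lo < min_region_len) next
      len <- hi - lo
      seqs <- list()
      for (ind in participants) {
        h1 <- h2 <- rep("N", len)
        for (k in idx[b$individual[idx] == ind]) {
          at <- (b$start[k] - lo + 1):(b$end[k] - lo)
          h1[at] <- strsplit(b$hap1[k], "")[[1]]
          h2[at] <- strsplit(b$hap2[k], "")[[1]]
        }
        seqs[[ind]] <- rbind(h1, h2)
      }
      regions[[length(regions) + 1L]] <- structure(
        list(scaffold = sc, start = lo, end = hi,
             participants = participants, seqs = seqs,
             labels = NULL, paralog = NULL),
        class = "phased_region"
      )
    }
  }
  ord <- order(vapply(regions, `[[`, character(1), "scaffold"),
               vapply(regions, `[[`, integer(1), "start"))
  regions[ord]
}

#' @export
print.phased_region <- function(x, ...) {
  cat(sprintf("phased_region %s:%d-%d (%d bp, %d individuals)%s\n",
              x$scaffold, x$start, x$end, x$end - x$start,
              length(x$participants),
              if (isTRUE(x$paralog$flag)) " [paralog-flagged]" else ""))
  invisible(x)
}

#' Mask low-coverage bases in a phased region
#'
#' Both haplotype rows of an individual are set to `N` wherever that
#' individual's read coverage falls below `min_depth` (the same threshold
#' used for genotype filtration, so unphased low-confidence bases never
#' enter the alignments). Individuals masked over their entire row are
#' removed; if fewer than two participants remain the region is no longer
#' phaseable and `NULL` is returned.
#'
#' @param region a `phased_region`
#' @param coverage named list of [coverage_track()]s, one per individual.
#' @param min_depth mask threshold (default 10).
#' @return the masked region, or `NULL` if it became invalid.
#' @export
mask_low_coverage <- function(region, coverage, min_depth = 10) {
  keep <- character(0)
  for (ind in region$participants) {
    if (!is.null(coverage[[ind]])) {
      dv <- depth_vector(coverage[[ind]], region$scaffold, region$start, region$end)
      low <- dv < min_depth
      region$seqs[[ind]][, low] <- "N"
    }
    if (any(region$seqs[[ind]] != "N")) keep <- c(keep, ind)
  }
  region$seqs <- region$seqs[keep]
  region$participants <- keep
  if (length(keep) < 2) return(NULL)
  region
}

#' Label the two haplotypes of each participant as A or B
#'
#' Haplotype A is the one closer to the reference sequence, B the more
#' diverged; distances are mismatch counts over columns where both the
#' haplotype and the reference are unambiguous nucleotides (degenerate or
#' masked positions are skipped). Exact ties are broken lexicographically
#' (the smaller sequence string becomes A) and flagged.
#'
#' @param region a `phased_region`
#' @param reference named character vector of full scaffold sequences (or a
#'   single unnamed sequence string for the region's scaffold).
#' @return the region with `labels` (named vector: which row, 1 or 2, is A)
#'   and `label_ties` (named logical) filled in.
#' @export
label_haplotypes <- function(region, reference) {
  refseq <- if (is.null(names(reference))) reference[[1]] else reference[[region$scaffold]]
  if (nchar(refseq) < region$end) stop("reference does not cover region")
  ref <- strsplit(toupper(substr(refseq, region$start + 1, region$end)), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  labels <- integer(0); ties <- logical(0)
  for (ind in region$participants) {
    s <- region$seqs[[ind]]
    mm <- vapply(1:2, function(r) {
      use <- s[r, ] %in% acgt & ref %in% acgt
      sum(s[r, use] != ref[use])
    }, numeric(1))
    if (mm[1] != mm[2]) {
      a <- which.min(mm); tie <- FALSE
    } else {
      str <- apply(s, 1, paste, collapse = "")
      a <- if (str[1] <= str[2]) 1L else 2L
      tie <- TRUE
    }
    labels[ind] <- a
    ties[ind] <- tie
  }
  region$labels <- labels
  region$label_ties <- ties
  region
}

#' Coverage-based paralog screen for a phased region
#'
#' Collapsed paralogs attract roughly twice the read coverage of
#' single-copy sequence. The region's median per-base genomic read coverage
#' is compared to the median over a single-copy baseline (e.g. conserved
#' single-copy genes); the region is flagged when the ratio reaches
#' `ratio_threshold`. The threshold defaults to 1.5, midway between the
#' single-copy (1x) and duplicate (about 2x) coverage classes; the boundary
#' case flags (`>=`).
#'
#' @param region a `phased_region`
#' @param genome_coverage [coverage_track()] of genomic read coverage.
#' @param singlecopy_baseline_median median coverage of the single-copy
#'   baseline (> 0).
#' @param ratio_threshold flag when ratio >= this (default 1.5).
#' @return the region with `paralog = list(flag, ratio, median_coverage)`.
#' @export
paralog_flag <- function(region, genome_coverage, singlecopy_baseline_median,
                         ratio_threshold = 1.5) {
  stopifnot(singlecopy_baseline_median > 0)
  dv <- depth_vector(genome_coverage, region$scaffold, region$start, region$end)
  if (!length(dv)) stop("empty coverage over region")
  med <- stats::median(dv)
  ratio <- med / singlecopy_baseline_median
  region$paralog <- list(flag = ratio >= ratio_threshold, ratio = ratio,
                         median_coverage = med)
  region
}

#' Export a labeled region as a multiple-sequence alignment
#'
#' Row names are `<individual>_A` / `<individual>_B`, individuals sorted, A
#' before B; all rows have the region length, with masked positions as `N`.
#'
#' @param region a labeled `phased_region` (run [label_haplotypes()] first).
#' @param file optional FASTA path to write.
#' @return named character vector of aligned sequences.
#' @export
export_alignment <- function(region, file = NULL) {
  if (is.null(region$labels)) stop("region is not labeled; run label_haplotypes() first")
  out <- character(0)
  for (ind in sort(region$participants)) {
    a <- region$labels[[ind]]
    out[paste0(ind, "_A")] <- paste(region$seqs[[ind]][a, ], collapse = "")
    out[paste0(ind, "_B")] <- paste(region$seqs[[ind]][3 - a, ], collapse = "")
  }
  if (!is.null(file)) write_fasta(out, file)
  out
}
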