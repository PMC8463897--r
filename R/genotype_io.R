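#' Read an all-sites VCF into a genotype matrix
#'
#' Consumes a VCF 4.x stream with `GT` and `DP` FORMAT fields, as produced by
#' joint genotyping with invariant-site output enabled. Multi-allelic records
#' are retained with their allele count recorded; filtering is a separate,
#' explicit step ([filter_sites()]).
#'
#' @param vcf path to a VCF file (optionally gzipped), or a `vcfR` object.
#' @param samples optional character vector restricting the individuals read;
#'   default all samples in the file.
#' @return A [genotype_matrix()]. A genotype is missing where GT contains
#'   `.`; phased (`|`) and unphased (`/`) separators are treated identically,
#'   as phase is taken only from read-backed phase blocks, never from the VCF.
#' @export
read_genotypes <- function(vcf, samples = NULL) {
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  available <- colnames(v@gt)[-1]
  if (is.null(samples)) {
    samples <- available
  } else if (!all(samples %in% available)) {
    stop(sprintf(
      "sample(s) %s not in VCF; available: %s",
      paste(setdiff(samples, available), collapse = ", "),
      paste(available, collapse = ", ")
    ))
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt[!is.na(alt) & alt == "."] <- NA_character_
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  n_alleles <- 1L + lengths(alt_list)
  is_indel <- nchar(ref) != 1L |
    vapply(alt_list, function(a) length(a) > 0 && any(nchar(a) != 1L), logical(1))

  sites <- data.frame(
    scaffold = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L, # VCF is 1-based; internal 0-based
    ref = ref,
    alt = alt,
    is_indel = is_indel,
    n_alleles = n_alleles,
    stringsAsFactors = FALSE
  )

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (is.null(dim(dp))) dp <- matrix(dp, nrow = 1, dimnames = list(NULL, names(dp)))
  gt <- gt[, samples, drop = FALSE]
  dp <- dp[, samples, drop = FALSE]

  calls <- gt_to_dosage(gt)
  depth <- dp
  storage.mode(depth) <- "integer"

  ord <- order(sites$scaffold, sites$pos)
  genotype_matrix(sites[ord, , drop = FALSE], samples,
                  calls[ord, , drop = FALSE], depth[ord, , drop = FALSE])
}

# Map GT strings to nonreference dosage. Any allele "." -> missing. The
# dosage is the count of nonzero allele indices, so a mixed-alternate call
# like "1/2" codes 2; such sites are multi-allelic and removed by the
# standard biallelic filter.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".") || length(al) != 2L) return(NA_integer_)
    sum(al != "0")
  }, integer(1))
  out <- matrix(code[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  out
}

#' Apply the standard site filters
#'
#' Filters are applied in a fixed order so per-filter removal counts are
#' well defined: (1) genotypes with depth below `min_depth` are set to
#' missing; then sites are dropped that are (2) indels, (3) more than
#' biallelic, (4) incomplete (any missing genotype), (5) monomorphic. A site
#' is attributed to the first filter that removes it. "Monomorphic" means all
#' non-missing calls are homozygous reference; an all-homozygous-alternate
#' site is kept as variant because downstream spectra count nonreference
#' alleles.
#'
#' @param gm a [genotype_matrix()]
#' @param min_depth genotypes with read depth below this (or with no reported
#'   depth) are set to missing before site predicates run. Default 10, the
#'   conventional minimum for confident diploid genotype calls from
#'   moderate-coverage data.
#' @param require_complete drop sites with at least one missing genotype.
#' @param biallelic_snps_only drop indels and sites with more than two
#'   alleles.
#' @param drop_monomorphic drop sites with no nonreference call.
#' @return A filtered [genotype_matrix()] with a `filter_report` attribute:
#'   a data.frame of per-filter masked-genotype and removed-site counts.
#'   Emits a warning (not an error) if no site survives.
#' @export
filter_sites <- function(gm, min_depth = 10, require_complete = TRUE,
                         biallelic_snps_only = TRUE, drop_monomorphic = TRUE) {
  stopifnot(min_depth >= 0)
  calls <- gm$calls
  n_in <- n_sites(gm)

  low <- !is.na(calls) & (is.na(gm$depth) | gm$depth < min_depth)
  n_masked <- sum(low)
  calls[low] <- NA_integer_

  removed <- c(indel = 0L, multiallelic = 0L, incomplete = 0L, monomorphic = 0L)
  keep <- rep(TRUE, n_in)

  if (biallelic_snps_only) {
    f <- keep & gm$sites$is_indel
    removed["indel"] <- sum(f)
    keep <- keep & !f
    f <- keep & gm$sites$n_alleles > 2L
    removed["multiallelic"] <- sum(f)
    keep <- keep & !f
  }
  if (require_complete) {
    f <- keep & (rowSums(is.na(calls)) > 0L)
    removed["incomplete"] <- sum(f)
    keep <- keep & !f
  }
  if (drop_monomorphic) {
    nonref <- rowSums(calls > 0L, na.rm = TRUE)
    informative <- rowSums(!is.na(calls)) > 0L
    f <- keep & informative & nonref == 0L
    # sites that became all-missing are monomorphic in the degenerate sense
    # only when completeness is not enforced; attribute them here too
    f <- f | (keep & !informative)
    removed["monomorphic"] <- sum(f)
    keep <- keep & !f
  }

  out <- genotype_matrix(
    gm$sites[keep, , drop = FALSE], gm$individuals,
    calls[keep, , drop = FALSE], gm$depth[keep, , drop = FALSE]
  )
  attr(out, "filter_report") <- data.frame(
    filter = c("depth_masked_genotypes", names(removed)),
    n = c(n_masked, unname(removed)),
    unit = c("genotypes", rep("sites", length(removed))),
    stringsAsFactors = FALSE
  )
  if (n_sites(out) == 0L) warning("no sites survived filtering")
  out
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `individual`, `population` and optionally
#'   `lineage` (empty or `NA` for individuals without a lineage assignment,
#'   e.g. divergent singletons).
#' @return data.frame with columns individual, population, lineage.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("individual", "population") %in% names(md))) {
    stop("metadata must have columns 'individual' and 'population'")
  }
  if (is.null(md$lineage)) md$lineage <- NA_character_
  md$lineage <- as.character(md$lineage)
  md
}

#' Write a sample metadata table
#' @param metadata data.frame as returned by [read_sample_metadata()]
#' @param path output TSV path
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Split a genotype matrix by population or lineage
#'
#' Individuals without a label at the requested level are dropped with a
#' warning (mirroring divergent singleton lineages that provide no
#' subpopulation context). Site lists are carried over unchanged; re-filter
#' each subset (e.g. for within-group polymorphism) downstream as needed.
#'
#' @param gm a [genotype_matrix()]
#' @param metadata data.frame with columns individual, population, lineage
#' @param level `"population"` or `"lineage"`
#' @return named list of [genotype_matrix()] objects, one per group.
#' @export
partition_by_group <- function(gm, metadata, level = c("population", "lineage")) {
  level <- match.arg(level)
  lab <- metadata[[level]][match(gm$individuals, metadata$individual)]
  if (level == "lineage" && all(is.na(lab))) {
    stop("no lineage labels in metadata")
  }
  if (any(is.na(lab))) {
    warning(sprintf(
      "dropping individual(s) without %s label: %s",
      level, paste(gm$individuals[is.na(lab)], collapse = ", ")
    ))
  }
  groups <- split(gm$individuals[!is.na(lab)], lab[!is.na(lab)])
  lapply(groups, function(ids) subset_gm(gm, individuals = ids))
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 with GT and DP; calls are written as unphased
#' biallelic genotypes (`0/0`, `0/1`, `1/1`, `./.`). Output is bgzipped
#' (`.vcf.gz`) as is conventional.
#'
#' @param gm a [genotype_matrix()]
#' @param path output path ending in `.vcf.gz`
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(gm$sites$scaffold), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"
  )
  fix <- cbind(
    CHROM = gm$sites$scaffold,
    POS = as.character(gm$sites$pos + 1L),
    ID = NA_character_,
    REF = gm$sites$ref,
    ALT = ifelse(is.na(gm$sites$alt), ".", gm$sites$alt),
    QUAL = NA_character_,
    FILTER = NA_character_,
    INFO = NA_character_
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L], nrow = n_sites(gm))
  gt_str[is.na(gm$calls)] <- "./."
  dp_str <- matrix(as.character(gm$depth), nrow = n_sites(gm))
  dp_str[is.na(gm$depth)] <- "."
  body <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = n_sites(gm),
                 dimnames = list(NULL, gm$individuals))
  gt <- cbind(FORMAT = rep("GT:DP", n_sites(gm)), body)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}
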