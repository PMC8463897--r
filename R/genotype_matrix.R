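#' Construct a genotype matrix
#'
#' The central container for multi-individual diploid genotype data: an
#' ordered site table plus per-(site, individual) genotype calls and read
#' depths. Genotype calls are coded by nonreference allele dosage:
#' `0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternate, `NA` = missing. Positions are 0-based internally; VCF I/O
#' converts to and from 1-based coordinates.
#'
#' @param sites data.frame with columns `scaffold` (character), `pos`
#'   (0-based integer), `ref`, `alt` (comma-separated alternate alleles, or
#'   `NA` for monomorphic records), `is_indel` (logical) and `n_alleles`
#'   (integer, >= 1).
#' @param individuals character vector of unique individual identifiers.
#' @param calls integer matrix, sites x individuals, values in `c(0, 1, 2, NA)`.
#' @param depth integer matrix of per-genotype read depths, same shape as
#'   `calls`; `NA` where no depth was reported.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, individuals, calls, depth) {
  calls <- as.matrix(calls)
  depth <- as.matrix(depth)
  storage.mode(calls) <- "integer"
  storage.mode(depth) <- "integer"
  colnames(calls) <- individuals
  colnames(depth) <- individuals
  gm <- structure(
    list(sites = sites, individuals = individuals, calls = calls, depth = depth),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  stopifnot(
    is.data.frame(gm$sites),
    all(c("scaffold", "pos", "ref", "alt", "is_indel", "n_alleles") %in% names(gm$sites)),
    nrow(gm$sites) == nrow(gm$calls),
    nrow(gm$calls) == nrow(gm$depth),
    ncol(gm$calls) == length(gm$individuals),
    ncol(gm$depth) == length(gm$individuals)
  )
  if (anyDuplicated(gm$individuals) > 0) {
    stop("individual identifiers must be unique")
  }
  if (nrow(gm$sites) > 0) {
    if (any(gm$sites$pos < 0)) stop("positions must be >= 0")
    if (any(gm$sites$n_alleles < 1)) stop("n_alleles must be >= 1")
    ord <- order(gm$sites$scaffold, gm$sites$pos)
    if (!identical(ord, seq_len(nrow(gm$sites)))) {
      stop("sites must be sorted by (scaffold, position)")
    }
  }
  bad <- gm$calls[!is.na(gm$calls)]
  if (length(bad) && !all(bad %in% 0:2)) stop("calls must be 0, 1, 2 or NA")
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d sites x %d individuals (%.1f%% missing)\n",
    n_sites(x), n_individuals(x),
    if (length(x$calls)) 100 * mean(is.na(x$calls)) else 0
  ))
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) {
    cat("filter report:\n")
    print(rep, row.names = FALSE)
  }
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a [genotype_matrix()]
#' @return integer
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Number of individuals in a genotype matrix
#' @param gm a [genotype_matrix()]
#' @return integer
#' @export
n_individuals <- function(gm) length(gm$individuals)

#' Subset a genotype matrix by sites and/or individuals
#'
#' The filter-report attribute is dropped (it no longer applies to the
#' subset).
#'
#' @param gm a [genotype_matrix()]
#' @param site_idx integer site indices (default all)
#' @param individuals individual identifiers to keep (default all)
#' @return a [genotype_matrix()]
#' @export
subset_gm <- function(gm, site_idx = NULL, individuals = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(n_sites(gm))
  if (is.null(individuals)) individuals <- gm$individuals
  genotype_matrix(
    sites = gm$sites[site_idx, , drop = FALSE],
    individuals = individuals,
    calls = gm$calls[site_idx, individuals, drop = FALSE],
    depth = gm$depth[site_idx, individuals, drop = FALSE]
  )
}
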