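#' Published summary tables for the Oppiella study system
#'
#' Per-individual heterozygosity and inbreeding estimates, per-region
#' topology-test counts, and parallel-divergence counts published for the
#' asexual oribatid mite *Oppiella nova* (nine individuals, two divergent
#' lineages plus two near-homozygous singletons) and its sexual relative
#' *Oppiella subpectinata* (nine individuals, three populations). These
#' tables are desk-scale inputs for the statistical stages of the package
#' (rank-sum comparison, binomial parallel-divergence test, ratio
#' summaries); the underlying sequence data are not shipped.
#'
#' @return named list of data.frames: `heterozygosity` (species, population,
#'   individual, pct_het), `fis` (adds lineage, fis, n_sites),
#'   `region_counts` (species, key, value) and `parallel` (lineage, k_taxa,
#'   n_resolved, n_separating, n_matching).
#' @export
oppiella_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "meselson", mustWork = TRUE)
  rd <- function(f) utils::read.table(p(f), header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      na.strings = c("NA", ""))
  list(
    heterozygosity = rd("oppiella_heterozygosity.tsv"),
    fis = rd("oppiella_fis.tsv"),
    region_counts = rd("oppiella_region_counts.tsv"),
    parallel = rd("oppiella_parallel.tsv")
  )
}
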