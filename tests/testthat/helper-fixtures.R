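# Shared fixture builders and independent oracles.

# genotype matrix from a dosage matrix (sites x individuals)
toy_gm <- function(calls, depth = NULL, scaffold = "s1", ref = "A", alt = "G",
                   is_indel = FALSE, n_alleles = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(depth)) depth <- matrix(100L, n, ncol(calls))
  if (is.null(n_alleles)) n_alleles <- rep(2L, n)
  inds <- colnames(calls)
  if (is.null(inds)) inds <- paste0("i", seq_len(ncol(calls)))
  genotype_matrix(
    sites = data.frame(
      scaffold = rep(scaffold, n), pos = seq_len(n) - 1L,
      ref = rep(ref, length.out = n), alt = rep(alt, length.out = n),
      is_indel = rep(is_indel, length.out = n),
      n_alleles = rep(n_alleles, length.out = n),
      stringsAsFactors = FALSE
    ),
    individuals = inds, calls = calls, depth = depth
  )
}

# plain-text VCF writer for I/O tests
write_toy_vcf <- function(path, records, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  )
  writeLines(lines, path)
  path
}

# brute-force hierarchical AMOVA from an explicit haplotype matrix
# (2N rows x sites) and per-individual population labels; the squared
# inter-haplotype distance is the Hamming distance between rows
amova_oracle <- function(hapm, pop) {
  n_ind <- nrow(hapm) / 2
  ind_of <- rep(seq_len(n_ind), each = 2)
  d2 <- as.matrix(dist(hapm, method = "manhattan"))
  Th <- nrow(hapm)
  ssd <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssd_total <- ssd(seq_len(Th))
  pops <- unique(pop)
  ssd_wp <- sum(vapply(pops, function(p) ssd(which(pop[ind_of] == p)), numeric(1)))
  ssd_wi <- sum(vapply(seq_len(n_ind), function(i) ssd(which(ind_of == i)), numeric(1)))
  P <- length(pops)
  df_ap <- P - 1; df_ai <- n_ind - P; df_wi <- n_ind
  ms_wi <- ssd_wi / df_wi
  ms_ai <- if (df_ai > 0) (ssd_wp - ssd_wi) / df_ai else NA_real_
  ms_ap <- (ssd_total - ssd_wp) / df_ap
  t_p <- vapply(pops, function(p) sum(pop == p) * 2, numeric(1))
  n_c <- (Th - sum(t_p^2) / Th) / (P - 1)
  s2_wi <- ms_wi
  s2_ai <- if (is.na(ms_ai)) 0 else (ms_ai - s2_wi) / 2
  s2_ap <- (ms_ap - s2_wi - 2 * s2_ai) / n_c
  c(among_pop = s2_ap, among_ind = s2_ai, within_ind = s2_wi)
}

# dosage matrix -> explicit pseudo-haplotype matrix with chosen phase
gm_to_haplotypes <- function(calls, flip = NULL) {
  n_ind <- ncol(calls)
  if (is.null(flip)) flip <- matrix(FALSE, nrow(calls), n_ind)
  out <- matrix(0L, 2 * n_ind, nrow(calls))
  for (i in seq_len(n_ind)) {
    h1 <- as.integer(calls[, i] == 2)
    h2 <- as.integer(calls[, i] >= 1)
    f <- flip[, i]
    out[2 * i - 1, ] <- ifelse(f, h2, h1)
    out[2 * i, ] <- ifelse(f, h1, h2)
  }
  out
}

# exhaustive generation of rooted leaf-labeled topologies by inserting each
# taxon on every edge (including a new root edge is not needed for rooted
# trees built this way); returns canonical newick strings
all_rooted_topologies <- function(labels) {
  if (length(labels) == 1) return(labels)
  if (length(labels) == 2) return(sprintf("(%s,%s)", labels[1], labels[2]))
  prev <- all_rooted_topologies(labels[-length(labels)])
  new <- labels[length(labels)]
  out <- character(0)
  for (t in prev) {
    for (i in seq_along(insertion_points(t))) {
      out <- c(out, insert_at(t, insertion_points(t)[[i]], new))
    }
  }
  unique(vapply(out, canonical_newick, character(1)))
}

# subtree spans (start, end indices) of every subtree in a newick string,
# plus the whole tree (new root)
insertion_points <- function(nwk) {
  pts <- list()
  depth <- 0
  start <- NULL
  chars <- strsplit(nwk, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    c <- chars[i]
    if (c == "(") depth <- depth + 1
    if (c == ")") depth <- depth - 1
    i <- i + 1
  }
  # simpler: find all maximal label tokens and parenthesized groups
  # token starts
  n <- length(chars)
  i <- 1
  while (i <= n) {
    c <- chars[i]
    if (c == "(") {
      d <- 1; j <- i + 1
      while (d > 0) { if (chars[j] == "(") d <- d + 1; if (chars[j] == ")") d <- d - 1; j <- j + 1 }
      pts[[length(pts) + 1]] <- c(i, j - 1)
      i <- i + 1
    } else if (!(c %in% c(",", ")", "("))) {
      j <- i
      while (j <= n && !(chars[j] %in% c(",", ")", "("))) j <- j + 1
      pts[[length(pts) + 1]] <- c(i, j - 1)
      i <- j
    } else {
      i <- i + 1
    }
  }
  pts
}

insert_at <- function(nwk, span, new) {
  sub <- substr(nwk, span[1], span[2])
  paste0(substr(nwk, 1, span[1] - 1), "(", sub, ",", new, ")",
         substr(nwk, span[2] + 1, nchar(nwk)))
}

canonical_newick <- function(nwk) {
  canon <- function(s) {
    if (!startsWith(s, "(")) return(s)
    inner <- substr(s, 2, nchar(s) - 1)
    parts <- character(0); d <- 0; start <- 1
    chars <- strsplit(inner, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") d <- d + 1
      if (chars[i] == ")") d <- d - 1
      if (chars[i] == "," && d == 0) {
        parts <- c(parts, substr(inner, start, i - 1)); start <- i + 1
      }
    }
    parts <- c(parts, substr(inner, start, nchar(inner)))
    paste0("(", paste(sort(vapply(parts, canon, character(1))), collapse = ","), ")")
  }
  canon(nwk)
}

# uniform random rooted leaf-labeled topology via random edge insertion
random_rooted_topology <- function(labels) {
  nwk <- labels[1]
  if (length(labels) == 1) return(nwk)
  nwk <- sprintf("(%s,%s)", labels[1], labels[2])
  for (k in seq_along(labels)[-(1:2)]) {
    pts <- insertion_points(nwk)
    nwk <- insert_at(nwk, pts[[sample(length(pts), 1)]], labels[k])
  }
  nwk
}

# full haplotype tree from two rooted subtree shapes (newick without
# branch lengths); every edge gets length 0.01 so the tree is resolved
join_haplotype_tree <- function(nwk_a, nwk_b) {
  add_len <- function(s) gsub("(\\))", "\\1:0.01", gsub("([A-Za-z0-9_]+)", "\\1:0.01", s))
  ape::read.tree(text = paste0("(", add_len(nwk_a), ",", add_len(nwk_b), ");"))
}

suffix_labels <- function(nwk, suffix) {
  gsub("([A-Za-z0-9]+)", paste0("\\1_", suffix), nwk)
}
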