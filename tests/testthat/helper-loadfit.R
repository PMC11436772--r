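# Shared test utilities: compact variant_table builders, a handcrafted VCF
# writer, an independent brute-force load-profile oracle, and a lazily cached
# default simulation reused across test files.

# Build a variant_table from vectors; positions default to 1, 2, 3, ...
make_table <- function(impact, geno, samples,
                       gene = NULL, pos = seq_along(impact)) {
  n <- length(impact)
  sites <- data.frame(
    chrom = rep("chr1", n), pos = pos,
    ref = rep("A", n), alt = rep("T", n),
    impact = impact,
    gene = gene %||% ifelse(impact == "OTHER", NA_character_,
                            paste0("G", seq_len(n))),
    stringsAsFactors = FALSE)
  variant_table(sites, geno, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a VCF from raw body lines (one string per record) with a minimal
# ANN-capable header for the given sample names.
write_raw_vcf <- function(path, samples, body) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

# Independent brute-force load-profile oracle: explicit loops over sites,
# no vectorised tallies shared with the package implementation.
brute_profile <- function(table, individual,
                          denominator = c("all_sites", "carrier_sites")) {
  denominator <- match.arg(denominator)
  der <- c(LOF = 0, MISSENSE = 0, SYNONYMOUS = 0)
  hom <- der; het <- der
  n_scored <- 0L
  n_carrier <- 0L
  for (j in seq_len(nrow(table$sites))) {
    cls <- table$sites$impact[j]
    if (!cls %in% names(der)) next
    n_scored <- n_scored + 1L
    g <- table$geno[j, individual]
    if (is.na(g)) next
    if (g > 0L) n_carrier <- n_carrier + 1L
    der[cls] <- der[cls] + g
    if (g == 2L) hom[cls] <- hom[cls] + 1
    if (g == 1L) het[cls] <- het[cls] + 1
  }
  tot <- sum(der)
  p <- if (tot == 0) c(NA_real_, NA_real_, NA_real_) else unname(der) / tot
  den <- if (denominator == "all_sites") n_scored else n_carrier
  e <- if (den > 0) unname(hom) / den else rep(NA_real_, 3)
  m <- if (den > 0) unname(het) / den else rep(NA_real_, 3)
  list(n_sites_scored = n_scored,
       p_lof = p[1], p_mis = p[2], p_syn = p[3],
       e_lof = e[1], e_mis = e[2], e_syn = e[3],
       m_lof = m[1], m_mis = m[2], m_syn = m[3])
}

# A fast simulator configuration for tests that only need a valid run.
small_cfg <- function(seed = 7, ...) {
  sim_config(n_founders = 10, n_generations = 4, carrying_capacity = 24,
             genome_length = 2e5,
             founder_sites = c(lof = 10, mis = 60, syn = 120, neutral = 250),
             mut_rates = c(lof = 0.002, mis = 0.05, syn = 0.1, neutral = 0.2),
             immigration_generation = 3, n_immigrants = 2,
             n_dens = 12, n_sample = 12, seed = seed, ...)
}

# One default-configuration simulation shared by the tests that inspect the
# study-scale behaviour (computed at most once per test run).
get_default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_population(sim_config())
    cache
  }
})
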