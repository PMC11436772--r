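# Zygosity-pattern screens for candidate loss-of-function variants and a
# generic Fisher-exact overrepresentation test. Screens implement the strict
# all-affected / no-unaffected-homozygote reading, with fraction parameters
# that reproduce the relaxed reported counts; outputs are invariant to the
# ordering of individuals and sites, and raising a threshold never adds
# variants.

check_groups <- function(table, a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop_loadfit("both groups must be non-empty", "loadfit_input_error")
  }
  if (length(intersect(a, b))) {
    stop_loadfit("groups must be disjoint", "loadfit_input_error")
  }
  missing <- setdiff(c(a, b), table$samples)
  if (length(missing)) stop_loadfit(
    paste0("individuals not in table: ", paste(missing, collapse = ", ")),
    "loadfit_input_error")
}

lof_geno <- function(table, ids) {
  lof <- which(table$sites$impact == "LOF")
  list(idx = lof, g = table$geno[lof, ids, drop = FALSE])
}

#' Ancestry screen: LoF variants private to the admixed gene pool
#'
#' Returns LoF sites absent from every native individual (no derived allele)
#' whose derived-allele frequency among the admixed ("hybrid") individuals,
#' over 2 x n chromosomes, is at or above `freq_threshold` (inclusive).
#'
#' @param table a filtered [variant_table].
#' @param native_ids,hybrid_ids disjoint, non-empty sample-id vectors.
#' @param freq_threshold minimum hybrid allele frequency (proportion).
#' @return data.frame of passing sites with `hybrid_freq_percent`, sorted by
#'   frequency, descending.
#' @export
hybrid_private_lofs <- function(table, native_ids, hybrid_ids,
                                freq_threshold = 0.20) {
  check_groups(table, native_ids, hybrid_ids)
  if (freq_threshold < 0 || freq_threshold > 1) {
    stop_loadfit("freq_threshold must lie in [0, 1]", "loadfit_input_error")
  }
  lof <- which(table$sites$impact == "LOF")
  g_nat <- table$geno[lof, native_ids, drop = FALSE]
  g_hyb <- table$geno[lof, hybrid_ids, drop = FALSE]
  absent_native <- rowSums(g_nat > 0L, na.rm = TRUE) == 0L
  freq <- rowSums(g_hyb, na.rm = TRUE) / (2 * length(hybrid_ids))
  pass <- absent_native & freq >= freq_threshold
  out <- table$sites[lof[pass], , drop = FALSE]
  out$hybrid_freq_percent <- 100 * freq[pass]
  out <- out[order(-out$hybrid_freq_percent, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Litter-size screen for candidate LoF variants
#'
#' A LoF site passes if every low-fecundity individual carries at least one
#' derived allele (homozygous or heterozygous, never absent) and no
#' high-fecundity individual is homozygous for it. The fraction of low-group
#' individuals that are homozygous is reported per passing site.
#'
#' @param table a filtered [variant_table].
#' @param low_group,high_group disjoint sample-id vectors (small- and
#'   large-litter individuals).
#' @return data.frame of passing sites with `low_hom_fraction`.
#' @export
litter_size_screen <- function(table, low_group, high_group) {
  check_groups(table, low_group, high_group)
  lg <- lof_geno(table, low_group)
  hg <- table$geno[lg$idx, high_group, drop = FALSE]
  all_low_carry <- rowSums(lg$g > 0L, na.rm = TRUE) == length(low_group) &
    !apply(lg$g, 1, anyNA)
  no_high_hom <- rowSums(hg == 2L, na.rm = TRUE) == 0L
  pass <- all_low_carry & no_high_hom
  out <- table$sites[lg$idx[pass], , drop = FALSE]
  out$low_hom_fraction <- rowSums(lg$g[pass, , drop = FALSE] == 2L, na.rm = TRUE) /
    length(low_group)
  out <- out[order(-out$low_hom_fraction, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Longevity screen for candidate LoF variants
#'
#' A LoF site passes if no long-lived individual is homozygous for the
#' derived allele and the fraction of short-lived individuals homozygous for
#' it is at least `min_hom_fraction`. The default 1.0 is the strict rule
#' (homozygous in *all* short-lived individuals); 0.4 reproduces the relaxed
#' "homozygous in at least 40%" report.
#'
#' @param table a filtered [variant_table].
#' @param short_group,long_group disjoint sample-id vectors.
#' @param min_hom_fraction required homozygote fraction in the short-lived
#'   group, in [0, 1].
#' @return data.frame of passing sites with `short_hom_fraction`.
#' @export
longevity_screen <- function(table, short_group, long_group,
                             min_hom_fraction = 1.0) {
  check_groups(table, short_group, long_group)
  if (min_hom_fraction < 0 || min_hom_fraction > 1) {
    stop_loadfit("min_hom_fraction must lie in [0, 1]", "loadfit_input_error")
  }
  sg <- lof_geno(table, short_group)
  lg <- table$geno[sg$idx, long_group, drop = FALSE]
  no_long_hom <- rowSums(lg == 2L, na.rm = TRUE) == 0L
  hom_frac <- rowSums(sg$g == 2L, na.rm = TRUE) / length(short_group)
  pass <- no_long_hom & hom_frac >= min_hom_fraction
  out <- table$sites[sg$idx[pass], , drop = FALSE]
  out$short_hom_fraction <- hom_frac[pass]
  out <- out[order(-out$short_hom_fraction, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher-exact overrepresentation test
#'
#' For each term in a gene-to-term map, tests whether candidate genes are
#' enriched for the term relative to a gene universe, using the one-sided
#' hypergeometric tail (equivalent to a one-sided Fisher exact test on the
#' 2x2 table), with Bonferroni adjustment.
#'
#' @param candidate_genes character vector, a subset of `universe_genes`.
#' @param universe_genes character vector of all scorable genes.
#' @param term_map data.frame with columns `gene_id` and `term_id` (a gene
#'   may map to any number of terms).
#' @param skip_zero_hit if TRUE (default) terms with no candidate hit are not
#'   tested (p reported as NA).
#' @param bonferroni_n `"tested"` (default): adjust by the number of terms
#'   actually tested; `"all"`: adjust by the total number of terms.
#' @return data.frame with one row per term: term_id, n_term (term genes in
#'   the universe), n_candidates, overlap, p_value, p_bonferroni.
#' @export
overrepresentation_test <- function(candidate_genes, universe_genes, term_map,
                                    skip_zero_hit = TRUE,
                                    bonferroni_n = c("tested", "all")) {
  bonferroni_n <- match.arg(bonferroni_n)
  universe_genes <- unique(universe_genes)
  candidate_genes <- unique(candidate_genes)
  if (length(universe_genes) == 0) stop_loadfit("empty gene universe", "loadfit_input_error")
  if (!all(candidate_genes %in% universe_genes)) {
    stop_loadfit("candidate_genes must be a subset of universe_genes", "loadfit_input_error")
  }
  if (!all(c("gene_id", "term_id") %in% names(term_map))) {
    stop_loadfit("term_map needs columns gene_id and term_id", "loadfit_input_error")
  }
  tm <- term_map[term_map$gene_id %in% universe_genes, , drop = FALSE]
  terms <- sort(unique(tm$term_id))
  N <- length(universe_genes)
  m <- length(candidate_genes)
  rows <- lapply(terms, function(tt) {
    genes <- unique(tm$gene_id[tm$term_id == tt])
    K <- length(genes)
    k <- length(intersect(genes, candidate_genes))
    data.frame(term_id = tt, n_term = K, n_candidates = m, overlap = k,
               p_value = if (k == 0 && skip_zero_hit) NA_real_ else
                 phyper(k - 1, K, N - K, m, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(term_id = character(0), n_term = integer(0),
               n_candidates = integer(0), overlap = integer(0),
               p_value = numeric(0))
  n_adj <- if (bonferroni_n == "tested") sum(!is.na(out$p_value)) else nrow(out)
  out$p_bonferroni <- pmin(1, out$p_value * max(n_adj, 1))
  out[order(out$p_value), , drop = FALSE]
}
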