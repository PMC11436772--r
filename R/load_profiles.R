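# Per-individual mutational load statistics, per-class site frequency
# spectra, heterozygosity per kb, and group gene-pool summaries.

#' Per-individual load profile
#'
#' Computes, for one individual, the allele-level load proportions
#' `p_lof`, `p_mis`, `p_syn` (derived alleles of each impact class over all
#' derived alleles the individual carries at LOF + MISSENSE + SYNONYMOUS
#' sites), the expressed load `e_*` (homozygous-derived genotypes over the
#' scored-site denominator) and the masked load `m_*` (heterozygous
#' genotypes over the same denominator). `OTHER`-impact sites are excluded
#' from all denominators.
#'
#' @param table a filtered [variant_table] (see [apply_site_filters()]).
#' @param individual sample name.
#' @param denominator `"all_sites"` (default): all retained annotated sites,
#'   constant across individuals after the complete-call filter;
#'   `"carrier_sites"`: only sites where the individual carries at least one
#'   derived allele.
#' @return named list with `n_sites_scored`, `p_lof`, `p_mis`, `p_syn`,
#'   `e_lof`, `e_mis`, `e_syn`, `m_lof`, `m_mis`, `m_syn`. Allele-level
#'   proportions are `NA` (with a warning) for an individual carrying no
#'   derived allele.
#' @export
compute_load_profile <- function(table, individual,
                                 denominator = c("all_sites", "carrier_sites")) {
  stopifnot(inherits(table, "variant_table"))
  denominator <- match.arg(denominator)
  if (!individual %in% table$samples) {
    stop_loadfit(paste0("unknown individual: ", individual), "loadfit_input_error")
  }
  annot <- table$sites$impact %in% c("LOF", "MISSENSE", "SYNONYMOUS")
  g <- table$geno[annot, individual]
  cls <- table$sites$impact[annot]
  n_scored <- length(g)
  der <- vapply(c("LOF", "MISSENSE", "SYNONYMOUS"),
                function(k) sum(g[cls == k], na.rm = TRUE), numeric(1))
  hom <- vapply(c("LOF", "MISSENSE", "SYNONYMOUS"),
                function(k) sum(g[cls == k] == 2L, na.rm = TRUE), numeric(1))
  het <- vapply(c("LOF", "MISSENSE", "SYNONYMOUS"),
                function(k) sum(g[cls == k] == 1L, na.rm = TRUE), numeric(1))
  tot_der <- sum(der)
  if (tot_der == 0) {
    warning(sprintf("individual %s carries no derived allele at scored sites; allele-load proportions are NA",
                    individual), call. = FALSE)
    p <- c(NA_real_, NA_real_, NA_real_)
  } else {
    p <- unname(der / tot_der)
  }
  denom <- if (denominator == "all_sites") n_scored else sum(g > 0L, na.rm = TRUE)
  e <- if (denom > 0) unname(hom / denom) else rep(NA_real_, 3)
  m <- if (denom > 0) unname(het / denom) else rep(NA_real_, 3)
  list(n_sites_scored = n_scored,
       p_lof = p[1], p_mis = p[2], p_syn = p[3],
       e_lof = e[1], e_mis = e[2], e_syn = e[3],
       m_lof = m[1], m_mis = m[2], m_syn = m[3])
}

#' Load profiles for every individual
#'
#' @inheritParams compute_load_profile
#' @param callable_length_bp callable genome length in bp used for
#'   [heterozygosity_per_kb()]; heterozygosity counts heterozygous genotypes
#'   across *all* sites in the table, coding and non-coding.
#' @return data.frame with one row per individual and columns id,
#'   n_sites_scored, p_lof, p_mis, p_syn, e_lof, e_mis, e_syn, m_lof, m_mis,
#'   m_syn, het_per_kb.
#' @export
compute_load_profiles <- function(table, callable_length_bp,
                                  denominator = c("all_sites", "carrier_sites")) {
  denominator <- match.arg(denominator)
  rows <- lapply(table$samples, function(id) {
    pr <- compute_load_profile(table, id, denominator)
    pr$het_per_kb <- heterozygosity_per_kb(table, id, callable_length_bp)
    c(list(id = id), pr)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Heterozygous sites per kb
#'
#' Genome-wide heterozygosity of one individual: heterozygous genotypes
#' across all sites (regardless of impact class) times 1000, divided by the
#' callable sequence length in bp.
#'
#' @inheritParams compute_load_profile
#' @param callable_length_bp callable sequence length in bp; must be > 0.
#' @return scalar heterozygous sites per 1 kb.
#' @export
heterozygosity_per_kb <- function(table, individual, callable_length_bp) {
  if (!is.numeric(callable_length_bp) || length(callable_length_bp) != 1 ||
      is.na(callable_length_bp) || callable_length_bp <= 0) {
    stop_loadfit("callable_length_bp must be a positive scalar", "loadfit_input_error")
  }
  if (!individual %in% table$samples) {
    stop_loadfit(paste0("unknown individual: ", individual), "loadfit_input_error")
  }
  sum(table$geno[, individual] == 1L, na.rm = TRUE) * 1000 / callable_length_bp
}

#' Site frequency spectrum of one impact class
#'
#' Tallies derived-allele counts (ALT treated as derived) of the retained
#' sites of a class into unfolded bins 1..(2N-1), N = number of individuals.
#'
#' @param table a filtered [variant_table].
#' @param category one of `"LOF"`, `"MISSENSE"`, `"SYNONYMOUS"`, `"OTHER"`.
#' @return object of class `sfs`: list with `category`, `n` (individuals),
#'   `counts` (named integer vector over bins 1..2N-1), and
#'   `mean_derived_freq` (mean derived-allele frequency over segregating
#'   sites of the class, `NA` if none).
#' @export
compute_sfs <- function(table, category = c("LOF", "MISSENSE", "SYNONYMOUS", "OTHER")) {
  category <- match.arg(category)
  n <- length(table$samples)
  bins <- seq_len(2L * n - 1L)
  idx <- which(table$sites$impact == category)
  dac <- rowSums(table$geno[idx, , drop = FALSE], na.rm = TRUE)
  dac <- dac[dac >= 1 & dac <= 2 * n - 1]
  counts <- setNames(integer(length(bins)), bins)
  if (length(dac)) {
    tt <- table(factor(dac, levels = bins))
    counts[] <- as.integer(tt)
  }
  structure(list(category = category, n = n, counts = counts,
                 mean_derived_freq = if (length(dac)) mean(dac / (2 * n)) else NA_real_),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<sfs> %s: %d segregating sites over %d individuals; mean derived freq %.4f\n",
              x$category, sum(x$counts), x$n, x$mean_derived_freq))
  invisible(x)
}

#' Percent excess of one count over another
#'
#' `100 * (n_b - n_a) / n_a`, reported to one decimal place.
#' @param n_a,n_b non-negative counts; `n_a` must be > 0.
#' @return scalar percent, rounded to one decimal.
#' @export
percent_excess <- function(n_a, n_b) {
  if (n_a <= 0) stop_loadfit("reference count must be > 0", "loadfit_input_error")
  round(100 * (n_b - n_a) / n_a, 1)
}

#' Gene-pool LoF summary for two groups
#'
#' A LoF site belongs to a group's gene pool if at least one group member
#' carries at least one derived allele. Reports the per-group LoF site
#' counts, the sites private to each group, and the percent excess of group
#' B over group A.
#'
#' @param table a filtered [variant_table].
#' @param group_assignment named character vector or factor mapping every
#'   individual in `table$samples` to exactly one of two group labels.
#' @return list with `groups`, `n_lof` (named counts), `private` (named
#'   counts of sites private to each group), `private_sites` (list of site
#'   data.frames) and `percent_excess_b_over_a`.
#' @export
gene_pool_lof_summary <- function(table, group_assignment) {
  ga <- group_assignment[table$samples]
  if (anyNA(ga)) stop_loadfit("every individual must be assigned to a group", "loadfit_input_error")
  groups <- sort(unique(as.character(ga)))
  if (length(groups) != 2) stop_loadfit("exactly two groups are required", "loadfit_input_error")
  if (!all(table(ga) > 0)) stop_loadfit("empty group", "loadfit_input_error")
  lof <- which(table$sites$impact == "LOF")
  g <- table$geno[lof, , drop = FALSE]
  in_pool <- function(grp) rowSums(g[, ga == grp, drop = FALSE] > 0L, na.rm = TRUE) > 0L
  pa <- in_pool(groups[1]); pb <- in_pool(groups[2])
  n_lof <- setNames(c(sum(pa), sum(pb)), groups)
  if (n_lof[1] == 0) stop_loadfit(
    paste0("group ", groups[1], " has an empty LoF gene pool"), "loadfit_input_error")
  list(groups = groups,
       n_lof = n_lof,
       private = setNames(c(sum(pa & !pb), sum(pb & !pa)), groups),
       private_sites = setNames(list(table$sites[lof[pa & !pb], , drop = FALSE],
                                     table$sites[lof[pb & !pa], , drop = FALSE]),
                                groups),
       percent_excess_b_over_a = percent_excess(n_lof[[1]], n_lof[[2]]))
}
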