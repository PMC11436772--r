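# Container for impact-annotated biallelic sites x individual genotypes.
# Genotypes are coded 0 = hom_ref, 1 = het, 2 = hom_alt, NA = missing; the
# ALT allele is treated as the derived allele throughout.

#' Construct a variant table
#'
#' @param sites data.frame with columns chrom, pos (1-based), ref, alt,
#'   impact (one of LOF, MISSENSE, SYNONYMOUS, OTHER) and gene.
#' @param geno integer matrix, sites x individuals, coded 0/1/2/NA.
#' @param samples character vector of sample names (columns of `geno`).
#' @return object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, samples) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "impact", "gene") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites),
            ncol(geno) == length(samples))
  if (!all(sites$impact %in% IMPACT_LEVELS)) {
    stop_loadfit("impact must be one of LOF, MISSENSE, SYNONYMOUS, OTHER",
                 "loadfit_input_error")
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop_loadfit("genotype codes must be 0, 1, 2 or NA", "loadfit_input_error")
  storage.mode(geno) <- "integer"
  rownames(geno) <- NULL
  colnames(geno) <- samples
  structure(list(sites = sites, geno = geno, samples = unname(samples)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d sites x %d individuals\n",
              nrow(x$sites), length(x$samples)))
  print(table(factor(x$sites$impact, levels = IMPACT_LEVELS)))
  invisible(x)
}

# map a SnpEff impact word to the load category
impact_to_category <- function(impact) {
  switch(impact,
         HIGH = "LOF",
         MODERATE = "MISSENSE",
         LOW = "SYNONYMOUS",
         "OTHER")
}

# Parse the ANN INFO entry of one record and return, for the given ALT
# allele, list(category, gene) using SnpEff field order
# Allele|Annotation|Annotation_Impact|Gene_Name|... Only fields 1-4 are used.
parse_ann_for_alt <- function(info, alt) {
  info <- as.vector(info)  # row subsets of a vcfR fix matrix carry names,
  alt <- as.vector(alt)    # which would defeat identical() below
  m <- regmatches(info, regexpr("(?:^|;)ANN=([^;]*)", info, perl = TRUE))
  if (length(m) == 0) return(NULL)
  ann <- sub("^;?ANN=", "", m)
  entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
  for (e in entries) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(f) >= 3 && identical(f[1], alt)) {
      gene <- if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_
      return(list(category = impact_to_category(f[3]), gene = gene))
    }
  }
  NULL
}

#' Read an impact-annotated multi-sample VCF
#'
#' Reads a VCF v4.2 (plain or gzipped) whose INFO field carries SnpEff-style
#' `ANN=Allele|Annotation|Impact|Gene|...` annotations, and returns a
#' [variant_table]. Multiallelic records are split into one biallelic record
#' per ALT allele, each carrying the ANN entry matching that allele; the
#' genotype relative to ALT allele *a* is the number of copies of *a*
#' (other ALT alleles count toward the reference class). Sites without a
#' parseable impact annotation are kept with category `OTHER` and a warning.
#'
#' @param path path to the VCF file.
#' @param required_samples optional character vector; an error lists any that
#'   are absent from the file.
#' @return a [variant_table].
#' @export
read_annotated_vcf <- function(path, required_samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  samples <- colnames(v@gt)[-1]
  if (!is.null(required_samples)) {
    missing <- setdiff(required_samples, samples)
    if (length(missing)) {
      stop_loadfit(paste0("samples missing from VCF: ",
                          paste(missing, collapse = ", ")),
                   "loadfit_input_error")
    }
  }
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0) {
    return(variant_table(
      data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
                 alt = character(0), impact = character(0), gene = character(0),
                 stringsAsFactors = FALSE),
      matrix(integer(0), 0, length(samples)), samples))
  }
  gt_raw <- v@gt[, -1, drop = FALSE]
  # strip FORMAT fields beyond GT
  gt <- sub(":.*$", "", gt_raw)

  n_unparsed <- 0L
  ann_of <- function(info, alt) {
    ann <- parse_ann_for_alt(info %||% "", alt)
    if (is.null(ann)) {
      n_unparsed <<- n_unparsed + 1L
      ann <- list(category = "OTHER", gene = NA_character_)
    }
    ann
  }

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)

  # fast path: biallelic records, diploid GT lookup
  bi <- which(!multi)
  bi_sites <- NULL; bi_geno <- NULL
  if (length(bi)) {
    lut <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
    bi_geno <- matrix(lut[gt[bi, , drop = FALSE]], nrow = length(bi),
                      dimnames = NULL)
    anns <- lapply(bi, function(r) ann_of(fix[r, "INFO"], fix[r, "ALT"]))
    bi_sites <- data.frame(
      chrom = fix[bi, "CHROM"], pos = as.numeric(fix[bi, "POS"]),
      ref = fix[bi, "REF"], alt = fix[bi, "ALT"],
      impact = vapply(anns, `[[`, character(1), "category"),
      gene = vapply(anns, `[[`, character(1), "gene"),
      stringsAsFactors = FALSE)
  }

  # per-record path: split multiallelic records into one row per ALT
  mu_sites <- list(); mu_geno <- list()
  for (r in which(multi)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[r, ], "[/|]")
    for (ai in seq_along(alts)) {
      ann <- ann_of(fix[r, "INFO"], alts[ai])
      gvec <- vapply(alleles, function(a) {
        if (any(a == ".") || length(a) == 0) return(NA_integer_)
        sum(a == as.character(ai))
      }, integer(1))
      mu_sites[[length(mu_sites) + 1L]] <- data.frame(
        chrom = fix[r, "CHROM"], pos = as.numeric(fix[r, "POS"]),
        ref = fix[r, "REF"], alt = alts[ai], impact = ann$category,
        gene = ann$gene, stringsAsFactors = FALSE)
      mu_geno[[length(mu_geno) + 1L]] <- gvec
    }
  }

  sites <- rbind(bi_sites, if (length(mu_sites)) do.call(rbind, mu_sites))
  geno <- rbind(bi_geno, if (length(mu_geno)) do.call(rbind, mu_geno))
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL
  if (n_unparsed > 0) {
    warning(sprintf("%d ALT allele(s) had no parseable ANN impact annotation; categorised as OTHER",
                    n_unparsed), call. = FALSE)
  }
  variant_table(sites, geno, samples)
}

#' Apply the study's site filters
#'
#' Retains exactly the sites that are (a) called in every individual (no
#' missing genotype) and (b) segregating: at least one individual carries the
#' derived (ALT) allele and not every individual is homozygous for it. Sites
#' where every genotype is hom_ref are dropped under the same
#' non-segregating rule; a site where every individual is heterozygous is
#' retained.
#'
#' @param table a [variant_table].
#' @return the filtered [variant_table], with an attribute `removal_log`
#'   (named integer vector: `missing`, `fixed`) reporting counts removed per
#'   rule. A site failing both rules is counted under `missing`.
#' @export
apply_site_filters <- function(table) {
  stopifnot(inherits(table, "variant_table"))
  g <- table$geno
  if (nrow(g) == 0) {
    attr(table, "removal_log") <- c(missing = 0L, fixed = 0L)
    return(table)
  }
  has_missing <- apply(g, 1, anyNA)
  all_hom_alt <- rowSums(g == 2L, na.rm = TRUE) == ncol(g) & !has_missing
  no_carrier <- rowSums(g > 0L, na.rm = TRUE) == 0L & !has_missing
  keep <- !has_missing & !all_hom_alt & !no_carrier
  out <- variant_table(table$sites[keep, , drop = FALSE],
                       g[keep, , drop = FALSE], table$samples)
  out$sites <- droplevels(out$sites)
  rownames(out$sites) <- NULL
  attr(out, "removal_log") <- c(missing = sum(has_missing),
                                fixed = sum(all_hom_alt | no_carrier))
  out
}
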