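# Writers for simulator results: VCF v4.2 with ANN-dialect annotations, and
# tab-delimited pedigree / fitness / litter / truth tables. All output is
# plain text with a fixed column order and no timestamps, so a fixed seed
# yields byte-identical files.

ann_term <- c(LOF = "stop_gained", MISSENSE = "missense_variant",
              SYNONYMOUS = "synonymous_variant", OTHER = "intergenic_region")
ann_impact <- c(LOF = "HIGH", MISSENSE = "MODERATE", SYNONYMOUS = "LOW",
                OTHER = "MODIFIER")

geno_to_gt <- c("0/0", "0/1", "1/1")

write_sim_vcf <- function(vt, path, genome_length) {
  sites <- vt$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=loadfit_simulator",
    sprintf("##contig=<ID=%s,length=%d>", sites$chrom[1] %||% "chr1",
            as.integer(genome_length)),
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID'\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t"))
  gene <- ifelse(is.na(sites$gene), "", sites$gene)
  info <- sprintf("ANN=%s|%s|%s|%s|%s", sites$alt, ann_term[sites$impact],
                  ann_impact[sites$impact], gene, gene)
  gtm <- matrix(geno_to_gt[vt$geno + 1L], nrow = nrow(vt$geno))
  gtm[is.na(vt$geno)] <- "./."
  body <- paste(sites$chrom, as.integer(sites$pos), ".", sites$ref, sites$alt,
                ".", "PASS", info, "GT",
                apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

write_tsv <- function(df, path) {
  # numeric columns at full precision, NA as literal "NA"
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE,
                     nsmall = 0),
              con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA",
              eol = "\n")
  invisible(path)
}

#' Write simulator outputs
#'
#' Writes the files downstream stages consume: `sim.vcf` (VCF v4.2 with
#' SnpEff-style ANN annotations, one impact string per ALT allele),
#' `pedigree.tsv`, `fitness.tsv` (id, sex, ancestry_class, natal_den,
#' rodent_phase, juvenile_survival, longevity_years, lrs, mean_litter_size),
#' `litters.tsv` and `truth.tsv` (the simulator's per-individual generative
#' covariates). Tables are tab-delimited with a header row, UTF-8, `NA` for
#' missing values.
#'
#' @param sim a `loadfit_sim` result from [simulate_population()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(sim, out_dir) {
  stopifnot(inherits(sim, "loadfit_sim"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_loadfit(paste0("cannot create output directory: ", out_dir),
                          "loadfit_io_error")
  }
  paths <- c(
    vcf = file.path(out_dir, "sim.vcf"),
    pedigree = file.path(out_dir, "pedigree.tsv"),
    fitness = file.path(out_dir, "fitness.tsv"),
    litters = file.path(out_dir, "litters.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_sim_vcf(sim$variants, paths[["vcf"]], sim$config$genome_length)
  write_tsv(sim$pedigree, paths[["pedigree"]])
  write_tsv(sim$fitness, paths[["fitness"]])
  write_tsv(sim$litters, paths[["litters"]])
  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
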