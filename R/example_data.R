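# Bundled summary tables from the long-term arctic fox monitoring study:
# printed group means of litter size, life span and lifetime reproductive
# success per ancestry class, and the LoF gene-pool counts of the native vs
# admixed ("hybrid") gene pools. These are inputs for the worked-example
# contrast computations.

#' Published ancestry-class trait means
#'
#' Group means of litter size (per pair combination), life span and LRS (per
#' individual ancestry class) from a long-term monitoring study of an
#' endangered Scandinavian arctic fox population, with sample sizes.
#'
#' @return data.frame with columns table, group, trait, mean, n.
#' @export
ancestry_trait_means <- function() {
  read.delim(system.file("extdata", "ancestry_trait_means.tsv",
                         package = "loadfit"),
             stringsAsFactors = FALSE)
}

#' Published LoF gene-pool counts
#'
#' Numbers of loss-of-function variant sites present in the native and in the
#' admixed (hybrid) gene pools of the same study population.
#'
#' @return named numeric vector with elements `native` and `hybrid`.
#' @export
lof_gene_pool_counts <- function() {
  df <- read.delim(system.file("extdata", "lof_gene_pool_counts.tsv",
                               package = "loadfit"),
                   stringsAsFactors = FALSE)
  setNames(df$n_lof, df$group)
}

#' Worked-example contrasts from the published group means
#'
#' Recomputes the headline descriptive contrasts from the bundled summary
#' tables: the LRS and life-span differences between first-generation
#' immigrant offspring (F1) and pooled F2+F3 descendants, the litter-size
#' difference between purebred native pairs and native backcross pairs, and
#' the percent excess of LoF sites in the hybrid over the native gene pool.
#'
#' @return named numeric vector with elements `lrs_f1_minus_f2f3_cubs`,
#'   `lifespan_f1_minus_f2f3_years`, `litter_native_minus_backcross_cubs`,
#'   `lof_excess_hybrid_percent`.
#' @export
worked_example_contrasts <- function() {
  tm <- ancestry_trait_means()
  pick <- function(tab, trait) {
    d <- tm[tm$table == tab & tm$trait == trait, ]
    setNames(d$mean, d$group)
  }
  lrs <- group_mean_contrast(pick("individuals", "lrs"), groups = c("F1", "F2F3"))
  lsp <- group_mean_contrast(pick("individuals", "life_span"), groups = c("F1", "F2F3"))
  lit <- group_mean_contrast(pick("litters", "litter_size"),
                             groups = c("native_x_native", "native_x_immigrantF14"))
  cnt <- lof_gene_pool_counts()
  c(lrs_f1_minus_f2f3_cubs = lrs$difference,
    lifespan_f1_minus_f2f3_years = lsp$difference,
    litter_native_minus_backcross_cubs = lit$difference,
    lof_excess_hybrid_percent = percent_excess(cnt[["native"]], cnt[["hybrid"]]))
}
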