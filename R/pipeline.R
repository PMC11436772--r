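# Pipeline orchestration: simulate -> load -> fit -> screen from a single
# validated configuration, with one log line per stage and a machine-readable
# report.json. All randomness flows from config$seed.

#' Validate a pipeline run configuration
#'
#' The configuration is a named list (or a YAML file with the same structure):
#' \preformatted{
#' seed: 1                      # integer, required
#' out_dir: "results"           # required
#' callable_length_bp: 1e6      # required unless a simulate block supplies it
#' load_denominator: all_sites  # or carrier_sites
#' simulate:                    # EITHER a simulate block (sim_config overrides)
#'   n_generations: 12
#' inputs:                      # OR paths to existing inputs
#'   vcf: "calls.vcf"
#'   metadata: "fitness.tsv"
#'   litters: "litters.tsv"     # optional
#'   terms: "terms.tsv"         # optional gene_id/term_id map
#' screen:
#'   freq_threshold: 0.20
#'   min_hom_fraction: 0.4
#'   n_extreme: 4               # group size for the litter screen
#'   short_max_years: 3         # short-lived group upper bound
#'   long_min_years: 4          # long-lived group lower bound
#' log_level: info              # or quiet
#' }
#' Referenced input files must exist at validation time; the seed is recorded
#' in the report.
#'
#' @param config named list or path to a YAML file.
#' @return the normalized configuration (class `run_config`).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_loadfit(
      paste0("config file not found: ", config), "loadfit_config_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_loadfit("config must be a list or a YAML path",
                                     "loadfit_config_error")
  fail <- function(msg) stop_loadfit(paste0("invalid run config: ", msg),
                                     "loadfit_config_error")
  if (is.null(config$seed) || !is.finite(config$seed)) fail("seed is required")
  config$seed <- as.integer(config$seed)
  if (is.null(config$out_dir)) fail("out_dir is required")
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) fail("either a simulate block or an inputs block is required")
  if (has_sim && has_inputs) fail("provide either simulate or inputs, not both")
  if (has_inputs) {
    for (f in c("vcf", "metadata")) {
      if (is.null(config$inputs[[f]])) fail(paste0("inputs$", f, " is required"))
      if (!file.exists(config$inputs[[f]])) fail(
        paste0("inputs$", f, " not found: ", config$inputs[[f]]))
    }
    for (f in c("litters", "terms")) {
      if (!is.null(config$inputs[[f]]) && !file.exists(config$inputs[[f]])) {
        fail(paste0("inputs$", f, " not found: ", config$inputs[[f]]))
      }
    }
    if (is.null(config$callable_length_bp)) fail(
      "callable_length_bp is required when inputs are supplied")
  }
  config$load_denominator <- match.arg(config$load_denominator %||% "all_sites",
                                       c("all_sites", "carrier_sites"))
  sc <- config$screen %||% list()
  config$screen <- list(
    freq_threshold = sc$freq_threshold %||% 0.20,
    min_hom_fraction = sc$min_hom_fraction %||% 0.4,
    n_extreme = sc$n_extreme %||% 4,
    short_max_years = sc$short_max_years %||% 3,
    long_min_years = sc$long_min_years %||% 4)
  config$log_level <- config$log_level %||% "info"
  structure(config, class = c("run_config", "list"))
}

pipe_log <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet")) {
    message(sprintf(paste0("[loadfit] ", fmt), ...))
  }
}

# short stable fingerprint of the configuration (order-independent for lists)
config_fingerprint <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

model_result_to_list <- function(mr) {
  if (inherits(mr, "model_result")) {
    out <- list(family = mr$family, response = mr$response, n = mr$n,
                r_squared = mr$r_squared, terms = mr$terms)
    if (!is.null(mr$extra$varcomp)) out$varcomp <- as.list(mr$extra$varcomp)
    out
  } else if (is.character(mr) && length(mr) == 1) {
    list(error = mr)
  } else {
    mr
  }
}

pooled_ancestry <- function(a) {
  ifelse(a == "native", "native",
         ifelse(a == "F1", "F1",
                ifelse(a %in% c("F2", "F3", "F4"), "F2F3", NA_character_)))
}

try_model <- function(expr) {
  tryCatch(expr, error = function(e) conditionMessage(e))
}

#' Fit the full model battery
#'
#' Joins per-individual load profiles to the fitness metadata and fits the
#' study's model battery: linear models of sqrt(LRS), log(longevity) and mean
#' litter size on each genomic predictor (adults only), binomial GLMs of
#' juvenile survival, Mann-Whitney comparisons of allele-level load between
#' natives and immigrant descendants, heterozygosity-load correlations, and
#' the random-intercept LMMs of the ancestry contrasts (individuals and, when
#' a litter table is supplied, litters). P values are not adjusted for
#' multiple testing across the battery. Models that cannot be fitted on the
#' supplied data are reported as an error message, not an abort.
#'
#' @param profiles load-profile data.frame from [compute_load_profiles()].
#' @param metadata fitness/metadata data.frame (id, sex, ancestry_class,
#'   natal_den, rodent_phase, juvenile_survival, longevity_years, lrs,
#'   mean_litter_size).
#' @param litters optional litter table (den, year, rodent_phase,
#'   pair_combination, litter_size).
#' @return list with `models` (named list of [model_result] objects or error
#'   strings), `group_summary` (Table-1 style group means), `genomes` (the
#'   joined table) and `adults` (its adult subset).
#' @export
fit_model_battery <- function(profiles, metadata, litters = NULL) {
  genomes <- merge(profiles, metadata, by = "id")
  adults <- genomes[!is.na(genomes$longevity_years) & genomes$longevity_years > 0, ]

  models <- list()
  for (resp in c("lrs_sqrt", "longevity_log", "litter_size")) {
    for (pred in c("e_lof", "m_lof", "e_mis", "e_syn", "het_per_kb")) {
      models[[paste(resp, pred, sep = "__")]] <-
        try_model(fit_trait_lm(adults, resp, pred))
    }
  }
  for (pred in c("e_lof", "m_lof", "e_mis", "e_syn", "het_per_kb")) {
    models[[paste("juvenile_survival", pred, sep = "__")]] <-
      try_model(fit_juvenile_survival_glm(genomes, pred))
  }

  anc <- ifelse(genomes$ancestry_class == "native", "native", "hybrid")
  mw <- lapply(c("p_lof", "p_mis", "p_syn"), function(p) {
    try_model(mann_whitney_groups(genomes[[p]][anc == "hybrid"],
                                  genomes[[p]][anc == "native"]))
  })
  names(mw) <- paste0("mw_hybrid_vs_native_", c("p_lof", "p_mis", "p_syn"))
  cors <- lapply(c("e_syn", "e_mis", "e_lof"), function(p) {
    try_model(correlate(genomes$het_per_kb, genomes[[p]]))
  })
  names(cors) <- paste0("cor_het_", c("e_syn", "e_mis", "e_lof"))

  metadata$ancestry_group <- pooled_ancestry(metadata$ancestry_class)
  meta_adults <- metadata[!is.na(metadata$longevity_years) &
                            metadata$longevity_years > 0 &
                            !is.na(metadata$ancestry_group), ]
  lmm <- list(
    lmm_lrs = try_model(fit_ancestry_lmm(meta_adults, "lrs_sqrt", "ancestry_group",
                                         fixed = c("sex", "rodent_phase"),
                                         reference = "native")),
    lmm_longevity = try_model(fit_ancestry_lmm(meta_adults, "longevity_log",
                                               "ancestry_group",
                                               fixed = c("sex", "rodent_phase"),
                                               reference = "native")))
  if (!is.null(litters) && nrow(litters) >= 8 &&
      length(unique(litters$den)) >= 2) {
    lmm$lmm_litter_size <- try_model(fit_ancestry_lmm(
      litters, "litter_size", "pair_combination", fixed = "rodent_phase",
      random = "den", reference = "native_x_native"))
  }

  # Table-1 style descriptive summary per ancestry class / pair combination
  grp_mean <- function(x, g) tapply(x, g, function(v) mean(v, na.rm = TRUE))
  summary_tbl <- list(
    lrs = as.list(round(grp_mean(meta_adults$lrs, meta_adults$ancestry_group), 2)),
    life_span = as.list(round(grp_mean(meta_adults$longevity_years,
                                       meta_adults$ancestry_group), 2)),
    n_adults = as.list(table(meta_adults$ancestry_group)))
  if (!is.null(litters) && nrow(litters)) {
    summary_tbl$litter_size <- as.list(round(grp_mean(litters$litter_size,
                                                      litters$pair_combination), 2))
    summary_tbl$n_litters <- as.list(table(litters$pair_combination))
  }

  list(models = c(models, mw, cors, lmm), group_summary = summary_tbl,
       genomes = genomes, adults = adults)
}

#' Run the candidate-variant screens
#'
#' Applies the ancestry, litter-size and longevity zygosity screens to a
#' filtered variant table, using per-individual metadata to form the contrast
#' groups, and (optionally) tests the union of screen hits for functional-term
#' overrepresentation. Screens whose contrast groups cannot be formed from the
#' available individuals are silently omitted.
#'
#' @param table a filtered [variant_table].
#' @param genomes data.frame with one row per sequenced individual: `id` (in
#'   `table$samples`), `ancestry_class`, `mean_litter_size`, `longevity_years`.
#' @param thresholds named list of screen settings: `freq_threshold` (ancestry
#'   screen), `min_hom_fraction` (relaxed longevity screen), `n_extreme`
#'   (litter-screen group size), `short_max_years`, `long_min_years`. Missing
#'   entries take the [validate_run_config()] defaults.
#' @param term_map optional gene_id/term_id data.frame for
#'   [overrepresentation_test()].
#' @return list with `screens` (named list of screen result data.frames,
#'   including `gene_pool` when both ancestry groups are present) and
#'   `enrichment` (data.frame or NULL).
#' @export
screen_battery <- function(table, genomes, thresholds = list(), term_map = NULL) {
  scr <- list(
    freq_threshold = thresholds$freq_threshold %||% 0.20,
    min_hom_fraction = thresholds$min_hom_fraction %||% 0.4,
    n_extreme = thresholds$n_extreme %||% 4,
    short_max_years = thresholds$short_max_years %||% 3,
    long_min_years = thresholds$long_min_years %||% 4)
  vs <- intersect(table$samples, genomes$id)
  ganc <- setNames(ifelse(genomes$ancestry_class == "native", "native", "hybrid"),
                   genomes$id)[vs]
  screens <- list()
  if (all(c("native", "hybrid") %in% ganc)) {
    screens$ancestry <- hybrid_private_lofs(
      table, vs[ganc == "native"], vs[ganc == "hybrid"], scr$freq_threshold)
    screens$gene_pool <- gene_pool_lof_summary(table, ganc)
  }
  gl <- setNames(genomes$mean_litter_size, genomes$id)[vs]
  with_lit <- vs[!is.na(gl)]
  if (length(with_lit) >= 2 * scr$n_extreme) {
    ordl <- with_lit[order(gl[with_lit])]
    screens$litter <- litter_size_screen(
      table, head(ordl, scr$n_extreme), utils::tail(ordl, scr$n_extreme))
  }
  glon <- setNames(genomes$longevity_years, genomes$id)[vs]
  short <- vs[!is.na(glon) & glon <= scr$short_max_years]
  long <- vs[!is.na(glon) & glon >= scr$long_min_years]
  if (length(short) >= 1 && length(long) >= 1) {
    screens$longevity_strict <- longevity_screen(table, short, long, 1.0)
    screens$longevity_relaxed <- longevity_screen(table, short, long,
                                                  scr$min_hom_fraction)
  }
  enrichment <- NULL
  if (!is.null(term_map)) {
    universe <- unique(stats::na.omit(table$sites$gene))
    cand <- unique(stats::na.omit(unlist(lapply(
      screens[setdiff(names(screens), "gene_pool")], function(s) s$gene))))
    cand <- intersect(cand, universe)
    if (length(cand)) {
      enrichment <- overrepresentation_test(cand, universe, term_map)
    }
  }
  list(screens = screens, enrichment = enrichment)
}

#' Run the full pipeline
#'
#' Executes simulate (optional), load, fit and screen in order, writing stage
#' outputs and a `report.json` under `config$out_dir`. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config a run configuration (list, YAML path, or `run_config`); see
#'   [validate_run_config()].
#' @return the report, invisibly (a named list mirroring report.json).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, run_pipeline_impl(config))
}

run_pipeline_impl <- function(config) {
  report <- list(
    loadfit_version = as.character(packageVersion("loadfit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_fingerprint = config_fingerprint(config),
    stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_loadfit(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   "loadfit_stage_error")
    })
  }

  ## -- simulate ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate
      args$seed <- config$seed
      do.call(sim_config, args)
    })
    simres <- stage("simulate", simulate_population(sim))
    sim_dir <- file.path(config$out_dir, "sim")
    paths <- stage("simulate", write_outputs(simres, sim_dir))
    config$inputs <- list(vcf = paths[["vcf"]], metadata = paths[["fitness"]],
                          litters = paths[["litters"]])
    config$callable_length_bp <- config$callable_length_bp %||% sim$genome_length
    report$stages$simulate <- list(
      n_individuals = nrow(simres$fitness), n_litters = nrow(simres$litters),
      n_sites = nrow(simres$variants$sites),
      n_sampled_genomes = length(simres$variants$samples))
    pipe_log(config, "simulate: %d individuals, %d litters, %d sites",
             nrow(simres$fitness), nrow(simres$litters),
             nrow(simres$variants$sites))
  }

  ## -- load --------------------------------------------------------------
  vt_raw <- stage("load", read_annotated_vcf(config$inputs$vcf))
  vt <- stage("load", apply_site_filters(vt_raw))
  profiles <- stage("load", compute_load_profiles(
    vt, config$callable_length_bp, denominator = config$load_denominator))
  sfs_list <- lapply(c("LOF", "MISSENSE", "SYNONYMOUS"),
                     function(k) compute_sfs(vt, k))
  names(sfs_list) <- c("LOF", "MISSENSE", "SYNONYMOUS")
  write_tsv(profiles, file.path(config$out_dir, "load_profiles.tsv"))
  for (k in names(sfs_list)) {
    write_tsv(data.frame(derived_count = as.integer(names(sfs_list[[k]]$counts)),
                         n_sites = as.integer(sfs_list[[k]]$counts)),
              file.path(config$out_dir, paste0("sfs_", tolower(k), ".tsv")))
  }
  rl <- attr(vt, "removal_log")
  report$stages$load <- list(
    n_sites_raw = nrow(vt_raw$sites), n_sites_retained = nrow(vt$sites),
    removed_missing = unname(rl[["missing"]]), removed_fixed = unname(rl[["fixed"]]),
    n_individuals = length(vt$samples),
    mean_derived_freq = lapply(sfs_list, function(s) s$mean_derived_freq))
  pipe_log(config, "load: %d/%d sites retained (removed %d missing, %d fixed), %d individuals",
           nrow(vt$sites), nrow(vt_raw$sites), rl[["missing"]], rl[["fixed"]],
           length(vt$samples))

  ## -- fit ---------------------------------------------------------------
  meta <- stage("fit", read.delim(config$inputs$metadata, stringsAsFactors = FALSE))
  litters <- if (!is.null(config$inputs$litters)) {
    read.delim(config$inputs$litters, stringsAsFactors = FALSE)
  }
  battery <- stage("fit", fit_model_battery(profiles, meta, litters))
  genomes <- battery$genomes
  adults <- battery$adults
  all_models <- battery$models
  summary_tbl <- battery$group_summary
  jsonlite::write_json(lapply(all_models, model_result_to_list),
                       file.path(config$out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  if (length(summary_tbl$lrs) >= 2) {
    contrasts <- group_mean_contrast(setNames(unlist(summary_tbl$lrs),
                                              names(summary_tbl$lrs)))
    write_tsv(contrasts, file.path(config$out_dir, "contrasts.tsv"))
  }
  report$stages$fit <- list(n_models = length(all_models),
                            n_genomes = nrow(genomes), n_adults = nrow(adults),
                            n_meta = nrow(meta))
  report$models <- lapply(all_models, model_result_to_list)
  report$group_summary <- summary_tbl
  pipe_log(config, "fit: %d models on %d genomes / %d metadata rows",
           length(all_models), nrow(genomes), nrow(meta))

  ## -- screen ------------------------------------------------------------
  term_map <- if (!is.null(config$inputs$terms)) {
    read.delim(config$inputs$terms, stringsAsFactors = FALSE)
  }
  sb <- stage("screen", screen_battery(vt, genomes, config$screen, term_map))
  screens <- sb$screens
  enrichment <- sb$enrichment
  for (nm in setdiff(names(screens), "gene_pool")) {
    write_tsv(screens[[nm]], file.path(config$out_dir, paste0("screen_", nm, ".tsv")))
  }
  if (!is.null(enrichment)) {
    write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  }
  report$stages$screen <- list(
    hits = lapply(screens[setdiff(names(screens), "gene_pool")], nrow),
    gene_pool = if (!is.null(screens$gene_pool)) list(
      n_lof = as.list(screens$gene_pool$n_lof),
      private = as.list(screens$gene_pool$private),
      percent_excess = screens$gene_pool$percent_excess_b_over_a),
    n_terms_tested = if (!is.null(enrichment)) sum(!is.na(enrichment$p_value)),
    min_p_bonferroni = if (!is.null(enrichment)) suppressWarnings(
      min(enrichment$p_bonferroni, na.rm = TRUE)))
  pipe_log(config, "screen: %s",
           paste(names(report$stages$screen$hits),
                 unlist(report$stages$screen$hits), collapse = ", "))

  report$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  pipe_log(config, "report written to %s", file.path(config$out_dir, "report.json"))
  invisible(report)
}
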