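#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_population()]. The
#' defaults emulate a small, re-founded arctic-fox-like population: ~20
#' founders, a carrying capacity of 60 breeding adults, a mid-run immigration
#' event of three outbred males, monogamous den-structured breeding, and a
#' 4-year rodent cycle driving litter sizes. Variant impact classes follow the
#' SnpEff convention: loss-of-function (HIGH, strongly deleterious and nearly
#' recessive), missense (MODERATE, mildly deleterious and partially recessive)
#' and synonymous (LOW, neutral), plus neutral non-coding sites that enter
#' genome-wide heterozygosity but not the load denominators.
#'
#' @param n_founders number of founding adults (year 0).
#' @param n_generations number of breeding years to simulate.
#' @param carrying_capacity maximum number of breeding adults per year.
#' @param genome_length callable genome length in bp (single pseudo-autosomal
#'   chromosome, uniform recombination, one crossover per meiosis).
#' @param founder_sites named count vector `c(lof, mis, syn, neutral)`:
#'   standing variants segregating among founders per impact class.
#' @param mut_rates named rate vector `c(lof, mis, syn, neutral)`: expected
#'   new mutations per diploid genome per generation. Coding defaults are
#'   proportional to segregating counts of 1300 : 44,433 : 86,508 across the
#'   three impact classes.
#' @param s,h named selection and dominance coefficients `c(lof, mis, syn)`.
#'   Viability of a newborn is `prod((1-s*h)^n_het * (1-s)^n_hom)` per class.
#' @param immigration_generation year at which immigrants arrive (`NA` or
#'   a value > `n_generations` disables admixture).
#' @param n_immigrants number of immigrant males added.
#' @param immigrant_source_diversity scalar >= 0 scaling the number of novel
#'   (source-private) variants immigrants may carry; 0 means none.
#' @param beta_lof_lrs,beta_lof_longevity effects of an individual's expressed
#'   (homozygous) LoF genotype proportion on log litter rate and log longevity.
#'   Expressed proportions are small numbers (homozygous sites / all annotated
#'   sites), so magnitudes of hundreds correspond to modest fitness effects.
#' @param beta_het_survival,beta_mis_survival logit-scale effects of
#'   heterozygous sites per kb and of the expressed missense proportion on
#'   first-year survival.
#' @param survival_intercept logit-scale intercept of juvenile survival.
#' @param beta_f1_litter log-scale litter-size boost for native x immigrant
#'   pairs (heterosis switch; 0 disables).
#' @param adult_survival constant annual adult survival probability; adult
#'   lifespan is geometric with this parameter.
#' @param litter_lambda named vector `c(increase, decrease)`: mean conceived
#'   litter size per rodent phase.
#' @param den_effect_sd standard deviation of the per-den random intercept on
#'   the log litter rate (the variance component the litter LMM estimates).
#' @param n_dens number of breeding dens (monogamous pairs per den per year).
#' @param rodent_cycle_period rodent cycle length in years (3-4); the first
#'   half of each cycle is the "increase" phase, the rest "decrease".
#' @param ancestral_ne effective size of the (unsimulated) source population,
#'   used only to tilt founder allele frequencies toward rarity for selected
#'   classes (mutation-selection balance); with `s = 0` founder frequencies
#'   follow the neutral 1/i site frequency spectrum.
#' @param n_sample number of individuals whose genotypes are emitted to the
#'   VCF (the "re-sequenced" subsample; balanced between natives and
#'   immigrant descendants where possible).
#' @param seed integer master seed; all randomness flows from one stream.
#'
#' @return object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_generations = 4, seed = 1)
#' cfg$carrying_capacity
sim_config <- function(n_founders = 20,
                       n_generations = 12,
                       carrying_capacity = 60,
                       genome_length = 1e6,
                       founder_sites = c(lof = 50, mis = 400, syn = 700, neutral = 1500),
                       mut_rates = c(lof = 0.006, mis = 0.2, syn = 0.4, neutral = 0.8),
                       s = c(lof = 0.15, mis = 0.02, syn = 0),
                       h = c(lof = 0.05, mis = 0.1, syn = 0.5),
                       immigration_generation = 6,
                       n_immigrants = 3,
                       immigrant_source_diversity = 1,
                       beta_lof_lrs = -300,
                       beta_lof_longevity = -300,
                       beta_het_survival = 7,
                       beta_mis_survival = -150,
                       survival_intercept = -3,
                       beta_f1_litter = 0.6,
                       adult_survival = 0.6,
                       litter_lambda = c(increase = 7, decrease = 5.5),
                       den_effect_sd = 0.15,
                       n_dens = 30,
                       rodent_cycle_period = 4,
                       ancestral_ne = 500,
                       n_sample = 37,
                       seed = 1L) {
  # YAML-sourced configs supply named lists where named vectors are expected
  founder_sites <- unlist(founder_sites)
  mut_rates <- unlist(mut_rates)
  s <- unlist(s); h <- unlist(h)
  litter_lambda <- unlist(litter_lambda)
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    carrying_capacity = as.integer(carrying_capacity),
    genome_length = as.numeric(genome_length),
    founder_sites = founder_sites,
    mut_rates = mut_rates,
    s = s, h = h,
    immigration_generation = if (is.na(immigration_generation)) NA_integer_ else as.integer(immigration_generation),
    n_immigrants = as.integer(n_immigrants),
    immigrant_source_diversity = as.numeric(immigrant_source_diversity),
    beta_lof_lrs = as.numeric(beta_lof_lrs),
    beta_lof_longevity = as.numeric(beta_lof_longevity),
    beta_het_survival = as.numeric(beta_het_survival),
    beta_mis_survival = as.numeric(beta_mis_survival),
    survival_intercept = as.numeric(survival_intercept),
    beta_f1_litter = as.numeric(beta_f1_litter),
    adult_survival = as.numeric(adult_survival),
    litter_lambda = litter_lambda,
    den_effect_sd = as.numeric(den_effect_sd),
    n_dens = as.integer(n_dens),
    rodent_cycle_period = as.integer(rodent_cycle_period),
    ancestral_ne = as.numeric(ancestral_ne),
    n_sample = as.integer(n_sample),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_loadfit(paste0("invalid sim_config: ", msg), "loadfit_config_error")
  chk(cfg$n_founders >= 2, "n_founders must be >= 2")
  chk(cfg$n_generations >= 0, "n_generations must be >= 0")
  chk(cfg$carrying_capacity >= 2, "carrying_capacity must be >= 2")
  chk(cfg$genome_length > 0, "genome_length must be > 0")
  chk(all(c("lof", "mis", "syn", "neutral") %in% names(cfg$founder_sites)),
      "founder_sites needs names lof, mis, syn, neutral")
  chk(all(cfg$founder_sites >= 0), "founder_sites must be >= 0")
  chk(all(c("lof", "mis", "syn", "neutral") %in% names(cfg$mut_rates)),
      "mut_rates needs names lof, mis, syn, neutral")
  chk(all(cfg$mut_rates >= 0), "mutation rates must be >= 0")
  chk(all(c("lof", "mis", "syn") %in% names(cfg$s)) &&
        all(c("lof", "mis", "syn") %in% names(cfg$h)),
      "s and h need names lof, mis, syn")
  chk(all(cfg$s >= 0 & cfg$s <= 1), "selection coefficients must lie in [0, 1]")
  chk(all(cfg$h >= 0 & cfg$h <= 1), "dominance coefficients must lie in [0, 1]")
  chk(is.na(cfg$immigration_generation) || cfg$immigration_generation >= 1,
      "immigration_generation must be >= 1 or NA")
  chk(cfg$n_immigrants >= 0, "n_immigrants must be >= 0")
  chk(cfg$immigrant_source_diversity >= 0, "immigrant_source_diversity must be >= 0")
  for (b in c("beta_lof_lrs", "beta_lof_longevity", "beta_het_survival",
              "beta_mis_survival", "survival_intercept", "beta_f1_litter")) {
    chk(is.finite(cfg[[b]]), paste0(b, " must be finite"))
  }
  chk(cfg$adult_survival > 0 && cfg$adult_survival < 1,
      "adult_survival must lie in (0, 1)")
  chk(all(c("increase", "decrease") %in% names(cfg$litter_lambda)) &&
        all(cfg$litter_lambda > 0), "litter_lambda needs positive increase/decrease entries")
  chk(cfg$den_effect_sd >= 0, "den_effect_sd must be >= 0")
  chk(cfg$n_dens >= 1, "n_dens must be >= 1")
  chk(cfg$rodent_cycle_period >= 2, "rodent_cycle_period must be >= 2")
  chk(cfg$ancestral_ne > 0, "ancestral_ne must be > 0")
  chk(cfg$n_sample >= 2, "n_sample must be >= 2")
  chk(is.finite(cfg$seed), "seed must be a finite integer")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  founders %d, years %d, K %d, genome %.3g bp, seed %d\n",
              x$n_founders, x$n_generations, x$carrying_capacity,
              x$genome_length, x$seed))
  cat(sprintf("  selection s: lof %.3g mis %.3g syn %.3g | h: %.2g %.2g %.2g\n",
              x$s[["lof"]], x$s[["mis"]], x$s[["syn"]],
              x$h[["lof"]], x$h[["mis"]], x$h[["syn"]]))
  cat(sprintf("  admixture: year %s, %d immigrants (diversity %.2g)\n",
              ifelse(is.na(x$immigration_generation), "none",
                     x$immigration_generation),
              x$n_immigrants, x$immigrant_source_diversity))
  invisible(x)
}

# Rodent phase of a calendar year: first half of each cycle is "increase".
rodent_phase_of <- function(year, period) {
  pos <- year %% period
  ifelse(pos < ceiling(period / 2), "increase", "decrease")
}
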