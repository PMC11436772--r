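# Simulator behaviour: configuration validation, determinism, identity and
# drift limits, selection response, Hardy-Weinberg, admixture effects and the
# causal fitness links.

test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_founders = 1), class = "loadfit_config_error")
  expect_error(sim_config(s = c(lof = 1.2, mis = 0, syn = 0)),
               class = "loadfit_config_error")
  expect_error(sim_config(h = c(lof = -0.1, mis = 0, syn = 0)),
               class = "loadfit_config_error")
  expect_error(sim_config(mut_rates = c(lof = -1, mis = 0, syn = 0, neutral = 0)),
               class = "loadfit_config_error")
  expect_error(sim_config(founder_sites = c(lof = 1, mis = 1)),
               class = "loadfit_config_error")
  expect_error(sim_config(beta_lof_lrs = Inf), class = "loadfit_config_error")
  expect_error(sim_config(adult_survival = 1), class = "loadfit_config_error")
})

test_that("standing-variation weights are neutral 1/q at gamma 0 and purifying otherwise", {
  w0 <- loadfit:::sfs_weights(20, 0)
  q <- (1:19) / 20
  expect_equal(w0, 1 / q)
  # purifying selection down-weights high frequencies relative to neutral
  w5 <- loadfit:::sfs_weights(20, 5)
  ratio <- w5 / w0
  expect_true(all(diff(ratio) < 0))
  expect_true(all(is.finite(loadfit:::sfs_weights(100, 500))))
})

test_that("n_generations = 0 yields exactly the founders and their standing variation", {
  cfg <- small_cfg()
  cfg$n_generations <- 0L
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$fitness), cfg$n_founders)
  expect_true(all(sim$fitness$ancestry_class == "native"))
  expect_equal(nrow(sim$litters), 0)
  n_standing <- sum(cfg$founder_sites)
  expect_lte(nrow(sim$variants$sites), n_standing)
  expect_true(all(sim$variants$sites$impact %in%
                    c("LOF", "MISSENSE", "SYNONYMOUS", "OTHER")))
})

test_that("a fixed seed is fully deterministic, including byte-identical VCFs", {
  s1 <- simulate_population(small_cfg())
  s2 <- simulate_population(small_cfg())
  expect_identical(s1, s2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_outputs(s1, d1); p2 <- write_outputs(s2, d2)
  for (f in names(p1)) {
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])),
                     label = paste("bytes of", f))
  }
  # a different seed gives a different realisation
  expect_false(identical(s1, simulate_population(small_cfg(seed = 8))))
})

test_that("simulated genotypes, positions and pedigree are internally consistent", {
  sim <- simulate_population(small_cfg())
  vt <- sim$variants
  expect_true(all(vt$geno %in% 0:2))
  expect_true(all(vt$sites$pos >= 1 & vt$sites$pos <= sim$config$genome_length))
  expect_false(any(duplicated(vt$sites$pos)))
  expect_true(all(rowSums(vt$geno) > 0))  # only carried sites are emitted
  ped <- sim$pedigree
  by <- setNames(ped$birth_year, ped$id)
  kids <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  expect_true(all(by[kids$id] > by[kids$sire]))
  expect_true(all(by[kids$id] > by[kids$dam]))
  # offspring of immigrant x native parents are F1
  cls <- setNames(ped$ancestry_class, ped$id)
  pc <- cbind(cls[kids$sire], cls[kids$dam])
  f1 <- rowSums(pc == "immigrant") == 1 & rowSums(pc == "native") == 1
  if (any(f1)) expect_true(all(cls[kids$id[f1]] == "F1"))
})

test_that("with no selection and no trait effects, allele frequencies drift around the founding value", {
  # pure Wright-Fisher check: descendant allele frequency is a martingale, so
  # the mean frequency change from founders to descendants is ~0 over replicates
  n_rep <- 200
  deltas <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(
      n_founders = 8, n_generations = 4, carrying_capacity = 16,
      genome_length = 1e4,
      founder_sites = c(lof = 0, mis = 0, syn = 6, neutral = 0),
      mut_rates = c(lof = 0, mis = 0, syn = 0, neutral = 0),
      s = c(lof = 0, mis = 0, syn = 0),
      immigration_generation = NA, n_immigrants = 0,
      beta_lof_lrs = 0, beta_lof_longevity = 0, beta_het_survival = 0,
      beta_mis_survival = 0, survival_intercept = 1, beta_f1_litter = 0,
      n_dens = 8, n_sample = 500, seed = 1000 + r)
    sim <- simulate_population(cfg)
    vt <- sim$variants
    founders <- sim$pedigree$id[sim$pedigree$birth_year == 0]
    desc <- setdiff(vt$samples, founders)
    q0 <- rowSums(vt$geno[, founders, drop = FALSE]) / (2 * length(founders))
    qf <- rowSums(vt$geno[, desc, drop = FALSE]) / (2 * length(desc))
    deltas[r] <- mean(qf - q0)
  }
  expect_lt(abs(mean(deltas)), 0.03)
})

test_that("recessive lethal-class selection shifts the LoF frequency spectrum below synonymous", {
  # mean derived frequency over all founder sites of a class, counting sites
  # purged from the sampled genomes as frequency 0 (otherwise the comparison
  # would condition on survival and understate the shift)
  class_mean_freq <- function(sim, class, n_founder_sites) {
    vt <- sim$variants
    n <- length(vt$samples)
    sum(rowSums(vt$geno[vt$sites$impact == class, , drop = FALSE]) / (2 * n)) /
      n_founder_sites
  }
  diffs <- vapply(1:3, function(seed) {
    cfg <- sim_config(
      n_founders = 30, n_generations = 16, carrying_capacity = 100,
      genome_length = 5e5,
      founder_sites = c(lof = 30, mis = 0, syn = 150, neutral = 50),
      mut_rates = c(lof = 0, mis = 0, syn = 0, neutral = 0),
      s = c(lof = 0.5, mis = 0, syn = 0),
      h = c(lof = 0, mis = 0, syn = 0),  # gamma = 0: founder spectra identical
      immigration_generation = NA, n_immigrants = 0,
      beta_lof_lrs = 0, beta_lof_longevity = 0, beta_het_survival = 0,
      beta_mis_survival = 0, survival_intercept = 2, beta_f1_litter = 0,
      adult_survival = 0.7, litter_lambda = c(increase = 10, decrease = 9),
      n_dens = 40, n_sample = 60, seed = seed)
    sim <- simulate_population(cfg)
    class_mean_freq(sim, "LOF", 30) - class_mean_freq(sim, "SYNONYMOUS", 150)
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("neutral sites are in Hardy-Weinberg proportions", {
  cfg <- sim_config(
    n_founders = 50, n_generations = 2, carrying_capacity = 100,
    genome_length = 1e6,
    founder_sites = c(lof = 0, mis = 0, syn = 500, neutral = 500),
    mut_rates = c(lof = 0, mis = 0, syn = 0, neutral = 0),
    s = c(lof = 0, mis = 0, syn = 0),
    immigration_generation = NA, n_immigrants = 0,
    beta_lof_lrs = 0, beta_lof_longevity = 0, beta_het_survival = 0,
    beta_mis_survival = 0, survival_intercept = 1, beta_f1_litter = 0,
    n_dens = 50, n_sample = 100, seed = 21)
  sim <- simulate_population(cfg)
  vt <- sim$variants
  idx <- which(vt$sites$impact == "OTHER")
  g <- vt$geno[idx, , drop = FALSE]
  n <- ncol(g)
  dac <- rowSums(g)
  obs_het <- sum(g == 1L)
  # expected heterozygotes if each site's alleles were paired at random
  exp_het <- sum(n * dac * (2 * n - dac) / choose(2 * n, 2))
  expect_gt(obs_het / exp_het, 0.93)
  expect_lt(obs_het / exp_het, 1.07)
})

test_that("expressed LoF load is negatively correlated with LRS across >= 200 adults", {
  cfg <- sim_config(n_generations = 10, carrying_capacity = 150, n_dens = 60,
                    n_sample = 2, seed = 11)
  sim <- simulate_population(cfg)
  d <- merge(sim$fitness, sim$truth[, c("id", "e_lof")], by = "id")
  adults <- d[!is.na(d$longevity_years), ]
  expect_gte(nrow(adults), 200)
  expect_lt(cor(adults$e_lof, adults$lrs), 0)
})

test_that("admixture raises F1 heterozygosity and adds hybrid-private LoF sites", {
  sim <- get_default_sim()
  tr <- sim$truth
  expect_gt(mean(tr$het_per_kb[tr$ancestry_class == "F1"]),
            mean(tr$het_per_kb[tr$ancestry_class == "native"]))
  vt <- apply_site_filters(sim$variants)
  cls <- setNames(sim$pedigree$ancestry_class, sim$pedigree$id)[vt$samples]
  ga <- setNames(ifelse(cls == "native", "native", "hybrid"), vt$samples)
  gp <- gene_pool_lof_summary(vt, ga)
  expect_gte(gp$private[["hybrid"]], 1)
})

test_that("extinction is reported as a classed error naming the generation", {
  cfg <- small_cfg()
  cfg$survival_intercept <- -30   # no cub survives its first year
  cfg$adult_survival <- 0.05      # adults die almost immediately
  cfg$n_generations <- 20L
  expect_error(simulate_population(cfg), "generation",
               class = "loadfit_extinction")
})
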