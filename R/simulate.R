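# Forward-in-time diploid simulator with overlapping generations (geometric
# adult lifespan), monogamous den-structured breeding, class-specific
# purifying selection, and a single admixture event. Mutations arise on an
# infinite-sites lattice; recombination is uniform with one crossover per
# meiosis on a single pseudo-autosomal chromosome.

IMPACT_LEVELS <- c("LOF", "MISSENSE", "SYNONYMOUS", "OTHER")

# Wright/Poisson-random-field shaped site-frequency weights for standing
# variation under purifying selection of strength g = 2*Ne*s*h > 0 against
# the derived allele: f(q) ~ (1 - exp(-2G(1-q))) / (q(1-q)(1-exp(-2G))) with
# signed G = -g, written in overflow-safe form (all exponents negative).
# Reduces to the neutral 1/q spectrum as g -> 0.
sfs_weights <- function(n_haps, gamma) {
  q <- seq_len(n_haps - 1) / n_haps
  if (!is.finite(gamma) || gamma < 1e-9) {
    1 / q
  } else {
    exp(-2 * gamma * q) * (1 - exp(-2 * gamma * (1 - q))) /
      (q * (1 - q) * (1 - exp(-2 * gamma)))
  }
}

sample_standing_counts <- function(n_sites, n_haps, gamma) {
  if (n_sites == 0) return(integer(0))
  w <- sfs_weights(n_haps, gamma)
  sample.int(n_haps - 1, n_sites, replace = TRUE, prob = w)
}

# sample() treats a lone integer as 1:n; these wrappers avoid that trap
shuffle_ids <- function(x) if (length(x) <= 1L) x else sample(x)
sample_ids <- function(x, k) x[sample.int(length(x), k)]

# read haplotype hh from the site-state environment at length ns, padding
# with ancestral (0) alleles for sites created after the vector was written
hap_vec_st <- function(st, hh, ns) {
  v <- if (hh <= length(st$Hl)) st$Hl[[hh]] else NULL
  if (is.null(v)) return(integer(ns))
  lv <- length(v)
  if (lv < ns) c(v, integer(ns - lv)) else v[seq_len(ns)]
}

ancestry_label <- function(gen) {
  ifelse(gen < 0, "native",
         ifelse(gen == 0, "immigrant", paste0("F", pmin(gen, 4))))
}

#' Simulate a small admixed population with deleterious variation
#'
#' Runs a year-by-year forward simulation under the causal structure the
#' downstream analysis assumes: expressed (homozygous) loss-of-function load
#' depresses litter production and longevity, genome-wide heterozygosity
#' raises first-year survival, expressed missense load lowers it, and an
#' immigration event introduces novel HIGH-impact alleles. Newborn viability
#' selection `w = prod((1-s*h)^n_het * (1-s)^n_hom)` acts every generation.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `loadfit_sim`: a list with elements
#'   \describe{
#'     \item{pedigree}{one row per individual: id, sire, dam, birth_year,
#'       sex, ancestry_class, natal_den.}
#'     \item{fitness}{field-monitoring style table for all recorded
#'       individuals: id, sex, ancestry_class, natal_den, rodent_phase,
#'       juvenile_survival, longevity_years, lrs, mean_litter_size.}
#'     \item{litters}{one row per observed litter: den, year, rodent_phase,
#'       pair_combination, litter_size, sire, dam.}
#'     \item{truth}{per-individual generative covariates (heterozygous sites
#'       per kb, expressed/masked load proportions, viability) for all
#'       recorded individuals; the ground truth for parameter-recovery
#'       experiments.}
#'     \item{variants}{a [variant_table] of the re-sequenced subsample
#'       (`config$n_sample` individuals, natives and immigrant descendants).}
#'     \item{config}{the configuration used.}
#'   }
#' @details With a fixed seed the result is fully deterministic: all draws
#'   come from one documented stream (per year: pair shuffle, den assignment;
#'   per pair: conceived litter size; per cub: sex, two gametes, mutations,
#'   neonatal viability, first-year survival, adult lifespan).
#' @export
#' @examples
#' sim <- simulate_population(sim_config(n_founders = 10, n_generations = 3,
#'                                       carrying_capacity = 20,
#'                                       founder_sites = c(lof = 10, mis = 40,
#'                                                         syn = 60, neutral = 100),
#'                                       immigration_generation = 2,
#'                                       n_immigrants = 2, seed = 42))
#' head(sim$pedigree)
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  with_seed(config$seed, sim_impl(config))
}

sim_impl <- function(cfg) {
  gl <- cfg$genome_length
  n_f <- cfg$n_founders
  s <- cfg$s; h <- cfg$h

  ## ---- site state ------------------------------------------------------
  fs <- cfg$founder_sites
  cls <- c(rep("LOF", fs[["lof"]]), rep("MISSENSE", fs[["mis"]]),
           rep("SYNONYMOUS", fs[["syn"]]), rep("OTHER", fs[["neutral"]]))
  n0 <- length(cls)
  cap_sites <- n0 + 512L

  st <- new.env(parent = emptyenv())
  st$n_sites <- n0
  st$pos <- c(sample.int(gl, n0), numeric(cap_sites - n0))
  st$cls <- c(cls, character(cap_sites - n0))
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, n0, replace = TRUE)
  alt <- nuc[(match(ref, nuc) - 1L + sample.int(3L, n0, replace = TRUE)) %% 4L + 1L]
  st$ref <- c(ref, character(cap_sites - n0))
  st$alt <- c(alt, character(cap_sites - n0))
  st$q0 <- c(rep(NA_real_, n0), numeric(cap_sites - n0))  # source-pop freq (founder sites)
  # haplotypes live in a list of integer vectors, one per haplotype: writing a
  # gamete then touches a single short vector instead of forcing a
  # copy-on-write of one big sites-by-haplotypes matrix. A vector may be
  # shorter than n_sites (sites created after it was written are absent, i.e.
  # ancestral); hap_vec() pads on read.
  st$Hl <- list()
  hap_vec <- function(hh, ns) hap_vec_st(st, hh, ns)

  gamma_of <- function(k) 2 * cfg$ancestral_ne * s[[k]] * h[[k]]
  class_gamma <- c(LOF = gamma_of("lof"), MISSENSE = gamma_of("mis"),
                   SYNONYMOUS = gamma_of("syn"), OTHER = 0)

  # founder standing counts per site, assigned to random founder haplotypes
  founder_counts <- integer(n0)
  for (k in IMPACT_LEVELS) {
    idx <- which(st$cls[seq_len(n0)] == k)
    founder_counts[idx] <- sample_standing_counts(length(idx), 2L * n_f,
                                                  class_gamma[[k]])
  }
  st$q0[seq_len(n0)] <- founder_counts / (2 * n_f)

  grow_sites <- function() {
    addl <- length(st$pos)
    st$pos <- c(st$pos, numeric(addl))
    st$cls <- c(st$cls, character(addl))
    st$ref <- c(st$ref, character(addl))
    st$alt <- c(st$alt, character(addl))
    st$q0 <- c(st$q0, numeric(addl))
  }

  # registers a new segregating site; the caller places the carrier alleles
  # (single-element writes into the large haplotype matrix would force a full
  # copy each time, so carriers are folded into whole-column writes instead)
  new_site <- function(class) {
    if (st$n_sites + 1L > length(st$pos)) grow_sites()
    repeat {
      p <- sample.int(gl, 1L)
      if (!p %in% st$pos[seq_len(st$n_sites)]) break
    }
    j <- st$n_sites + 1L
    st$n_sites <- j
    st$pos[j] <- p
    st$cls[j] <- class
    r <- sample(nuc, 1L)
    st$ref[j] <- r
    st$alt[j] <- nuc[(match(r, nuc) - 1L + sample.int(3L, 1L)) %% 4L + 1L]
    st$q0[j] <- NA_real_
    j
  }

  ## ---- individual state ------------------------------------------------
  cap_ind <- 512L
  iv <- new.env(parent = emptyenv())
  iv$n <- 0L
  for (f in c("sire", "dam", "birth_year", "anc", "den", "recruit_year",
              "death_year", "juv", "nlit")) assign(f, rep(NA_integer_, cap_ind), envir = iv)
  for (f in c("longevity", "lrs", "litsum", "het_kb", "e_lof", "e_mis",
              "e_syn", "m_lof", "m_mis", "m_syn", "p_lof", "p_mis", "p_syn",
              "w")) assign(f, rep(NA_real_, cap_ind), envir = iv)
  iv$sex <- rep(NA_character_, cap_ind)
  iv$adult <- rep(FALSE, cap_ind)

  grow_ind <- function() {
    for (f in ls(iv)) {
      if (f == "n") next
      v <- get(f, envir = iv)
      fill <- if (is.logical(v)) FALSE else v[NA_integer_][1L]
      assign(f, c(v, rep(fill, length(v))), envir = iv)
    }
  }

  add_ind <- function(sire, dam, sex, birth_year, anc, den) {
    if (iv$n + 1L > length(iv$sire)) grow_ind()
    i <- iv$n + 1L
    iv$n <- i
    iv$sire[i] <- sire; iv$dam[i] <- dam; iv$sex[i] <- sex
    iv$birth_year[i] <- birth_year; iv$anc[i] <- anc; iv$den[i] <- den
    iv$nlit[i] <- 0L
    i
  }

  hapcols <- function(i) c(2L * i - 1L, 2L * i)

  class_idx <- function() {
    k <- st$cls[seq_len(st$n_sites)]
    list(lof = which(k == "LOF"), mis = which(k == "MISSENSE"),
         syn = which(k == "SYNONYMOUS"))
  }

  # genotype-derived covariates and viability for individual i
  geno_stats <- function(i) {
    ns <- st$n_sites
    hc <- hapcols(i)
    g <- hap_vec(hc[1L], ns) + hap_vec(hc[2L], ns)
    ci <- class_idx()
    n_annot <- length(ci$lof) + length(ci$mis) + length(ci$syn)
    cnt <- function(ix) {
      gi <- g[ix]
      c(het = sum(gi == 1L), hom = sum(gi == 2L), der = sum(gi))
    }
    cl <- cnt(ci$lof); cm <- cnt(ci$mis); cs <- cnt(ci$syn)
    w <- (1 - s[["lof"]] * h[["lof"]])^cl[["het"]] * (1 - s[["lof"]])^cl[["hom"]] *
      (1 - s[["mis"]] * h[["mis"]])^cm[["het"]] * (1 - s[["mis"]])^cm[["hom"]] *
      (1 - s[["syn"]] * h[["syn"]])^cs[["het"]] * (1 - s[["syn"]])^cs[["hom"]]
    tot_der <- cl[["der"]] + cm[["der"]] + cs[["der"]]
    list(
      het_kb = sum(g == 1L) * 1000 / gl,
      e_lof = cl[["hom"]] / n_annot, e_mis = cm[["hom"]] / n_annot,
      e_syn = cs[["hom"]] / n_annot,
      m_lof = cl[["het"]] / n_annot, m_mis = cm[["het"]] / n_annot,
      m_syn = cs[["het"]] / n_annot,
      p_lof = if (tot_der > 0) cl[["der"]] / tot_der else NA_real_,
      p_mis = if (tot_der > 0) cm[["der"]] / tot_der else NA_real_,
      p_syn = if (tot_der > 0) cs[["der"]] / tot_der else NA_real_,
      w = w
    )
  }

  store_stats <- function(i, g) {
    for (f in names(g)) {
      v <- get(f, envir = iv); v[i] <- g[[f]]; assign(f, v, envir = iv)
    }
  }

  draw_longevity <- function(e_lof) {
    g <- 1 + rgeom(1L, prob = 1 - cfg$adult_survival)
    g * exp(cfg$beta_lof_longevity * e_lof)
  }

  recruit_adult <- function(i, year) {
    iv$adult[i] <- TRUE
    iv$recruit_year[i] <- year
    L <- draw_longevity(iv$e_lof[i])
    iv$longevity[i] <- L
    iv$death_year[i] <- year + max(1L, as.integer(round(L))) - 1L
    iv$lrs[i] <- 0
  }

  # one crossover per meiosis, uniform breakpoint, random starting haplotype
  gamete <- function(i) {
    ns <- st$n_sites
    hc <- hapcols(i)
    x <- runif(1L, 0, gl)
    first <- sample.int(2L, 1L)
    m <- st$pos[seq_len(ns)] <= x
    out <- integer(ns)
    out[m] <- hap_vec(hc[first], ns)[m]
    out[!m] <- hap_vec(hc[3L - first], ns)[!m]
    out
  }

  mut_class_map <- c(lof = "LOF", mis = "MISSENSE", syn = "SYNONYMOUS",
                     neutral = "OTHER")

  ## ---- founders --------------------------------------------------------
  founder_sex <- rep(c("M", "F"), length.out = n_f)
  for (i in seq_len(n_f)) add_ind(NA_integer_, NA_integer_, founder_sex[i], 0L, -1L, NA_integer_)
  # distribute standing derived alleles over founder haplotypes (built as a
  # small block, assigned to the haplotype matrix in one write)
  Hf <- matrix(0L, n0, 2L * n_f)
  for (j in seq_len(n0)) {
    k <- founder_counts[j]
    if (k > 0L) Hf[j, sample.int(2L * n_f, k)] <- 1L
  }
  for (hh in seq_len(2L * n_f)) st$Hl[[hh]] <- Hf[, hh]
  for (i in seq_len(n_f)) {
    store_stats(i, geno_stats(i))
    recruit_adult(i, 1L)
  }

  den_u <- stats::rnorm(cfg$n_dens, 0, cfg$den_effect_sd)

  make_immigrants <- function(year) {
    ids <- integer(cfg$n_immigrants)
    for (m in seq_len(cfg$n_immigrants)) {
      ids[m] <- add_ind(NA_integer_, NA_integer_, "M", year - 1L, 0L, NA_integer_)
    }
    fsites <- which(!is.na(st$q0[seq_len(st$n_sites)]))
    # novel source-private variants, frequency-tilted per class; carriers are
    # recorded as local haplotype indices (1..2*n_immigrants) and written
    # together with the founder-site draws in one column write per haplotype
    n_hap_i <- 2L * cfg$n_immigrants
    nov_j <- integer(0)
    nov_carriers <- list()
    if (cfg$immigrant_source_diversity > 0 && cfg$n_immigrants > 0) {
      base <- c(lof = 40, mis = 150, syn = 250, neutral = 300)
      kept_lof <- 0L
      for (k in names(base)) {
        n_cand <- as.integer(round(cfg$immigrant_source_diversity * base[[k]]))
        if (n_cand == 0L) next
        klab <- mut_class_map[[k]]
        wts <- sfs_weights(100L, class_gamma[[klab]])
        for (cnd in seq_len(n_cand)) {
          qn <- sample.int(99L, 1L, prob = wts) / 100
          carriers <- which(runif(n_hap_i) < qn)
          if (length(carriers) == 0L) next
          nov_j <- c(nov_j, new_site(klab))
          nov_carriers[[length(nov_carriers) + 1L]] <- carriers
          if (klab == "LOF") kept_lof <- kept_lof + 1L
        }
      }
      if (kept_lof == 0L) {
        # admixture always introduces at least one novel LoF
        nov_j <- c(nov_j, new_site("LOF"))
        nov_carriers[[length(nov_carriers) + 1L]] <- 1L
      }
    }
    ns <- st$n_sites
    for (m in seq_along(ids)) {
      hc <- hapcols(ids[m])
      for (a in 1:2) {
        hloc <- 2L * (m - 1L) + a
        v <- integer(ns)
        # alleles at native standing sites drawn at the shared source frequency
        v[fsites] <- as.integer(runif(length(fsites)) < st$q0[fsites])
        if (length(nov_j)) {
          carry <- vapply(nov_carriers, function(cc) hloc %in% cc, logical(1))
          v[nov_j[carry]] <- 1L
        }
        st$Hl[[hc[a]]] <- v
      }
    }
    for (m in ids) {
      store_stats(m, geno_stats(m))
      recruit_adult(m, year)
    }
    ids
  }

  # pair categories follow the four monitoring-study classes; any pair of two
  # immigrant-descended animals (including immigrant x F1-4) falls in the
  # fourth class, so the classification is exhaustive
  pair_combination <- function(a_s, a_d) {
    a <- sort(c(a_s, a_d))
    if (all(a == -1L)) return("native_x_native")
    if (a[1L] == -1L && a[2L] == 0L) return("native_x_immigrant")
    if (a[1L] == -1L && a[2L] >= 1L) return("native_x_immigrantF14")
    "immigrantF14_x_immigrantF14"
  }

  litters <- list()
  pending_recruits <- integer(0)

  ## ---- yearly loop -----------------------------------------------------
  if (cfg$n_generations > 0) {
    for (year in seq_len(cfg$n_generations)) {
      # recruit last year's surviving cubs, subject to carrying capacity
      alive <- which(iv$adult[seq_len(iv$n)] & iv$death_year[seq_len(iv$n)] >= year)
      if (length(pending_recruits) > 0) {
        room <- max(0L, cfg$carrying_capacity - length(alive))
        rec <- pending_recruits
        if (length(rec) > room) rec <- sample_ids(rec, room)
        for (i in rec) recruit_adult(i, year)
        pending_recruits <- integer(0)
        alive <- which(iv$adult[seq_len(iv$n)] & iv$death_year[seq_len(iv$n)] >= year)
      }
      if (!is.na(cfg$immigration_generation) && year == cfg$immigration_generation &&
          cfg$n_immigrants > 0) {
        make_immigrants(year)
        alive <- which(iv$adult[seq_len(iv$n)] & iv$death_year[seq_len(iv$n)] >= year)
      }
      if (length(alive) == 0L) {
        stop_loadfit(sprintf("population extinct at generation %d: no breeding adults remain", year),
                     "loadfit_extinction", generation = year)
      }
      phase <- rodent_phase_of(year, cfg$rodent_cycle_period)
      males <- shuffle_ids(alive[iv$sex[alive] == "M"])
      females <- shuffle_ids(alive[iv$sex[alive] == "F"])
      n_pairs <- min(length(males), length(females), cfg$n_dens)
      if (n_pairs == 0L) next
      dens <- sample.int(cfg$n_dens, n_pairs)
      cohort <- integer(0)
      for (p in seq_len(n_pairs)) {
        sire <- males[p]; dam <- females[p]; den <- dens[p]
        comb <- pair_combination(iv$anc[sire], iv$anc[dam])
        lam <- cfg$litter_lambda[[phase]] *
          exp(den_u[den] +
                cfg$beta_lof_lrs * (iv$e_lof[sire] + iv$e_lof[dam]) / 2 +
                (comb == "native_x_immigrant") * cfg$beta_f1_litter)
        n_conceived <- rpois(1L, lam)
        n_born <- 0L
        if (n_conceived > 0L) {
          child_anc <- if (iv$anc[sire] < 0L && iv$anc[dam] < 0L) -1L else {
            anc_s <- if (iv$anc[sire] < 0L) .Machine$integer.max else iv$anc[sire]
            anc_d <- if (iv$anc[dam] < 0L) .Machine$integer.max else iv$anc[dam]
            min(anc_s, anc_d) + 1L
          }
          for (cub in seq_len(n_conceived)) {
            sexc <- if (runif(1L) < 0.5) "M" else "F"
            g1 <- gamete(sire)
            g2 <- gamete(dam)
            ns_before <- length(g1)
            # de-novo mutations: new sites first, carrier bits folded into the
            # full-column haplotype writes below
            mut_j <- integer(0)
            mut_on_first <- logical(0)
            for (k in names(mut_class_map)) {
              nmut <- rpois(1L, cfg$mut_rates[[k]])
              if (nmut > 0L) for (mm in seq_len(nmut)) {
                mut_j <- c(mut_j, new_site(mut_class_map[[k]]))
                mut_on_first <- c(mut_on_first, sample.int(2L, 1L) == 1L)
              }
            }
            i <- add_ind(sire, dam, sexc, year, child_anc, den)
            hc <- hapcols(i)
            ns <- st$n_sites
            h1 <- integer(ns); h1[seq_len(ns_before)] <- g1
            h2 <- integer(ns); h2[seq_len(ns_before)] <- g2
            h1[mut_j[mut_on_first]] <- 1L
            h2[mut_j[!mut_on_first]] <- 1L
            st$Hl[[hc[1L]]] <- h1
            st$Hl[[hc[2L]]] <- h2
            gs <- geno_stats(i)
            if (runif(1L) < gs$w) {
              # cub survives the neonatal viability filter and is recorded
              store_stats(i, gs)
              psurv <- plogis(cfg$survival_intercept +
                                cfg$beta_het_survival * gs$het_kb +
                                cfg$beta_mis_survival * gs$e_mis)
              iv$juv[i] <- rbinom(1L, 1L, psurv)
              n_born <- n_born + 1L
              cohort <- c(cohort, i)
            } else {
              # unrecorded neonatal death: genotype columns stay unused
              iv$juv[i] <- NA_integer_
              iv$den[i] <- NA_integer_  # flag as unrecorded
              iv$sex[i] <- NA_character_
            }
          }
        }
        if (n_born > 0L) {
          litters[[length(litters) + 1L]] <- data.frame(
            den = paste0("den", formatC(den, width = 2, flag = "0")),
            year = year, rodent_phase = phase, pair_combination = comb,
            litter_size = n_born, sire = sire, dam = dam,
            stringsAsFactors = FALSE)
          iv$lrs[sire] <- iv$lrs[sire] + n_born
          iv$lrs[dam] <- iv$lrs[dam] + n_born
          iv$nlit[sire] <- iv$nlit[sire] + 1L
          iv$nlit[dam] <- iv$nlit[dam] + 1L
          iv$litsum[sire] <- sum(iv$litsum[sire], n_born, na.rm = TRUE)
          iv$litsum[dam] <- sum(iv$litsum[dam], n_born, na.rm = TRUE)
        }
      }
      pending_recruits <- cohort[!is.na(iv$juv[cohort]) & iv$juv[cohort] == 1L]
    }
  }

  assemble_sim_result(cfg, st, iv, litters)
}

assemble_sim_result <- function(cfg, st, iv, litters) {
  n <- iv$n
  recorded <- which(!(iv$birth_year[seq_len(n)] > 0L & is.na(iv$sex[seq_len(n)])))
  ids <- sprintf("ind%04d", recorded)
  idmap <- setNames(ids, recorded)
  lab <- ancestry_label(iv$anc[recorded])
  phase_birth <- rodent_phase_of(pmax(iv$birth_year[recorded], 1L),
                                 cfg$rodent_cycle_period)
  den_lab <- ifelse(is.na(iv$den[recorded]), NA_character_,
                    paste0("den", formatC(iv$den[recorded], width = 2, flag = "0")))

  pedigree <- data.frame(
    id = ids,
    sire = ifelse(is.na(iv$sire[recorded]), NA_character_,
                  idmap[as.character(iv$sire[recorded])]),
    dam = ifelse(is.na(iv$dam[recorded]), NA_character_,
                 idmap[as.character(iv$dam[recorded])]),
    birth_year = iv$birth_year[recorded],
    sex = iv$sex[recorded],
    ancestry_class = lab,
    natal_den = den_lab,
    stringsAsFactors = FALSE)

  fitness <- data.frame(
    id = ids,
    sex = iv$sex[recorded],
    ancestry_class = lab,
    natal_den = den_lab,
    rodent_phase = phase_birth,
    juvenile_survival = iv$juv[recorded],
    longevity_years = iv$longevity[recorded],
    lrs = iv$lrs[recorded],
    mean_litter_size = ifelse(iv$nlit[recorded] > 0,
                              iv$litsum[recorded] / iv$nlit[recorded], NA_real_),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    id = ids,
    ancestry_class = lab,
    het_per_kb = iv$het_kb[recorded],
    e_lof = iv$e_lof[recorded], e_mis = iv$e_mis[recorded],
    e_syn = iv$e_syn[recorded],
    m_lof = iv$m_lof[recorded], m_mis = iv$m_mis[recorded],
    m_syn = iv$m_syn[recorded],
    p_lof = iv$p_lof[recorded], p_mis = iv$p_mis[recorded],
    p_syn = iv$p_syn[recorded],
    viability = iv$w[recorded],
    stringsAsFactors = FALSE)

  lit_df <- if (length(litters)) do.call(rbind, litters) else
    data.frame(den = character(0), year = integer(0),
               rodent_phase = character(0), pair_combination = character(0),
               litter_size = integer(0), sire = integer(0), dam = integer(0))
  if (nrow(lit_df)) {
    lit_df$sire <- idmap[as.character(lit_df$sire)]
    lit_df$dam <- idmap[as.character(lit_df$dam)]
  }

  # re-sequenced subsample: balance natives vs immigrant descendants, and
  # within each group prefer individuals with complete lifetime fitness
  # records (recruited adults), as a monitoring study would
  pool <- recorded[iv$anc[recorded] != 0L]  # immigrants themselves not sequenced
  hyb <- pool[iv$anc[pool] >= 1L]
  nat <- pool[iv$anc[pool] < 0L]
  # ~60% recruited adults (complete lifetime fitness) and ~40% juveniles
  # (both first-year fates), so survival and lifetime-fitness models are both
  # estimable on the sequenced subsample
  prefer_adults <- function(x, k) {
    k <- min(k, length(x))
    ad <- x[!is.na(iv$longevity[x])]
    juv <- setdiff(x, ad)
    k_ad <- min(length(ad), ceiling(0.6 * k))
    take <- sample_ids(ad, k_ad)
    if (length(take) < k) take <- c(take, sample_ids(juv, min(length(juv), k - length(take))))
    if (length(take) < k) take <- c(take, sample_ids(setdiff(ad, take), k - length(take)))
    take
  }
  n_target <- min(cfg$n_sample, length(pool))
  n_h <- min(length(hyb), ceiling(n_target / 2))
  n_n <- min(length(nat), n_target - n_h)
  take <- c(if (n_h > 0) prefer_adults(hyb, n_h), if (n_n > 0) prefer_adults(nat, n_n))
  if (length(take) < n_target) {
    rest <- setdiff(pool, take)
    take <- c(take, prefer_adults(rest, n_target - length(take)))
  }
  take <- sort(take)

  ns <- st$n_sites
  geno <- matrix(NA_integer_, ns, length(take))
  for (jj in seq_along(take)) {
    i <- take[jj]
    geno[, jj] <- hap_vec_st(st, 2L * i - 1L, ns) + hap_vec_st(st, 2L * i, ns)
  }
  carried <- rowSums(geno) > 0L
  ord <- order(st$pos[seq_len(ns)][carried])
  sites <- data.frame(
    chrom = "chr1",
    pos = st$pos[seq_len(ns)][carried][ord],
    ref = st$ref[seq_len(ns)][carried][ord],
    alt = st$alt[seq_len(ns)][carried][ord],
    impact = st$cls[seq_len(ns)][carried][ord],
    gene = ifelse(st$cls[seq_len(ns)][carried][ord] == "OTHER", NA_character_,
                  sprintf("GENE%04d", st$pos[seq_len(ns)][carried][ord] %/% 5000)),
    stringsAsFactors = FALSE)
  vt <- variant_table(sites, geno[carried, , drop = FALSE][ord, , drop = FALSE],
                      samples = idmap[as.character(take)])

  structure(list(pedigree = pedigree, fitness = fitness, litters = lit_df,
                 truth = truth, variants = vt, config = cfg),
            class = "loadfit_sim")
}

#' @export
print.loadfit_sim <- function(x, ...) {
  cat("<loadfit_sim>\n")
  cat(sprintf("  %d recorded individuals, %d litters, %d segregating sites in %d sampled genomes\n",
              nrow(x$fitness), nrow(x$litters), nrow(x$variants$sites),
              length(x$variants$samples)))
  invisible(x)
}
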