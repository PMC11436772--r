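# Zygosity screens on planted fixtures and the overrepresentation test
# against direct hypergeometric enumeration.

# Planted longevity fixture: 4 short-lived (s1-s4) and 3 long-lived (l1-l3).
#   site 1 LOF: hom in all short, never hom in long -> strict hit
#   site 2 LOF: hom in 2/4 short (50%), no long hom  -> relaxed (0.4) hit only
#   site 3 LOF: hom in all short but also hom in l2  -> never passes
#   site 4 LOF: het everywhere                        -> never passes
#   site 5 MISSENSE: hom in all short                 -> wrong class, ignored
longevity_fixture <- function() {
  ids <- c(paste0("s", 1:4), paste0("l", 1:3))
  make_table(
    c("LOF", "LOF", "LOF", "LOF", "MISSENSE"),
    rbind(c(2L, 2L, 2L, 2L, 0L, 1L, 0L),
          c(2L, 2L, 1L, 0L, 1L, 0L, 0L),
          c(2L, 2L, 2L, 2L, 0L, 2L, 0L),
          c(1L, 1L, 1L, 1L, 1L, 1L, 1L),
          c(2L, 2L, 2L, 2L, 0L, 0L, 0L)),
    ids)
}

test_that("strict longevity screen returns exactly the planted variant", {
  vt <- longevity_fixture()
  hit <- longevity_screen(vt, paste0("s", 1:4), paste0("l", 1:3), 1.0)
  expect_equal(hit$pos, 1)
  expect_equal(hit$short_hom_fraction, 1)
})

test_that("relaxed longevity screen adds the partial-homozygote variant", {
  vt <- longevity_fixture()
  hit <- longevity_screen(vt, paste0("s", 1:4), paste0("l", 1:3), 0.4)
  expect_equal(hit$pos, c(1, 2))
  expect_equal(hit$short_hom_fraction, c(1, 0.5))
  # raising the threshold never adds variants
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    lo <- longevity_screen(vt, paste0("s", 1:4), paste0("l", 1:3), thr)$pos
    hi <- longevity_screen(vt, paste0("s", 1:4), paste0("l", 1:3),
                           min(1, thr + 0.25))$pos
    expect_true(all(hi %in% lo))
  }
  expect_error(longevity_screen(vt, paste0("s", 1:4), paste0("l", 1:3), 1.5),
               class = "loadfit_input_error")
})

test_that("screens validate their groups", {
  vt <- longevity_fixture()
  expect_error(longevity_screen(vt, character(0), "l1"),
               class = "loadfit_input_error")
  expect_error(longevity_screen(vt, c("s1", "s2"), c("s2", "l1")),
               class = "loadfit_input_error")
  expect_error(longevity_screen(vt, c("s1", "ghost"), "l1"), "ghost",
               class = "loadfit_input_error")
})

test_that("litter screen requires carriage in all low and no high homozygote", {
  ids <- c("lo1", "lo2", "lo3", "hi1", "hi2")
  vt <- make_table(
    c("LOF", "LOF", "LOF", "LOF"),
    rbind(c(2L, 1L, 1L, 0L, 1L),    # all low carry, no high hom -> hit
          c(2L, 2L, 0L, 0L, 0L),    # lo3 does not carry -> out
          c(1L, 1L, 1L, 2L, 0L),    # hi1 homozygous -> out
          c(2L, 2L, 2L, 1L, 1L)),   # all low hom, highs het -> hit
    ids)
  hit <- litter_size_screen(vt, c("lo1", "lo2", "lo3"), c("hi1", "hi2"))
  expect_equal(sort(hit$pos), c(1, 4))
  expect_equal(hit$low_hom_fraction[hit$pos == 1], 1 / 3)
  expect_equal(hit$low_hom_fraction[hit$pos == 4], 1)
})

test_that("ancestry screen keeps hybrid-frequent LoFs absent from natives", {
  ids <- c("n1", "n2", "h1", "h2", "h3", "h4", "h5")
  vt <- make_table(
    c("LOF", "LOF", "LOF", "SYNONYMOUS"),
    rbind(c(0L, 0L, 1L, 1L, 0L, 0L, 0L),   # hybrid freq 2/10 = threshold: kept
          c(0L, 0L, 1L, 0L, 0L, 0L, 0L),   # hybrid freq 1/10: below threshold
          c(0L, 1L, 2L, 2L, 2L, 2L, 2L),   # native carrier: excluded
          c(0L, 0L, 2L, 2L, 2L, 2L, 2L)),  # not LOF: excluded
    ids)
  hit <- hybrid_private_lofs(vt, c("n1", "n2"), paste0("h", 1:5), 0.20)
  expect_equal(hit$pos, 1)
  expect_equal(hit$hybrid_freq_percent, 20)
  none <- hybrid_private_lofs(vt, c("n1", "n2"), paste0("h", 1:5), 0.21)
  expect_equal(nrow(none), 0)
})

test_that("screen results are invariant to sample and site order", {
  vt <- longevity_fixture()
  perm_s <- sample(ncol(vt$geno))
  perm_r <- sample(nrow(vt$geno))
  vt2 <- variant_table(vt$sites[perm_r, ], vt$geno[perm_r, perm_s],
                       vt$samples[perm_s])
  a <- longevity_screen(vt, paste0("s", 1:4), paste0("l", 1:3), 0.4)
  b <- longevity_screen(vt2, paste0("s", c(3, 1, 4, 2)), paste0("l", c(2, 3, 1)), 0.4)
  expect_equal(a$pos, b$pos)
  expect_equal(a$short_hom_fraction, b$short_hom_fraction)
})

test_that("overrepresentation p equals hypergeometric enumeration for all margins <= 30", {
  # independent oracle: explicit sum of hypergeometric point masses by choose()
  enum_p <- function(N, K, m, k) {
    js <- k:min(K, m)
    sum(choose(K, js) * choose(N - K, m - js)) / choose(N, m)
  }
  for (N in c(2:10, 15, 20, 30)) {
    genes <- sprintf("g%02d", seq_len(N))
    for (m in unique(c(1, max(1, N %/% 3), N - 1, N))) {
      if (m < 1 || m > N) next
      cand <- genes[seq_len(m)]
      # one term per feasible (K, k): k candidate genes + (K - k) non-candidates
      combos <- list(); terms <- list()
      for (K in 1:N) for (k in max(0, K + m - N):min(K, m)) {
        tid <- sprintf("T_%d_%d", K, k)
        tg <- c(genes[seq_len(k)],
                if (K - k > 0) genes[m + seq_len(K - k)])
        combos[[tid]] <- c(K = K, k = k)
        terms[[tid]] <- data.frame(gene_id = tg, term_id = tid,
                                   stringsAsFactors = FALSE)
      }
      tm <- do.call(rbind, terms)
      res <- overrepresentation_test(cand, genes, tm, skip_zero_hit = FALSE)
      for (i in seq_len(nrow(res))) {
        cb <- combos[[res$term_id[i]]]
        expect_equal(res$overlap[i], unname(cb["k"]))
        expect_equal(res$p_value[i], enum_p(N, cb["K"], m, cb["k"]),
                     tolerance = 1e-12,
                     label = sprintf("p for N=%d m=%d K=%d k=%d", N, m,
                                     cb["K"], cb["k"]))
      }
    }
  }
})

test_that("overrepresentation test edge behaviour", {
  genes <- paste0("g", 1:10)
  tm <- data.frame(gene_id = genes, term_id = "ALL", stringsAsFactors = FALSE)
  # a term covering the whole universe can never be enriched
  expect_equal(overrepresentation_test(genes[1:3], genes, tm)$p_value, 1)
  tm2 <- rbind(tm, data.frame(gene_id = c("g9", "g10"), term_id = "MISS"))
  res <- overrepresentation_test(genes[1:3], genes, tm2)
  expect_true(is.na(res$p_value[res$term_id == "MISS"]))  # skip_zero_hit
  res2 <- overrepresentation_test(genes[1:3], genes, tm2, skip_zero_hit = FALSE)
  expect_false(anyNA(res2$p_value))
  expect_true(all(res2$p_bonferroni <= 1))
  expect_true(all(res2$p_bonferroni >= res2$p_value))
  expect_error(overrepresentation_test(c("zz"), genes, tm),
               class = "loadfit_input_error")
  expect_error(overrepresentation_test("g1", genes, data.frame(gene = "g1")),
               class = "loadfit_input_error")
  expect_error(overrepresentation_test("g1", character(0), tm),
               class = "loadfit_input_error")
})
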