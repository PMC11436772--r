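# Statistical routines checked against closed forms and independent oracles:
# OLS normal equations, two-group logistic closed form, MASS::boxcox,
# rank-based identities for Mann-Whitney, Fisher-z correlation, and a
# variance-component recovery experiment for the LMM.

test_that("fit_trait_lm reproduces the closed-form OLS solution", {
  set.seed(101)
  n <- 60
  rec <- data.frame(id = paste0("i", 1:n),
                    e_lof = runif(n),
                    lrs = rpois(n, 6))
  fit <- fit_trait_lm(rec, "lrs_sqrt", "e_lof", covariates = character(0))
  X <- cbind(1, rec$e_lof)
  y <- sqrt(rec$lrs)
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(crossprod(X))))
  tval <- drop(beta) / se
  expect_equal(fit$terms$estimate, drop(beta), tolerance = 1e-10)
  expect_equal(fit$terms$se, unname(se), tolerance = 1e-10)
  expect_equal(fit$terms$statistic, unname(tval), tolerance = 1e-10)
  expect_equal(fit$terms$p_value, unname(2 * pt(-abs(tval), n - 2)), tolerance = 1e-10)
  expect_equal(fit$terms$ci_lo, unname(drop(beta) - qt(0.975, n - 2) * se),
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1 - sum(resid^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(fit$n, n)
  expect_equal(fit$response, "sqrt(lrs)")
})

test_that("trait transforms are frozen and guarded", {
  rec <- data.frame(id = c("a", "b", "c"), longevity_years = c(2, 0, 3),
                    mean_litter_size = c(4, 5, 6), x = 1:3)
  expect_error(fit_trait_lm(rec, "longevity_log", "x", covariates = character(0)),
               "offending record", class = "loadfit_input_error")
  expect_error(fit_trait_lm(rec, "unknown_resp", "x", covariates = character(0)),
               class = "loadfit_input_error")
  # identity transform for litter size
  expect_equal(loadfit:::trait_response(rec, "litter_size")$y, c(4, 5, 6))
})

test_that("fit_trait_lm flags rank deficiency and too few cases", {
  set.seed(1)
  rec <- data.frame(id = paste0("i", 1:20), lrs = rpois(20, 5), x = runif(20))
  rec$z <- 2 * rec$x
  expect_error(fit_trait_lm(rec, "lrs_sqrt", "x", covariates = "z"),
               "collinear", class = "loadfit_model_error")
  expect_error(fit_trait_lm(rec[1:2, ], "lrs_sqrt", "x", covariates = character(0)),
               class = "loadfit_model_error")
  expect_error(fit_trait_lm(rec, "lrs_sqrt", "missing_col", covariates = character(0)),
               class = "loadfit_input_error")
})

test_that("boxcox_advise agrees with the MASS::boxcox profile", {
  check_against_mass <- function(values) {
    adv <- boxcox_advise(values)
    bc <- MASS::boxcox(values ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
    expect_equal(adv$lambda, bc$x[which.max(bc$y)], tolerance = 0.021)
    adv
  }
  set.seed(7)
  adv_log <- check_against_mass(rlnorm(400))             # lambda near 0
  expect_equal(adv_log$transform, "log")
  adv_sqrt <- check_against_mass(rnorm(400, 20, 2)^2 / 40)  # lambda near 0.5
  expect_equal(adv_sqrt$transform, "sqrt")
  adv_id <- check_against_mass(rnorm(400, 50, 2))        # lambda near 1
  expect_equal(adv_id$transform, "identity")
  expect_error(boxcox_advise(c(1, -2, 3)), class = "loadfit_input_error")
  expect_warning(flat <- boxcox_advise(c(2, 2, 2, 2)), "degenerate")
  expect_equal(flat$transform, "identity")
})

test_that("survival GLM matches the two-group logistic closed form", {
  rec <- data.frame(
    juvenile_survival = c(rep(1, 12), rep(0, 18), rep(1, 21), rep(0, 9)),
    x = c(rep(0, 30), rep(1, 30)))
  fit <- fit_juvenile_survival_glm(rec, "x", covariates = character(0))
  p0 <- 12 / 30; p1 <- 21 / 30
  slope <- qlogis(p1) - qlogis(p0)
  se_slope <- sqrt(1 / (30 * p0 * (1 - p0)) + 1 / (30 * p1 * (1 - p1)))
  expect_equal(fit$terms$estimate, c(qlogis(p0), slope), tolerance = 1e-6)
  expect_equal(fit$terms$se[2], se_slope, tolerance = 1e-6)
  expect_equal(fit$terms$p_value[2],
               2 * pnorm(-abs(slope / se_slope)), tolerance = 1e-4)
  expect_equal(fit$family, "binomial glm (logit)")
})

test_that("survival GLM rejects bad responses and separation", {
  expect_error(
    fit_juvenile_survival_glm(data.frame(juvenile_survival = c(0, 2, 1), x = 1:3),
                              "x", covariates = character(0)),
    class = "loadfit_input_error")
  expect_error(
    fit_juvenile_survival_glm(data.frame(juvenile_survival = rep(1, 10), x = 1:10),
                              "x", covariates = character(0)),
    "constant", class = "loadfit_model_error")
  sep <- data.frame(juvenile_survival = rep(c(0, 1), each = 20),
                    x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(fit_juvenile_survival_glm(sep, "x", covariates = character(0)),
               "separation", class = "loadfit_model_error")
})

test_that("Mann-Whitney U satisfies rank identities and the exact small-sample p", {
  mw <- mann_whitney_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)   # 2 * 1/C(6,3)... exact two-sided tail
  expect_equal(mw$estimate, -3)   # Hodges-Lehmann: median pairwise difference
  # U_A + U_B equals n_A * n_B for any tie-free data
  set.seed(9)
  a <- rnorm(11); b <- rnorm(7)
  expect_equal(mann_whitney_groups(a, b)$U + mann_whitney_groups(b, a)$U, 77)
  # invariance under a common monotone shift
  expect_equal(mann_whitney_groups(a, b)$p_value,
               mann_whitney_groups(a + 10, b + 10)$p_value)
  expect_error(mann_whitney_groups(numeric(0), b), class = "loadfit_input_error")
})

test_that("correlate matches the closed-form Pearson test", {
  set.seed(13)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  ct <- correlate(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt(38) / sqrt(1 - r^2)
  expect_equal(ct$r, r, tolerance = 1e-12)
  expect_equal(ct$t, tval, tolerance = 1e-12)
  expect_equal(ct$p_value, 2 * pt(-abs(tval), 38), tolerance = 1e-12)
  z <- atanh(r)
  expect_equal(ct$ci, tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(37)),
               tolerance = 1e-6)
  expect_equal(ct$n, 40)
  expect_error(correlate(1:2, 2:3), class = "loadfit_input_error")
  expect_error(correlate(rep(1, 5), rnorm(5)), class = "loadfit_input_error")
})

test_that("ancestry LMM recovers a planted den variance component", {
  set.seed(31)
  n_den <- 50; per_den <- 4
  den <- rep(paste0("d", seq_len(n_den)), each = per_den)
  u <- rep(rnorm(n_den, 0, 2), each = per_den)
  grp <- sample(c("native", "F1"), n_den * per_den, replace = TRUE)
  rec <- data.frame(y = 3 + (grp == "F1") * 1.5 + u + rnorm(n_den * per_den, 0, 1),
                    grp = grp, den = den, stringsAsFactors = FALSE)
  fit <- fit_ancestry_lmm(rec, "y", "grp", fixed = character(0), random = "den",
                          reference = "native")
  vc <- fit$extra$varcomp
  expect_gt(vc[["den"]], 2)        # truth 4
  expect_lt(vc[["den"]], 7)
  expect_gt(vc[["Residual"]], 0.6) # truth 1
  expect_lt(vc[["Residual"]], 1.6)
  # treatment coding against the requested reference
  expect_true("grpF1" %in% fit$terms$term)
  est <- fit$terms$estimate[fit$terms$term == "grpF1"]
  expect_gt(est, 0.8); expect_lt(est, 2.2)
  expect_error(fit_ancestry_lmm(rec, "y", "grp", fixed = character(0),
                                random = "den", reference = "nope"),
               class = "loadfit_input_error")
  one_den <- rec; one_den$den <- "d1"
  expect_error(fit_ancestry_lmm(one_den, "y", "grp", fixed = character(0),
                                random = "den"),
               class = "loadfit_model_error")
})

test_that("a zero den effect is reported as a singular fit", {
  set.seed(1)
  rec <- data.frame(y = rnorm(120), grp = rep(c("a", "b"), 60),
                    den = rep(paste0("d", 1:30), each = 4))
  expect_warning(
    fit <- fit_ancestry_lmm(rec, "y", "grp", fixed = character(0), random = "den"),
    "singular")
  expect_true(fit$extra$singular)
  expect_equal(fit$extra$varcomp[["den"]], 0, tolerance = 1e-6)
})

test_that("group_mean_contrast reproduces printed-precision differences", {
  means <- c(F1 = 12.19, F2F3 = 6.94, native = 7.60)
  out <- group_mean_contrast(means, groups = c("F1", "F2F3"))
  expect_equal(out$difference, 5.25)
  ls <- group_mean_contrast(c(F1 = 4.8, F2F3 = 3.2))
  expect_equal(ls$difference, 1.6)
  lit <- group_mean_contrast(
    data.frame(group = c("native_x_native", "native_x_immigrantF14"),
               mean = c(6.30, 5.14)))
  expect_equal(lit$difference, 1.16)
  # rounding uses the larger decimal count of each pair
  expect_equal(group_mean_contrast(c(a = 1.5, b = 0.25))$difference, 1.25)
  expect_equal(nrow(group_mean_contrast(means)), 3)
  expect_error(group_mean_contrast(means, groups = c("F1", "zz")),
               class = "loadfit_input_error")
  expect_error(group_mean_contrast(c(a = 1)), class = "loadfit_input_error")
  expect_error(group_mean_contrast(c(1, 2)), class = "loadfit_input_error")
})

test_that("model_result enforces its term-table contract", {
  terms <- data.frame(term = "x", estimate = 1, se = 0.1, statistic = 10,
                      p_value = 0.001, ci_lo = 0.8, ci_hi = 1.2)
  expect_s3_class(model_result("f", "y", terms, n = 10), "model_result")
  bad <- terms; bad$ci_lo <- 1.1
  expect_error(model_result("f", "y", bad, n = 10),
               class = "loadfit_internal_error")
  expect_error(model_result("f", "y", terms[, -2], n = 10))
})
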