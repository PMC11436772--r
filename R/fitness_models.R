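# Models linking load metrics, heterozygosity and ancestry to fitness traits:
# OLS linear models with the study's fixed transforms (sqrt LRS, log
# longevity, identity litter size), binomial GLMs for first-year survival,
# random-intercept LMMs for the ancestry contrasts, Mann-Whitney group
# comparisons and Pearson correlations. P values are two-sided and not
# adjusted for multiple testing across the model battery.

#' Container for one fitted model
#'
#' @param family model family label.
#' @param response response description (including transform).
#' @param terms data.frame with columns term, estimate, se, statistic,
#'   p_value, ci_lo, ci_hi.
#' @param r_squared coefficient of determination (linear models, else NA).
#' @param n number of observations used.
#' @param extra optional named list of fit metadata.
#' @return object of class `model_result`.
#' @export
model_result <- function(family, response, terms, r_squared = NA_real_, n,
                         extra = list()) {
  stopifnot(all(c("term", "estimate", "se", "statistic", "p_value",
                  "ci_lo", "ci_hi") %in% names(terms)))
  bad_ci <- with(terms, !is.na(ci_lo) & (ci_lo > estimate | ci_hi < estimate))
  if (any(bad_ci)) stop_loadfit("confidence bounds must bracket the estimate",
                                "loadfit_internal_error")
  structure(list(family = family, response = response, terms = terms,
                 r_squared = r_squared, n = n, extra = extra),
            class = "model_result")
}

#' @export
print.model_result <- function(x, digits = 4, ...) {
  cat(sprintf("<model_result> %s: %s (n = %d%s)\n", x$family, x$response, x$n,
              if (!is.na(x$r_squared)) sprintf(", R^2 = %.3f", x$r_squared) else ""))
  print(format(x$terms, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.model_result <- function(x, ...) x$terms

# transforms frozen to the study's choices
trait_response <- function(records, response) {
  switch(response,
         lrs_sqrt = {
           y <- records$lrs
           if (any(y < 0, na.rm = TRUE)) stop_loadfit("lrs must be >= 0", "loadfit_input_error")
           list(y = sqrt(y), label = "sqrt(lrs)")
         },
         longevity_log = {
           y <- records$longevity_years
           bad <- which(!is.na(y) & y <= 0)
           if (length(bad)) stop_loadfit(
             paste0("longevity must be positive for the log transform; offending record(s): ",
                    paste(records$id[bad] %||% bad, collapse = ", ")),
             "loadfit_input_error")
           list(y = log(y), label = "log(longevity_years)")
         },
         litter_size = list(y = records$mean_litter_size, label = "mean_litter_size"),
         stop_loadfit(paste0("unknown response: ", response), "loadfit_input_error"))
}

#' Box-Cox transform advice
#'
#' Maximises the Box-Cox profile log-likelihood of an intercept-only normal
#' model on a grid of lambda in [-2, 2] (step 0.01) and maps the maximiser to
#' a conventional transform: |lambda| <= 0.25 -> log, lambda in (0.25, 0.75]
#' -> sqrt, otherwise identity. Advisory only: the trait models always use
#' the frozen transforms (sqrt LRS, log longevity, identity litter size).
#'
#' @param values positive numeric vector.
#' @return list with `lambda` (the maximiser), `transform` and the profile
#'   (`grid`, `loglik`).
#' @export
boxcox_advise <- function(values) {
  values <- values[!is.na(values)]
  bad <- which(values <= 0)
  if (length(bad)) stop_loadfit(
    paste0("Box-Cox requires positive values; offending record(s): ",
           paste(bad, collapse = ", ")), "loadfit_input_error")
  if (length(values) < 3 || var(values) == 0) {
    warning("degenerate data: Box-Cox profile is flat; returning identity", call. = FALSE)
    return(list(lambda = NA_real_, transform = "identity",
                grid = numeric(0), loglik = numeric(0)))
  }
  grid <- seq(-2, 2, by = 0.01)
  n <- length(values)
  slog <- sum(log(values))
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(values) else (values^lam - 1) / lam
    s2 <- sum((z - mean(z))^2) / n
    -n / 2 * log(s2) + (lam - 1) * slog
  }, numeric(1))
  lam_hat <- grid[which.max(ll)]
  transform <- if (abs(lam_hat) <= 0.25) "log" else
    if (lam_hat > 0.25 && lam_hat <= 0.75) "sqrt" else "identity"
  list(lambda = lam_hat, transform = transform, grid = grid, loglik = ll)
}

build_design_data <- function(records, y, predictors, covariates) {
  dat <- records[, intersect(c(predictors, covariates), names(records)), drop = FALSE]
  missing_cols <- setdiff(c(predictors, covariates), names(records))
  if (length(missing_cols)) stop_loadfit(
    paste0("columns missing from records: ", paste(missing_cols, collapse = ", ")),
    "loadfit_input_error")
  dat$.y <- y
  cc <- complete.cases(dat)
  dat[cc, , drop = FALSE]
}

lm_terms <- function(fit, level = 0.95) {
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- suppressMessages(stats::confint(fit, level = level))
  data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
             statistic = co[, 3], p_value = co[, 4],
             ci_lo = ci[rownames(co), 1], ci_hi = ci[rownames(co), 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Linear model for a fitness trait
#'
#' Ordinary least-squares fit of a transformed fitness trait on one genomic
#' predictor plus covariates, with two-sided t tests and 95% confidence
#' intervals. Transforms are frozen: square-root for LRS, log for longevity
#' (adults only, longevity >= 1), identity for mean litter size.
#'
#' @param records data.frame holding the joined load-profile and fitness
#'   columns (id, lrs, longevity_years, mean_litter_size, sex, rodent_phase,
#'   and the predictor columns).
#' @param response one of `"lrs_sqrt"`, `"longevity_log"`, `"litter_size"`.
#' @param predictor name of the genomic predictor column (e.g. `"e_lof"`,
#'   `"m_lof"`, `"e_mis"`, `"e_syn"`, `"het_per_kb"`).
#' @param covariates character vector of covariate columns (default sex and
#'   rodent phase); use `character(0)` for none.
#' @return a [model_result].
#' @export
fit_trait_lm <- function(records, response, predictor,
                         covariates = c("sex", "rodent_phase")) {
  resp <- trait_response(records, response)
  dat <- build_design_data(records, resp$y, predictor, covariates)
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  fit <- lm(as.formula(paste(".y ~", rhs)), data = dat)
  if (anyNA(coef(fit))) {
    stop_loadfit(paste0("rank-deficient design; collinear term(s): ",
                        paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
                 "loadfit_model_error")
  }
  if (nrow(dat) <= length(coef(fit))) {
    stop_loadfit("not enough complete cases for the number of parameters",
                 "loadfit_model_error")
  }
  model_result("gaussian lm", resp$label, lm_terms(fit),
               r_squared = summary(fit)$r.squared, n = nrow(dat),
               extra = list(sigma = summary(fit)$sigma, predictor = predictor))
}

#' Binomial GLM for juvenile survival
#'
#' Logistic regression (logit link, maximum likelihood) of first-year
#' survival on one or more genomic predictors plus covariates, with Wald z
#' statistics.
#'
#' @param records data.frame with a binary `juvenile_survival` column and the
#'   predictor/covariate columns.
#' @param predictor character vector of predictor column names.
#' @param covariates covariate columns; `character(0)` for none.
#' @return a [model_result].
#' @export
fit_juvenile_survival_glm <- function(records, predictor,
                                      covariates = c("sex", "rodent_phase")) {
  y <- records$juvenile_survival
  if (!all(y %in% c(0, 1) | is.na(y))) {
    stop_loadfit("juvenile_survival must be binary 0/1", "loadfit_input_error")
  }
  dat <- build_design_data(records, y, predictor, covariates)
  if (length(unique(dat$.y)) < 2) {
    stop_loadfit("response is constant (all 0 or all 1); the survival model is not estimable",
                 "loadfit_model_error")
  }
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(as.formula(paste(".y ~", rhs)), data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation || !fit$converged) {
    stop_loadfit("(quasi-)complete separation detected; consider a penalized (Firth) logistic fit",
                 "loadfit_model_error")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  ci_lo <- co[, 1] - qnorm(0.975) * co[, 2]
  ci_hi <- co[, 1] + qnorm(0.975) * co[, 2]
  terms <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      statistic = co[, 3], p_value = co[, 4],
                      ci_lo = ci_lo, ci_hi = ci_hi,
                      row.names = NULL, stringsAsFactors = FALSE)
  model_result("binomial glm (logit)", "juvenile_survival", terms,
               n = nrow(dat),
               extra = list(deviance = fit$deviance, predictor = predictor))
}

#' Random-intercept LMM for ancestry effects
#'
#' REML fit of `response ~ ancestry + fixed covariates + (1 | random)` with
#' Wald t tests for the fixed effects. Degrees of freedom use the residual
#' (n - rank) approximation. A singular random-effect variance is retained
#' and reported as 0 with a warning.
#'
#' @param records data.frame (individuals or litters).
#' @param response `"lrs_sqrt"`, `"longevity_log"`, `"litter_size"` for trait
#'   columns, or the name of a numeric column (e.g. a litter table's
#'   `litter_size` column).
#' @param ancestry name of the ancestry/pair-combination factor column.
#' @param fixed additional fixed-effect columns (e.g. sex, rodent_phase).
#' @param random grouping column for the random intercept (natal den).
#' @param reference optional reference level for the ancestry factor
#'   (treatment coding); contrasts are reported against it.
#' @return a [model_result]; `extra` carries the variance components.
#' @export
fit_ancestry_lmm <- function(records, response, ancestry,
                             fixed = c("rodent_phase"), random = "natal_den",
                             reference = NULL) {
  if (response %in% c("lrs_sqrt", "longevity_log", "litter_size") &&
      !response %in% names(records)) {
    resp <- trait_response(records, response)
    y <- resp$y; label <- resp$label
  } else {
    if (!response %in% names(records)) {
      stop_loadfit(paste0("unknown response column: ", response), "loadfit_input_error")
    }
    y <- records[[response]]; label <- response
  }
  dat <- build_design_data(records, y, ancestry, c(fixed, random))
  dat[[ancestry]] <- factor(dat[[ancestry]])
  if (!is.null(reference)) {
    if (!reference %in% levels(dat[[ancestry]])) {
      stop_loadfit(paste0("reference level not found: ", reference), "loadfit_input_error")
    }
    dat[[ancestry]] <- stats::relevel(dat[[ancestry]], ref = reference)
  }
  if (length(unique(dat[[random]])) < 2) {
    stop_loadfit("at least 2 grouping levels are required for the random intercept",
                 "loadfit_model_error")
  }
  fml <- as.formula(paste(".y ~", paste(c(ancestry, fixed), collapse = " + "),
                          "+ (1 |", random, ")"))
  fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("singular fit: random-intercept variance estimated as 0", call. = FALSE)
  }
  co <- summary(fit)$coefficients  # Estimate, Std. Error, t value
  n <- nrow(dat)
  df <- n - nrow(co)
  tval <- co[, "t value"]
  p <- 2 * pt(-abs(tval), df = df)
  crit <- qt(0.975, df = df)
  terms <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      statistic = tval, p_value = p,
                      ci_lo = co[, 1] - crit * co[, 2],
                      ci_hi = co[, 1] + crit * co[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  model_result("gaussian lmm (REML, random intercept)", label, terms,
               n = n,
               extra = list(varcomp = setNames(vc$vcov, vc$grp),
                            df = df, singular = lme4::isSingular(fit, tol = 1e-5)))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with a Hodges-Lehmann
#' location-shift estimate and confidence interval: exact p for small
#' tie-free samples, normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @param conf.level confidence level for the location-shift interval.
#' @return list with `U` (statistic for group A), `p_value`, `estimate`
#'   (Hodges-Lehmann shift A - B), `ci`, and `method`.
#' @export
mann_whitney_groups <- function(values_a, values_b, conf.level = 0.95) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop_loadfit("both groups must be non-empty", "loadfit_input_error")
  }
  wt <- suppressWarnings(wilcox.test(values_a, values_b, conf.int = TRUE,
                                     conf.level = conf.level))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       estimate = unname(wt$estimate), ci = unname(wt$conf.int),
       method = wt$method)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values.
#' @return list with `r`, `t`, `p_value`, `ci`, `n`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_loadfit("need at least 3 complete pairs", "loadfit_input_error")
  if (var(x) == 0 || var(y) == 0) {
    stop_loadfit("zero variance in x or y", "loadfit_input_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       p_value = ct$p.value,
       ci = if (!is.null(ct$conf.int)) as.vector(ct$conf.int) else c(NA_real_, NA_real_),
       n = length(x))
}

n_decimals <- function(x) {
  s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(x, digits = 12, scientific = FALSE)))
  nchar(s)
}

#' Pairwise differences of printed group means
#'
#' Unadjusted pairwise differences of group means, reported to the precision
#' of the printed inputs (the larger decimal count of each pair).
#'
#' @param means named numeric vector (names = group labels) or data.frame
#'   with columns `group` and `mean`.
#' @param groups optional character vector restricting the contrasts to these
#'   groups; an unknown label is an error.
#' @return data.frame with columns group_a, group_b, difference (mean_a -
#'   mean_b).
#' @export
group_mean_contrast <- function(means, groups = NULL) {
  if (is.data.frame(means)) {
    if (!all(c("group", "mean") %in% names(means))) {
      stop_loadfit("data.frame input needs columns 'group' and 'mean'", "loadfit_input_error")
    }
    means <- setNames(means$mean, means$group)
  }
  if (!is.null(groups)) {
    unknown <- setdiff(groups, names(means))
    if (length(unknown)) stop_loadfit(
      paste0("unknown group label(s): ", paste(unknown, collapse = ", ")),
      "loadfit_input_error")
    means <- means[groups]
  }
  if (length(means) < 2) stop_loadfit("need at least 2 groups", "loadfit_input_error")
  if (is.null(names(means)) || any(!nzchar(names(means)))) {
    stop_loadfit("group means must be named", "loadfit_input_error")
  }
  pairs <- combn(names(means), 2)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    difference = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- means[[pairs[1, i]]]; b <- means[[pairs[2, i]]]
    out$difference[i] <- round(a - b, max(n_decimals(a), n_decimals(b)))
  }
  out
}
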