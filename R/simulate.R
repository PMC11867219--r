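#' Cohort composition for the simulation engine
#'
#' The seven proportions that determine a simulated cohort's phenotype
#' structure: the sex split, disease prevalence within each sex, and the
#' probability of a positive first-degree family history within each
#' sex-by-case stratum.
#'
#' @param p_female P(female).
#' @param p_case_female,p_case_male Disease prevalence within each sex.
#' @param p_fh_female_control,p_fh_female_case,p_fh_male_control,p_fh_male_case
#'   P(family history = 1) within the four sex-by-case strata.
#' @param label Optional label (e.g. the cancer type).
#' @return A `cohort_proportions` object.
#' @export
cohort_proportions <- function(p_female, p_case_female, p_case_male,
                               p_fh_female_control, p_fh_female_case,
                               p_fh_male_control, p_fh_male_case,
                               label = NA_character_) {
  v <- c(p_female, p_case_female, p_case_male, p_fh_female_control,
         p_fh_female_case, p_fh_male_control, p_fh_male_case)
  if (any(v < 0 | v > 1)) stop("all proportions must lie in [0, 1]")
  structure(list(p_female = p_female, p_case_female = p_case_female,
                 p_case_male = p_case_male,
                 p_fh_female_control = p_fh_female_control,
                 p_fh_female_case = p_fh_female_case,
                 p_fh_male_control = p_fh_male_control,
                 p_fh_male_case = p_fh_male_case, label = label),
            class = "cohort_proportions")
}

#' Packaged cohort compositions for four cancers
#'
#' Sex, case and family-history proportions matching the UK Biobank cohort
#' for breast, prostate, bowel and lung cancer, as used in the power
#' simulations. `ukb_cancer_counts()` returns the corresponding realised
#' case/control counts by sex.
#'
#' @param cancer One of `"breast"`, `"prostate"`, `"bowel"`, `"lung"`.
#' @return [cohort_proportions()] for `cancer_proportions()`; a one-row data
#'   frame of counts for `ukb_cancer_counts()`.
#' @export
cancer_proportions <- function(cancer = c("breast", "prostate", "bowel", "lung")) {
  cancer <- match.arg(cancer)
  tab <- list(
    breast   = c(0.54, 0.079,  0.00049, 0.11,  0.18, 0.10,  0.16),
    prostate = c(0.54, 0,      0.061,   0.081, 0,    0.077, 0.15),
    bowel    = c(0.54, 0.013,  0.021,   0.11,  0.15, 0.12,  0.18),
    lung     = c(0.54, 0.0077, 0.0099,  0.13,  0.23, 0.13,  0.22))
  v <- tab[[cancer]]
  cohort_proportions(v[1], v[2], v[3], v[4], v[5], v[6], v[7], label = cancer)
}

#' @rdname cancer_proportions
#' @export
ukb_cancer_counts <- function(cancer = c("breast", "prostate", "bowel", "lung")) {
  cancer <- match.arg(cancer)
  tab <- data.frame(
    cancer = c("breast", "prostate", "bowel", "lung"),
    female_controls = c(209435, 227393, 224404, 225641),
    female_cases = c(17958, 0, 2989, 1752),
    male_controls = c(191820, 180249, 187956, 190009),
    male_cases = c(94, 11665, 3958, 1905))
  tab[tab$cancer == cancer, ]
}

#' Simulation configuration
#'
#' Bundles every parameter of a Monte-Carlo power or type-I-error run. The
#' defaults are the study conditions the engine targets: cohorts of 450,000,
#' 5,000 replicates, a baseline aggregate carrier frequency of 0.001
#' (`alpha = log(0.001)` on the logit scale), a sex effect of
#' `beta3 = log(1.15)` (attached to males by default), family-history weight 0.5 in
#' both the generator and the Model 3 fit, and significance levels 0.05
#' (nominal) and 2.5e-6 (exome-wide).
#'
#' @param proportions A [cohort_proportions()] object.
#' @param n Cohort size per replicate.
#' @param reps Number of Monte-Carlo replicates.
#' @param or_grid Odds ratios to simulate under the alternative.
#' @param k_generate Family-history weight in the generating model
#'   (`beta2 = k_generate * log(OR)`).
#' @param k_fit Weight used when fitting Model 3.
#' @param alpha Generator intercept on the logit scale.
#' @param beta3 Generator sex log odds ratio.
#' @param levels Named significance levels (rejection uses strict `<`).
#' @param seed Master seed; together with the replicate index it fully
#'   determines every replicate (counter-based derivation, so replicates are
#'   reproducible in any order).
#' @param sex_one Which sex the indicator codes as 1 — that sex receives
#'   `beta3`. The default `"male"` is the calibration that reproduces the
#'   published operating characteristics of the four cancer cohorts; see the
#'   methods vignette.
#' @return A `sim_config` object.
#' @export
sim_config <- function(proportions, n = 450000, reps = 5000, or_grid = 2,
                       k_generate = 0.5, k_fit = 0.5, alpha = log(0.001),
                       beta3 = log(1.15),
                       levels = c(nominal = 0.05, exome_wide = 2.5e-6),
                       seed = 1, sex_one = c("male", "female")) {
  sex_one <- match.arg(sex_one)
  stopifnot(n >= 1, reps >= 1, all(levels > 0 & levels < 1),
            all(or_grid > 0), is.finite(k_generate), is.finite(k_fit))
  if (is.null(names(levels))) {
    names(levels) <- paste0("level_", format(levels, trim = TRUE))
  }
  structure(list(proportions = proportions, n = n, reps = reps,
                 or_grid = or_grid, k_generate = k_generate, k_fit = k_fit,
                 alpha = alpha, beta3 = beta3, levels = levels,
                 seed = as.integer(seed), sex_one = sex_one),
            class = "sim_config")
}

#' Counter-based replicate seed
#'
#' Derives a deterministic seed below 2^31 from the master seed, a stream
#' identifier and a counter, so any replicate can be regenerated in
#' isolation and replicates may run in any order.
#'
#' @param master Master seed (integer).
#' @param stream Stream identifier (e.g. encodes the scenario).
#' @param counter Replicate counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
replicate_seed <- function(master, stream, counter) {
  s <- (as.double(master) * 69069 + as.double(stream) * 1000003 +
        as.double(counter) * 10007 + 12345) %% 2147483646
  as.integer(s) + 1L
}

# stream id encoding the generating scenario (OR, k_generate)
scenario_stream <- function(or, k_generate) {
  round(1000 * or) + 1e6 * round(1000 * k_generate)
}

#' Simulate the phenotype structure of one cohort
#'
#' Draws sex, then case status given sex, then family history given sex and
#' case status, each by binomial sampling at the configured proportions, and
#' returns the 2 x 2 x 2 phenotype cell counts (sufficient for everything
#' downstream — individuals are exchangeable within cells).
#'
#' @param config A [sim_config()].
#' @param seed Replicate seed (see [replicate_seed()]).
#' @return Data frame with columns `sex`, `case`, `fh`, `n` (8 rows).
#' @export
generate_cohort <- function(config, seed) {
  set.seed(seed)
  pr <- config$proportions
  n <- config$n
  n_f <- stats::rbinom(1, n, pr$p_female)
  n_m <- n - n_f
  n_case_f <- stats::rbinom(1, n_f, pr$p_case_female)
  n_case_m <- stats::rbinom(1, n_m, pr$p_case_male)
  strata <- data.frame(
    female = c(1, 1, 0, 0), case = c(0, 1, 0, 1),
    n = c(n_f - n_case_f, n_case_f, n_m - n_case_m, n_case_m),
    p_fh = c(pr$p_fh_female_control, pr$p_fh_female_case,
             pr$p_fh_male_control, pr$p_fh_male_case))
  n_fh <- stats::rbinom(4, strata$n, strata$p_fh)
  sex <- if (config$sex_one == "female") strata$female else 1 - strata$female
  out <- rbind(
    data.frame(sex = sex, case = strata$case, fh = 0, n = strata$n - n_fh),
    data.frame(sex = sex, case = strata$case, fh = 1, n = n_fh))
  rownames(out) <- NULL
  out
}

#' Draw carrier counts given the phenotype cells
#'
#' For each phenotype cell the number of carriers is binomial with success
#' probability `expit(alpha + beta1 case + beta2 fh + beta3 sex)` where
#' `beta1 = log(OR)` and `beta2 = k_generate * log(OR)`.
#'
#' @param pheno_cells Output of [generate_cohort()].
#' @param or Generating odds ratio (`or = 1` simulates the null).
#' @param config A [sim_config()] (supplies `alpha`, `beta3`, `k_generate`).
#' @param seed Replicate seed.
#' @return A [cohort_cells()] table ready for the model fits.
#' @export
generate_carriers <- function(pheno_cells, or, config, seed) {
  set.seed(seed)
  b1 <- log(or)
  b2 <- config$k_generate * b1
  pcar <- stats::plogis(config$alpha + b1 * pheno_cells$case +
                        b2 * pheno_cells$fh + config$beta3 * pheno_cells$sex)
  nc <- stats::rbinom(nrow(pheno_cells), pheno_cells$n, pcar)
  cells_from_counts(data.frame(sex = pheno_cells$sex, case = pheno_cells$case,
                               fh = pheno_cells$fh, n_carrier = nc,
                               n_total = pheno_cells$n))
}

# Lean grouped fit returning only what the power loop needs. Shares
# model_design/glm.fit/grouped_loglik with fit_core; tests assert its
# log-likelihood equals fit_core's.
fit_ll <- function(cells, model, k = NULL) {
  keep <- cells$n_total > 0
  y <- cells$n_carrier[keep] / cells$n_total[keep]
  w <- cells$n_total[keep]
  X <- model_design(cells$case[keep], cells$fh[keep], cells$sex[keep],
                    model, k)
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = w, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  ll <- grouped_loglik(cells$n_carrier[keep], w, fit$fitted.values)
  list(loglik = ll, df = fit$rank, converged = fit$converged,
       separation = any(abs(fit$coefficients) > 15, na.rm = TRUE) ||
         !fit$converged)
}

# One replicate of the power loop: LRT p-values of m1/m2/m3 against the null.
replicate_pvalues <- function(config, or, rep, models) {
  stream <- scenario_stream(or, config$k_generate)
  pheno <- generate_cohort(config, replicate_seed(config$seed, stream, 2 * rep))
  cells <- generate_carriers(pheno, or, config,
                             replicate_seed(config$seed, stream, 2 * rep + 1))
  ncar <- sum(cells$n_carrier)
  if (ncar == 0 || ncar == sum(cells$n_total)) {
    return(list(p = rep(NA_real_, length(models)), ok = FALSE))
  }
  nul <- fit_ll(cells, "null")
  ok <- nul$converged && !nul$separation
  p <- vapply(models, function(m) {
    f <- fit_ll(cells, m, k = if (m == "m3") config$k_fit else NULL)
    ok <<- ok && f$converged && !f$separation
    stat <- max(0, 2 * (f$loglik - nul$loglik))
    stats::pchisq(stat, df = f$df - nul$df, lower.tail = FALSE)
  }, numeric(1))
  list(p = p, ok = ok)
}

#' Monte-Carlo power of the burden models
#'
#' For each odds ratio in the configured grid, simulates `reps` cohorts,
#' fits the null model and Models 1-3 on the grouped phenotype-by-carrier
#' cells, and estimates power as the proportion of likelihood-ratio p-values
#' strictly below each significance level (1 df for Models 1 and 3, 2 df for
#' Model 2). Replicates with non-converged or separated fits are excluded
#' from the denominator and tallied.
#'
#' @param config A [sim_config()].
#' @param models Subset of `c("m1", "m2", "m3")` to fit.
#' @return A `power_estimate` data frame: one row per (OR, model, level)
#'   with `power`, Monte-Carlo `se`, normal 95% CI, `reps_used` and
#'   `n_degenerate`.
#' @export
estimate_power <- function(config, models = c("m1", "m2", "m3")) {
  stopifnot(inherits(config, "sim_config"), all(models %in% c("m1", "m2", "m3")))
  out <- list()
  for (or in config$or_grid) {
    rej <- array(0, dim = c(length(models), length(config$levels)))
    used <- 0L; degen <- 0L
    for (r in seq_len(config$reps)) {
      res <- replicate_pvalues(config, or, r, models)
      if (!res$ok) { degen <- degen + 1L; next }
      used <- used + 1L
      for (li in seq_along(config$levels)) {
        rej[, li] <- rej[, li] + (res$p < config$levels[li])
      }
    }
    for (mi in seq_along(models)) for (li in seq_along(config$levels)) {
      pw <- if (used > 0) rej[mi, li] / used else NA_real_
      se <- if (used > 1) sqrt(pw * (1 - pw) / used) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        or = or, model = models[mi], level = unname(config$levels[li]),
        level_name = names(config$levels)[li], power = pw, se = se,
        ci_low = if (is.na(se)) NA_real_ else max(0, pw - 1.96 * se),
        ci_high = if (is.na(se)) NA_real_ else min(1, pw + 1.96 * se),
        reps_used = used, n_degenerate = degen)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("power_estimate", "data.frame")
  attr(res, "seed") <- config$seed
  res
}

#' Monte-Carlo type-I error under the null
#'
#' Runs [estimate_power()] with OR = 1 and adds, per row, the exact binomial
#' (Clopper-Pearson) 99% confidence interval of the rejection rate and a
#' flag for whether the nominal level lies inside it.
#'
#' @param config A [sim_config()]; its `or_grid` is ignored.
#' @inheritParams estimate_power
#' @return A `power_estimate` data frame with extra columns `ci99_low`,
#'   `ci99_high`, `level_consistent`.
#' @export
estimate_type1 <- function(config, models = c("m1", "m2", "m3")) {
  config$or_grid <- 1
  res <- estimate_power(config, models)
  ci <- t(vapply(seq_len(nrow(res)), function(i) {
    if (is.na(res$power[i]) || res$reps_used[i] < 1) return(c(NA_real_, NA_real_))
    bt <- stats::binom.test(round(res$power[i] * res$reps_used[i]),
                            res$reps_used[i], conf.level = 0.99)
    bt$conf.int
  }, numeric(2)))
  res$ci99_low <- ci[, 1]
  res$ci99_high <- ci[, 2]
  res$level_consistent <- res$level >= res$ci99_low & res$level <= res$ci99_high
  res
}

#' Power over a grid of odds ratios and family-history weights
#'
#' Convenience wrapper running [estimate_power()] for every combination of
#' generating odds ratio and Model 3 fitting weight, returning one long
#' table. Cohort generation depends only on the master seed and OR, so runs
#' at different `k_fit` share replicates (common random numbers), which makes
#' cross-`k` power differences directly comparable.
#'
#' @param config A [sim_config()].
#' @param or_grid Odds ratios (defaults to the config's grid).
#' @param k_grid Model 3 fitting weights (defaults to the config's `k_fit`).
#' @param models Models to fit at each grid point.
#' @return Long data frame: `cancer`, `or`, `k_fit`, `model`, `level`,
#'   `power`, `se`, `reps_used`.
#' @export
power_curve <- function(config, or_grid = config$or_grid,
                        k_grid = config$k_fit, models = c("m1", "m2", "m3")) {
  out <- list()
  for (k in k_grid) {
    cfg <- config
    cfg$k_fit <- k
    cfg$or_grid <- or_grid
    if (length(or_grid) == 0) break
    pw <- estimate_power(cfg, models)
    pw$k_fit <- k
    out[[length(out) + 1L]] <- pw
  }
  if (!length(out)) {
    return(data.frame(cancer = character(), or = numeric(), k_fit = numeric(),
                      model = character(), level = numeric(), power = numeric(),
                      se = numeric(), reps_used = integer()))
  }
  res <- do.call(rbind, out)
  data.frame(cancer = config$proportions$label, or = res$or, k_fit = res$k_fit,
             model = res$model, level = res$level, power = res$power,
             se = res$se, reps_used = res$reps_used)
}
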