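#' Cross-classified cohort cell counts
#'
#' When the only covariates are the three binaries (case status, family
#' history, sex), the 2 x 2 x 2 x 2 table of counts over
#' sex x case x FH x carrier is sufficient for every burden model fitted by
#' this package, and fitting on the grouped table is orders of magnitude
#' faster than on individual records. `cohort_cells()` builds the table from
#' per-sample records; `cells_from_counts()` takes the counts directly.
#'
#' @param records Data frame with binary columns `case`, `fh`, `sex` and
#'   `carrier` (0/1), one row per sample.
#' @return An object of class `cohort_cells`: a data frame with one row per
#'   sex x case x FH stratum and columns `sex`, `case`, `fh`, `n_carrier`,
#'   `n_total`.
#' @export
cohort_cells <- function(records) {
  needed <- c("case", "fh", "sex", "carrier")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  for (v in needed) {
    if (!all(records[[v]] %in% c(0, 1))) {
      stop("column '", v, "' must be binary 0/1")
    }
  }
  grid <- expand.grid(sex = 0:1, case = 0:1, fh = 0:1)
  key_r <- records$sex + 2L * records$case + 4L * records$fh
  key_g <- grid$sex + 2L * grid$case + 4L * grid$fh
  n_total <- tabulate(match(key_r, key_g), nbins = 8L)
  n_carr <- vapply(seq_len(8L), function(i) {
    sum(records$carrier[key_r == key_g[i]])
  }, numeric(1))
  cells_from_counts(data.frame(grid, n_carrier = n_carr, n_total = n_total))
}

#' @rdname cohort_cells
#' @param counts Data frame with columns `sex`, `case`, `fh`, `n_carrier`,
#'   `n_total` (counts may be real-valued for expected-count designs).
#' @export
cells_from_counts <- function(counts) {
  needed <- c("sex", "case", "fh", "n_carrier", "n_total")
  miss <- setdiff(needed, names(counts))
  if (length(miss)) stop("counts lack column(s): ", paste(miss, collapse = ", "))
  if (any(counts$n_carrier < 0) || any(counts$n_total < counts$n_carrier)) {
    stop("need 0 <= n_carrier <= n_total in every cell")
  }
  out <- counts[, needed]
  class(out) <- c("cohort_cells", "data.frame")
  out
}

#' Expand grouped cells back to per-sample records
#'
#' Inverse of [cohort_cells()] (up to row order); used mainly to verify the
#' sufficiency of the grouped representation. Counts must be whole numbers.
#'
#' @param cells A `cohort_cells` object.
#' @return Data frame of per-sample records with `case`, `fh`, `sex`, `carrier`.
#' @export
expand_cells <- function(cells) {
  stopifnot(inherits(cells, "cohort_cells"))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n_total[i]
    if (n == 0) return(NULL)
    data.frame(case = rep(cells$case[i], n), fh = rep(cells$fh[i], n),
               sex = rep(cells$sex[i], n),
               carrier = rep(c(1, 0), c(cells$n_carrier[i],
                                        n - cells$n_carrier[i])))
  })
  do.call(rbind, rows)
}

# Build the design matrix for one of the burden models.
model_design <- function(case, fh, sex, model, k, extra = NULL) {
  X <- switch(model,
    "null" = cbind(alpha = 1, beta3 = sex),
    "m1"   = cbind(alpha = 1, beta1 = case, beta3 = sex),
    "m2"   = cbind(alpha = 1, beta1 = case, beta2 = fh, beta3 = sex),
    "m3"   = cbind(alpha = 1, beta1 = case + k * fh, beta3 = sex),
    stop("unknown model tag: ", model))
  if (!is.null(extra) && ncol(extra) > 0) X <- cbind(X, extra)
  X
}

# Bernoulli log-likelihood on grouped counts (no binomial-coefficient term,
# so grouped and expanded representations give identical values).
grouped_loglik <- function(n_carrier, n_total, mu) {
  n_non <- n_total - n_carrier
  sum(ifelse(n_carrier > 0, n_carrier * log(mu), 0) +
      ifelse(n_non > 0, n_non * log1p(-mu), 0))
}

# Core ML fit shared by fit_null / fit_model1 / fit_model2 / fit_model3.
# `data` is a cohort_cells table or a per-record data frame with a `carrier`
# column; `covariates` names extra numeric columns (per-record path only).
fit_core <- function(data, model, k = NULL, covariates = character()) {
  grouped <- inherits(data, "cohort_cells")
  if (grouped && length(covariates)) {
    stop("extra covariates require per-record data, not grouped cells")
  }
  if (grouped) {
    keep <- data$n_total > 0
    cells <- data[keep, , drop = FALSE]
    y <- cells$n_carrier / cells$n_total
    w <- cells$n_total
    X <- model_design(cells$case, cells$fh, cells$sex, model, k)
    n <- sum(w)
    n_carriers <- sum(cells$n_carrier)
    nc <- cells$n_carrier; nt <- cells$n_total
  } else {
    needed <- c("carrier", "case", "fh", "sex")
    miss <- setdiff(needed, names(data))
    if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
    extra <- if (length(covariates)) {
      bad <- setdiff(covariates, names(data))
      if (length(bad)) stop("unknown covariate column(s): ", paste(bad, collapse = ", "))
      as.matrix(data[, covariates, drop = FALSE])
    } else NULL
    y <- data$carrier
    w <- rep(1, nrow(data))
    X <- model_design(data$case, data$fh, data$sex, model, k, extra)
    n <- nrow(data)
    n_carriers <- sum(y)
    nc <- y; nt <- w
  }
  if (n_carriers == 0 || n_carriers == n) {
    stop("cannot fit '", model, "': need at least one carrier and one ",
         "non-carrier (observed ", n_carriers, " of ", n, ")")
  }
  # a constant model column (beyond the intercept) is inestimable
  for (j in seq_len(ncol(X))[-1]) {
    vals <- X[, j][w > 0]
    if (length(unique(vals)) < 2) {
      stop("covariate '", colnames(X)[j], "' is constant in the data (",
           "model '", model, "' is inestimable)")
    }
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = w, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  vc <- matrix(NA_real_, ncol(X), ncol(X),
               dimnames = list(colnames(X), colnames(X)))
  vc[piv, piv] <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  mu <- fit$fitted.values
  ll <- grouped_loglik(nc, nt, mu)
  separation <- any(abs(beta) > 15, na.rm = TRUE) || !fit$converged
  if (separation) {
    warning("possible separation or non-convergence in model '", model, "'")
  }
  structure(list(
    model = model, k = k, coefficients = beta, vcov = vc, loglik = ll,
    df = p, n = n, n_carriers = n_carriers, converged = fit$converged,
    separation = separation,
    k_T = if (model == "m2") unname(beta["beta2"] / beta["beta1"]) else NULL),
    class = "fh_model_fit")
}

#' @export
print.fh_model_fit <- function(x, ...) {
  cat(sprintf("burden model '%s'%s: n = %g, carriers = %g, logLik = %.4f%s\n",
              x$model, if (!is.null(x$k)) sprintf(" (k = %g)", x$k) else "",
              x$n, x$n_carriers, x$loglik,
              if (x$separation) " [separation flagged]" else ""))
  print(x$coefficients)
  if (!is.null(x$k_T)) cat(sprintf("k_T = beta2/beta1 = %.4f\n", x$k_T))
  invisible(x)
}

#' Fit the burden association models
#'
#' Maximum-likelihood fits of the reversed logistic regression in which
#' carrier status G is the outcome:
#' \describe{
#'   \item{null}{`logit P(G=1) = alpha + beta3 Sex (+ covariates)`}
#'   \item{Model 1}{adds `beta1 Case` — the standard case-control burden model}
#'   \item{Model 2}{adds `beta1 Case + beta2 FH` — free family-history effect;
#'     the fit also reports `k_T = beta2/beta1`}
#'   \item{Model 3}{adds `beta1 (Case + k FH)` — the composite-phenotype model
#'     with a fixed family-history weight `k`}
#' }
#' Regressing carrier status on disease status rather than the reverse leaves
#' the odds ratio unchanged (the 2 x 2 cross-product ratio is symmetric in the
#' two margins) and makes the family-history extension a one-line change of
#' covariate.
#'
#' Fitting uses iteratively reweighted least squares on the grouped cell table
#' when `data` is a [cohort_cells()] object (the fast path used by the
#' simulation engine) or on per-sample records otherwise. Separation (some
#' covariate pattern perfectly predicting carrier status) is detected via
#' diverging coefficients and flagged, never silently dropped.
#'
#' @param data A [cohort_cells()] table or a per-record data frame with binary
#'   columns `carrier`, `case`, `fh`, `sex` plus any covariate columns.
#' @param covariates Character vector naming extra numeric covariate columns
#'   (per-record data only).
#' @param k Family-history weight for Model 3 (finite; `k = 0` reproduces
#'   Model 1 and `k = 1` treats family history as equivalent to a case).
#'
#' @return An `fh_model_fit`: coefficients (`alpha`, `beta1`, `beta2`,
#'   `beta3`, ...), covariance matrix, Bernoulli log-likelihood, degrees of
#'   freedom, sample size, convergence and separation flags, and for Model 2
#'   the ratio `k_T`.
#' @seealso [lrt()], [wald_test()], [optimal_k()]
#' @export
fit_null <- function(data, covariates = character()) {
  fit_core(data, "null", covariates = covariates)
}

#' @rdname fit_null
#' @export
fit_model1 <- function(data, covariates = character()) {
  fit_core(data, "m1", covariates = covariates)
}

#' @rdname fit_null
#' @export
fit_model2 <- function(data, covariates = character()) {
  fit_core(data, "m2", covariates = covariates)
}

#' @rdname fit_null
#' @export
fit_model3 <- function(data, k = 0.5, covariates = character()) {
  if (!is.numeric(k) || !is.finite(k)) stop("k must be finite")
  fit_core(data, "m3", k = k, covariates = covariates)
}

#' Likelihood-ratio test of nested burden models
#'
#' Twice the log-likelihood difference referred to a chi-squared distribution
#' with degrees of freedom equal to the difference in free parameters: 1 df
#' for Model 1 or Model 3 against the null, 2 df for Model 2 against the null.
#'
#' @param fit,null_fit `fh_model_fit` objects on the same data, `null_fit`
#'   nested in `fit`.
#' @return List with `statistic` (clamped at 0), `df` and `p`.
#' @export
lrt <- function(fit, null_fit) {
  stopifnot(inherits(fit, "fh_model_fit"), inherits(null_fit, "fh_model_fit"))
  if (fit$n != null_fit$n || fit$n_carriers != null_fit$n_carriers) {
    stop("models were fitted on different data (n or carrier totals differ)")
  }
  df <- fit$df - null_fit$df
  if (df <= 0) stop("'null_fit' is not nested in 'fit' (no extra parameters)")
  stat <- max(0, 2 * (fit$loglik - null_fit$loglik))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Wald test and confidence interval for one coefficient
#'
#' @param fit An `fh_model_fit`.
#' @param coef Coefficient name (default `"beta1"`, the burden log-OR).
#' @return List with `estimate`, `se`, `z`, `p` (two-sided normal) and
#'   `ci95 = estimate +/- 1.96 se` on the log-odds scale.
#' @export
wald_test <- function(fit, coef = "beta1") {
  stopifnot(inherits(fit, "fh_model_fit"))
  if (!coef %in% names(fit$coefficients)) {
    stop("no coefficient named '", coef, "' in model '", fit$model, "'")
  }
  est <- unname(fit$coefficients[coef])
  se <- sqrt(fit$vcov[coef, coef])
  if (!is.finite(se) || se <= 0) {
    stop("degenerate standard error for '", coef, "'")
  }
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       ci95 = c(est - 1.96 * se, est + 1.96 * se))
}

#' Locally optimal family-history weight for a given effect size
#'
#' For a rare risk allele with case-control log-odds `beta1`, the allele
#' frequency in relatives of cases implies a family-history effect
#' `exp(beta2) = (exp(beta1) + 1) / 2`, hence an optimal composite weight
#' `k = beta2 / beta1 = log((exp(beta1) + 1) / 2) / beta1`. As `beta1 -> 0`
#' this tends to 1/2 (first-degree relatives share half their alleles), and it
#' increases with effect size, so weights above 1/2 favour large effects.
#'
#' @param beta1 Log odds ratio (scalar or vector).
#' @return The optimal weight `k`; exactly 0.5 when `|beta1| < 1e-8`.
#' @export
optimal_k <- function(beta1) {
  stopifnot(is.numeric(beta1))
  ifelse(abs(beta1) < 1e-8, 0.5, log((exp(beta1) + 1) / 2) / beta1)
}

#' Gene-by-gene burden association scan
#'
#' Fits the requested burden model and the null model per gene, reporting the
#' odds ratio, Wald and likelihood-ratio p-values and significance flags at
#' the supplied thresholds (applied as strict `<`). Genes with zero carriers
#' cannot be tested and are listed separately rather than dropped silently.
#'
#' @param carriers Named list of per-gene carrier indicators — either
#'   `burden_vector` objects from [collapse_burden()] or named 0/1 vectors
#'   keyed by sample id.
#' @param phenotypes Data frame with `sample_id`, `case`, `fh`, `sex` and any
#'   covariate columns (see [read_phenotypes()]).
#' @param model `"m1"`, `"m2"` or `"m3"`.
#' @param k Family-history weight when `model = "m3"`.
#' @param thresholds Named or unnamed numeric vector of significance levels;
#'   defaults to exome-wide `2.5e-6` and the follow-up level `1e-3`.
#' @param covariates Extra covariate column names in `phenotypes`.
#'
#' @return List with `results` (one data-frame row per tested gene: `gene`,
#'   `model`, `k`, `n_carriers`, `OR`, `CI_low`, `CI_high`, `p_wald`, `p_lrt`,
#'   significance flags, `converged`, `separation`) and `skipped` (gene ids
#'   with zero carriers).
#' @export
run_gene_scan <- function(carriers, phenotypes, model = "m3", k = 0.5,
                          thresholds = c(exome_wide = 2.5e-6, followup = 1e-3),
                          covariates = character()) {
  stopifnot(model %in% c("m1", "m2", "m3"))
  if (is.null(names(thresholds))) {
    names(thresholds) <- paste0("sig_", format(thresholds, trim = TRUE))
  } else {
    names(thresholds) <- paste0("sig_", names(thresholds))
  }
  results <- list()
  skipped <- character()
  for (gene in names(carriers)) {
    cv <- carriers[[gene]]
    g <- if (inherits(cv, "burden_vector")) cv$G else cv
    idx <- match(phenotypes$sample_id, names(g))
    if (anyNA(idx)) {
      offenders <- phenotypes$sample_id[is.na(idx)]
      stop("sample id(s) in phenotypes missing from carriers for gene ", gene,
           ": ", paste(utils::head(offenders, 10), collapse = ", "))
    }
    dat <- phenotypes
    dat$carrier <- as.numeric(g[idx])
    dat <- dat[!is.na(dat$carrier), , drop = FALSE]
    if (sum(dat$carrier) == 0) {
      skipped <- c(skipped, gene)
      next
    }
    input <- if (length(covariates)) dat else cohort_cells(dat)
    fit <- switch(model,
                  m1 = fit_model1(input, covariates),
                  m2 = fit_model2(input, covariates),
                  m3 = fit_model3(input, k, covariates))
    nul <- fit_null(input, covariates)
    lr <- lrt(fit, nul)
    wd <- wald_test(fit, "beta1")
    row <- data.frame(
      gene = gene, model = model, k = if (model == "m3") k else NA_real_,
      n_carriers = sum(dat$carrier), OR = exp(wd$estimate),
      CI_low = exp(wd$ci95[1]), CI_high = exp(wd$ci95[2]),
      p_wald = wd$p, p_lrt = lr$p,
      converged = fit$converged, separation = fit$separation)
    for (nm in names(thresholds)) row[[nm]] <- lr$p < thresholds[[nm]]
    results[[gene]] <- row
  }
  res <- if (length(results)) do.call(rbind, results) else data.frame()
  rownames(res) <- NULL
  list(results = res, skipped = skipped)
}
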