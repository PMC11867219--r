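#' Adjacent-categories per-allele association models
#'
#' For common variants the genotype G takes values 0, 1, 2 and collapsing to
#' carrier status discards information. The adjacent-categories analogue of
#' the burden models constrains each consecutive-category contrast to share
#' the same slopes:
#' \deqn{\log P(G=j+1)/P(G=j) = \alpha_{j0} + \eta_i, \quad j = 0, 1,}
#' with free intercepts `alpha00`, `alpha10` and a shared linear predictor
#' `eta` built exactly as in the binary models (`beta1 Case + beta3 Sex` for
#' Model 1, adding `beta2 FH` for Model 2, or `beta1 (Case + k FH)` for
#' Model 3). `beta1` is then the per-allele log odds ratio.
#'
#' The model is a constrained multinomial: the category log-weights are
#' `0, alpha00 + eta, alpha00 + alpha10 + 2 eta`. It is fitted by direct
#' maximisation of the grouped multinomial likelihood (BFGS with the analytic
#' gradient), with the covariance taken from the inverse observed information.
#' When no sample carries two copies the model collapses to the single
#' transition and the ordinary logistic fit is returned with the intercept
#' relabelled.
#'
#' @param G Integer vector of genotypes in \{0, 1, 2\}, one per row of `data`.
#' @param data Data frame with binary columns `case`, `fh`, `sex`.
#' @param model `"null"`, `"m1"`, `"m2"` or `"m3"`.
#' @param k Family-history weight when `model = "m3"`.
#'
#' @return An `fh_model_fit` with model tag `"ac-<model>"`; coefficients
#'   `alpha00`, `alpha10` (when both transitions are observed) and the shared
#'   slopes. [lrt()] applies unchanged for nested pairs.
#' @export
fit_adjacent_categories <- function(G, data, model = c("m1", "m2", "m3", "null"),
                                    k = 0.5) {
  model <- match.arg(model)
  if (length(G) != nrow(data)) stop("length(G) must equal nrow(data)")
  if (!all(G %in% 0:2)) stop("genotypes must be 0, 1 or 2")
  levels_present <- sort(unique(G))
  if (length(levels_present) < 2) {
    stop("only one genotype level present (all G = ", levels_present,
         "); the model is inestimable")
  }
  if (!any(G == 1) && any(G == 2)) {
    stop("genotype level 1 unobserved while level 2 is present; ",
         "both transition intercepts cannot be identified")
  }
  if (!any(G == 2)) {
    # single observed transition: ordinary logistic regression on G in {0,1}
    rec <- data
    rec$carrier <- G
    fit <- fit_core(rec, model, k = if (model == "m3") k else NULL)
    names(fit$coefficients)[names(fit$coefficients) == "alpha"] <- "alpha00"
    dimnames(fit$vcov) <- rep(list(names(fit$coefficients)), 2)
    fit$model <- paste0("ac-", model)
    return(fit)
  }

  eta_design <- function(d) switch(model,
    "null" = cbind(beta3 = d$sex),
    "m1"   = cbind(beta1 = d$case, beta3 = d$sex),
    "m2"   = cbind(beta1 = d$case, beta2 = d$fh, beta3 = d$sex),
    "m3"   = cbind(beta1 = d$case + k * d$fh, beta3 = d$sex))
  Z <- eta_design(data)
  for (j in seq_len(ncol(Z))) {
    if (length(unique(Z[, j])) < 2) {
      stop("covariate '", colnames(Z)[j], "' is constant in the data (",
           "model '", model, "' is inestimable)")
    }
  }
  # group samples by covariate pattern; counts per genotype category
  pat <- apply(Z, 1, paste, collapse = "\r")
  upat <- !duplicated(pat)
  Zu <- Z[upat, , drop = FALSE]
  idx <- match(pat, pat[upat])
  ncat <- vapply(0:2, function(j) {
    vapply(seq_len(sum(upat)), function(i) sum(G[idx == i] == j), numeric(1))
  }, numeric(sum(upat)))  # patterns x 3
  if (is.null(dim(ncat))) ncat <- matrix(ncat, nrow = 1)
  Ntot <- rowSums(ncat)
  q <- ncol(Zu)

  nll <- function(theta) {
    a1 <- theta[1]; a2 <- theta[2]; b <- theta[-(1:2)]
    eta <- drop(Zu %*% b)
    s1 <- a1 + eta; s2 <- a1 + a2 + 2 * eta
    m <- pmax(0, pmax(s1, s2))
    lse <- m + log(exp(-m) + exp(s1 - m) + exp(s2 - m))
    -sum(ncat[, 2] * s1 + ncat[, 3] * s2 - Ntot * lse)
  }
  gr <- function(theta) {
    a1 <- theta[1]; a2 <- theta[2]; b <- theta[-(1:2)]
    eta <- drop(Zu %*% b)
    s1 <- a1 + eta; s2 <- a1 + a2 + 2 * eta
    m <- pmax(0, pmax(s1, s2))
    denom <- exp(-m) + exp(s1 - m) + exp(s2 - m)
    p1 <- exp(s1 - m) / denom
    p2 <- exp(s2 - m) / denom
    g_a1 <- sum(ncat[, 2] + ncat[, 3] - Ntot * (p1 + p2))
    g_a2 <- sum(ncat[, 3] - Ntot * p2)
    resid <- ncat[, 2] + 2 * ncat[, 3] - Ntot * (p1 + 2 * p2)
    g_b <- drop(crossprod(Zu, resid))
    -c(g_a1, g_a2, g_b)
  }
  # moment starts for the intercepts, zero slopes
  tot <- colSums(ncat)
  start <- c(log((tot[2] + 0.5) / (tot[1] + 0.5)),
             log((tot[3] + 0.5) / (tot[2] + 0.5)), rep(0, q))
  opt <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  theta <- opt$par
  # Newton polish: BFGS stops on function decrease; a few Newton steps drive
  # the score to numerical zero (quadratic convergence near the optimum)
  H <- NULL
  grad_tol <- 1e-8 * max(1, sum(Ntot))
  for (it in 1:10) {
    g <- gr(theta)
    H <- stats::optimHess(theta, nll, gr)
    if (sqrt(sum(g^2)) < grad_tol) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - step
    if (nll(cand) <= nll(theta)) theta <- cand else break
  }
  names(theta) <- c("alpha00", "alpha10", colnames(Zu))
  vc <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, length(theta), length(theta))
  })
  dimnames(vc) <- list(names(theta), names(theta))
  converged <- opt$convergence == 0 && sqrt(sum(gr(theta)^2)) < grad_tol
  opt$value <- nll(theta)
  separation <- any(abs(theta) > 15) || !converged
  structure(list(
    model = paste0("ac-", model), k = if (model == "m3") k else NULL,
    coefficients = theta, vcov = vc, loglik = -opt$value,
    df = length(theta), n = length(G), n_carriers = sum(G > 0),
    converged = converged, separation = separation,
    k_T = if (model == "m2") unname(theta["beta2"] / theta["beta1"]) else NULL),
    class = "fh_model_fit")
}
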