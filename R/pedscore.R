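#' Allele-sharing weight by relationship to the proband
#'
#' Returns twice the kinship coefficient: the expected proportion of alleles
#' shared identical-by-descent with the proband. This is the weight each
#' relative's (incidence-adjusted) disease status receives in the pedigree
#' score statistic: 1 for the proband, 1/2 for first-degree relatives, 1/4
#' for second-degree relatives, 0 for unrelated individuals.
#'
#' @param relationship Character vector among `"self"`, `"first_degree"`,
#'   `"second_degree"`, `"unrelated"`.
#' @return Numeric vector of weights `2 * phi`.
#' @export
kinship_weight <- function(relationship) {
  w <- c(self = 1, first_degree = 0.5, second_degree = 0.25, unrelated = 0)
  bad <- setdiff(unique(relationship), names(w))
  if (length(bad)) stop("unknown relationship(s): ", paste(bad, collapse = ", "))
  unname(w[relationship])
}

#' Piecewise-constant cumulative incidence model
#'
#' Population cumulative disease hazard to age t, supplied as age-band values:
#' `Lambda0(t)` equals `cumhaz[i]` for `t` in the half-open band
#' `[age_start[i], age_start[i + 1])` and 0 below the first band. Values must
#' be nondecreasing. A plain R function of age is also accepted wherever an
#' incidence model is expected.
#'
#' @param age_start Strictly increasing band start ages (years).
#' @param cumhaz Nondecreasing cumulative hazards, one per band.
#' @return A function `Lambda0(t)` of class `incidence_model`.
#' @export
incidence_model <- function(age_start, cumhaz) {
  if (length(age_start) != length(cumhaz) || length(age_start) < 1) {
    stop("age_start and cumhaz must be nonempty and of equal length")
  }
  if (is.unsorted(age_start, strictly = TRUE)) {
    stop("age_start must be strictly increasing")
  }
  if (is.unsorted(cumhaz) || any(cumhaz < 0)) {
    stop("cumhaz must be nonnegative and nondecreasing")
  }
  f <- function(t) {
    idx <- findInterval(t, age_start)
    ifelse(idx == 0, 0, cumhaz[pmax(idx, 1)])
  }
  class(f) <- c("incidence_model", "function")
  f
}

# Validate a long-format pedigree table and return it with derived columns.
validate_pedigrees <- function(pedigrees) {
  needed <- c("ped_id", "relationship", "status", "age")
  miss <- setdiff(needed, names(pedigrees))
  if (length(miss)) stop("pedigree table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"genotype" %in% names(pedigrees)) pedigrees$genotype <- NA_real_
  if (!all(pedigrees$status %in% c(0, 1))) stop("status must be 0/1")
  if (any(pedigrees$age < 0, na.rm = TRUE)) stop("ages must be >= 0")
  pedigrees$w <- kinship_weight(pedigrees$relationship)
  is_proband <- pedigrees$relationship == "self"
  by_ped <- split(seq_len(nrow(pedigrees)), pedigrees$ped_id)
  for (pid in names(by_ped)) {
    rows <- by_ped[[pid]]
    pro <- rows[is_proband[rows]]
    if (length(pro) != 1) {
      stop("pedigree ", pid, " must contain exactly one proband ",
           "(relationship 'self'); found ", length(pro))
    }
    if (is.na(pedigrees$genotype[pro])) {
      stop("missing proband genotype in pedigree ", pid)
    }
    rel_geno <- rows[!is_proband[rows] & !is.na(pedigrees$genotype[rows])]
    if (length(rel_geno)) {
      stop("pedigree ", pid, " carries genotypes on non-proband members; ",
           "only the proband is genotyped in this test (genotyped relatives ",
           "are out of scope)")
    }
  }
  if (!all(pedigrees$genotype[is_proband] %in% 0:2)) {
    stop("proband genotypes must be 0, 1 or 2")
  }
  pedigrees
}

# Per-pedigree weighted, incidence-adjusted phenotype sum
# S_i = sum_j (D_ij - Lambda0(t_ij)) * 2 phi_ij0, plus the proband genotype.
pedigree_summaries <- function(pedigrees, incidence) {
  ped <- validate_pedigrees(pedigrees)
  lam <- incidence(ped$age)
  term <- (ped$status - lam) * ped$w
  S <- tapply(term, ped$ped_id, sum)
  pro <- ped$relationship == "self"
  g <- ped$genotype[pro][match(names(S), ped$ped_id[pro])]
  list(S = as.numeric(S), g = as.numeric(g), ids = names(S))
}

#' Kinship-weighted pedigree score statistic
#'
#' Score statistic for association between a variant and disease using the
#' full pedigree phenotype: each family contributes its weighted sum of
#' incidence-adjusted disease indicators times the proband's centred
#' genotype,
#' \deqn{U = \sum_i \sum_j (D_{ij} - \Lambda_0(t_{ij})) \, 2\phi_{ij0}
#'   \, (g_{i0} - 2p).}
#' With singleton pedigrees and `Lambda0 = 0` this is the ordinary
#' case-control score numerator; with unascertained first-degree relatives of
#' a rare disease it reduces to regressing genotype on `d + f/2`, the
#' composite phenotype used by the burden models.
#'
#' @param pedigrees Long-format data frame, one row per family member:
#'   `ped_id`, `relationship` (`"self"` marks the proband), `status` (0/1),
#'   `age`, `genotype` (0/1/2 on the proband row only).
#' @param incidence An [incidence_model()] or any function mapping age to
#'   cumulative hazard.
#' @param p Population allele frequency in (0, 1).
#' @return `score_statistic()`: the scalar U. `score_variance()`: the null
#'   variance `V = 2 p (1 - p) sum_i (S_i - mean(S))^2` where `S_i` is the
#'   per-pedigree weighted phenotype sum (population 1/N variance divisor
#'   times N). `score_test()`: list with `U`, `V`, `Z = U / sqrt(V)` and the
#'   two-sided normal p-value.
#' @export
score_statistic <- function(pedigrees, incidence, p) {
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  ps <- pedigree_summaries(pedigrees, incidence)
  sum(ps$S * (ps$g - 2 * p))
}

#' @rdname score_statistic
#' @export
score_variance <- function(pedigrees, incidence, p) {
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  ps <- pedigree_summaries(pedigrees, incidence)
  2 * p * (1 - p) * sum((ps$S - mean(ps$S))^2)
}

#' @rdname score_statistic
#' @export
score_test <- function(pedigrees, incidence, p) {
  U <- score_statistic(pedigrees, incidence, p)
  V <- score_variance(pedigrees, incidence, p)
  if (V <= 0) {
    stop("degenerate null variance (V = ", V,
         "): the weighted phenotype is constant across pedigrees")
  }
  Z <- U / sqrt(V)
  structure(list(U = U, V = V, Z = Z, p = 2 * stats::pnorm(-abs(Z))),
            class = "fh_score_result")
}

#' @export
print.fh_score_result <- function(x, ...) {
  cat(sprintf("pedigree score test: U = %.4g, V = %.4g, Z = %.3f, p = %.3g\n",
              x$U, x$V, x$Z, x$p))
  invisible(x)
}

#' Rare-disease composite phenotype d + f/2
#'
#' The reduction of the pedigree score test when only a binary first-degree
#' family-history summary is available and the disease is rare enough that
#' the expected-incidence terms are negligible: the proband's disease status
#' plus half the number of affected first-degree relatives. In the analyses
#' the package targets, multiple affected relatives are not distinguished, so
#' by default `f` is capped at 1.
#'
#' @param d Proband disease status (0/1).
#' @param n_affected_fdr Number of affected first-degree relatives.
#' @param cap If `TRUE` (default), `f = min(n_affected_fdr, 1)`.
#' @return The composite phenotype `u = d + f / 2`.
#' @export
reduced_phenotype <- function(d, n_affected_fdr, cap = TRUE) {
  if (!all(d %in% c(0, 1))) stop("d must be 0/1")
  if (any(n_affected_fdr < 0)) stop("n_affected_fdr must be >= 0")
  f <- if (cap) pmin(n_affected_fdr, 1) else n_affected_fdr
  d + 0.5 * f
}
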