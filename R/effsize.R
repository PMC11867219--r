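#' Case/control by family-history margin counts
#'
#' The four phenotype margins that drive the effective-sample-size algebra:
#' controls and cases split by positive first-degree family history. Counts
#' may be real-valued, so expected-count designs (cohort proportions times a
#' target size) can be analysed directly.
#'
#' @param N00 Controls without family history.
#' @param N01 Controls with family history.
#' @param N10 Cases without family history.
#' @param N11 Cases with family history.
#' @return A `four_cell_counts` object with derived margins `N0`, `N1`, `N`.
#' @export
four_cell_counts <- function(N00, N01, N10, N11) {
  v <- c(N00 = N00, N01 = N01, N10 = N10, N11 = N11)
  if (any(!is.finite(v)) || any(v < 0)) stop("counts must be finite and >= 0")
  structure(list(N00 = N00, N01 = N01, N10 = N10, N11 = N11,
                 N0 = N00 + N01, N1 = N10 + N11,
                 N = N00 + N01 + N10 + N11),
            class = "four_cell_counts")
}

#' Effective sample sizes of the three analysis strategies
#'
#' The effective sample size of a design is the size of a balanced
#' case-control study yielding the same expected score-test Z, so that for
#' every strategy `E(Z | beta) = beta sqrt(2 p (1 - p)) sqrt(Neff / 2)`.
#'
#' * `neff_case_control()`: the standard analysis ignoring family history,
#'   `Neff1 = 2 N0 N1 / (N0 + N1)` (harmonic-mean formula).
#' * `neff_weighted_fh()`: the weighted composite phenotype `u = d + f/2`,
#'   `Neff2 = (N00 N01 + N01 N10 + N10 N11 + 4 (N00 N10 + N01 N11)
#'   + 9 N00 N11) / (2 N)`. With no family-history subjects this reduces to
#'   `2 N00 N10 / N = Neff1`.
#' * `neff_proxy()`: the proxy-case strategy that pools family-history
#'   controls with cases, `y = max(d, f)`:
#'   `Neff3 = N00 (N01 + 2 N10 + 3 N11)^2 / (2 N (N01 + N10 + N11))`, which
#'   likewise reduces to `Neff1` when `N01 = N11 = 0`.
#'
#' @param counts A [four_cell_counts()] object.
#' @return A single nonnegative number (0 when a required margin is empty).
#' @export
neff_case_control <- function(counts) {
  stopifnot(inherits(counts, "four_cell_counts"))
  if (counts$N0 == 0 || counts$N1 == 0) return(0)
  2 * counts$N0 * counts$N1 / counts$N
}

#' @rdname neff_case_control
#' @export
neff_weighted_fh <- function(counts) {
  stopifnot(inherits(counts, "four_cell_counts"))
  if (counts$N == 0) return(0)
  with(counts,
       (N00 * N01 + N01 * N10 + N10 * N11 +
        4 * (N00 * N10 + N01 * N11) + 9 * N00 * N11) / (2 * N))
}

#' @rdname neff_case_control
#' @export
neff_proxy <- function(counts) {
  stopifnot(inherits(counts, "four_cell_counts"))
  denom_margin <- counts$N01 + counts$N10 + counts$N11
  if (counts$N == 0 || counts$N00 == 0 || denom_margin == 0) return(0)
  counts$N00 * (counts$N01 + 2 * counts$N10 + 3 * counts$N11)^2 /
    (2 * counts$N * denom_margin)
}

#' Expected score-test Z under a per-allele effect
#'
#' Closed-form expectation of the score-test Z-statistic for a variant with
#' population allele frequency `p` and per-allele log rate ratio `beta`,
#' under each analysis strategy:
#' `E(Z | beta) = beta sqrt(2 p (1 - p)) sqrt(Neff / 2)` with the
#' strategy-specific effective sample size. Accurate for small `beta` (the
#' local alternative under which the score test is optimal).
#'
#' @param p Allele frequency, strictly inside (0, 1).
#' @param beta Per-allele log rate ratio.
#' @param counts A [four_cell_counts()] object.
#' @param method `"cc"` (case-control), `"weighted"` (d + f/2) or `"proxy"`
#'   (max(d, f)).
#' @return Expected Z (signed as `beta`).
#' @export
expected_z <- function(p, beta, counts, method = c("cc", "weighted", "proxy")) {
  method <- match.arg(method)
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  neff <- switch(method,
                 cc = neff_case_control(counts),
                 weighted = neff_weighted_fh(counts),
                 proxy = neff_proxy(counts))
  beta * sqrt(2 * p * (1 - p)) * sqrt(neff / 2)
}

#' Expected margin counts from cohort proportions
#'
#' Converts a cohort composition (see [cancer_proportions()]) into the
#' expected four-cell margins for a cohort of size `n`, collapsing sex.
#' Counts are returned real-valued.
#'
#' @param proportions A `cohort_proportions` object or a list with fields
#'   `p_female`, `p_case_female`, `p_case_male`, `p_fh_female_control`,
#'   `p_fh_female_case`, `p_fh_male_control`, `p_fh_male_case`.
#' @param n Cohort size.
#' @return A [four_cell_counts()] object.
#' @export
counts_from_proportions <- function(proportions, n) {
  pr <- proportions
  pf <- pr$p_female
  cell <- function(sex_p, case_p, fh_p, fh = 1) {
    n * sex_p * case_p * if (fh == 1) fh_p else (1 - fh_p)
  }
  N10 <- cell(pf, pr$p_case_female, pr$p_fh_female_case, 0) +
         cell(1 - pf, pr$p_case_male, pr$p_fh_male_case, 0)
  N11 <- cell(pf, pr$p_case_female, pr$p_fh_female_case, 1) +
         cell(1 - pf, pr$p_case_male, pr$p_fh_male_case, 1)
  N00 <- cell(pf, 1 - pr$p_case_female, pr$p_fh_female_control, 0) +
         cell(1 - pf, 1 - pr$p_case_male, pr$p_fh_male_control, 0)
  N01 <- cell(pf, 1 - pr$p_case_female, pr$p_fh_female_control, 1) +
         cell(1 - pf, 1 - pr$p_case_male, pr$p_fh_male_control, 1)
  four_cell_counts(N00, N01, N10, N11)
}
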