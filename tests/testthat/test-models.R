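test_that("null model recovers the carrier frequency with no sex effect", {
  cells <- cells_from_counts(data.frame(
    sex = c(0, 1), case = 0, fh = 0,
    n_carrier = c(30, 60), n_total = c(300, 600)))
  f <- fit_null(cells)
  expect_equal(unname(f$coefficients["beta3"]), 0, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["alpha"]), qlogis(0.1), tolerance = 1e-8)
})

test_that("reported log-likelihood equals the direct Bernoulli evaluation", {
  cells <- random_cells(101)
  for (m in c("null", "m1", "m2")) {
    f <- switch(m, null = fit_null(cells), m1 = fit_model1(cells),
                m2 = fit_model2(cells))
    X <- oracle_design(cells, m)
    expect_equal(f$loglik,
                 bernoulli_ll(unname(f$coefficients), X, cells$n_carrier,
                              cells$n_total),
                 tolerance = 1e-8)
  }
  f3 <- fit_model3(cells, k = 0.5)
  expect_equal(f3$loglik,
               bernoulli_ll(unname(f3$coefficients),
                            oracle_design(cells, "m3", 0.5),
                            cells$n_carrier, cells$n_total),
               tolerance = 1e-8)
})

test_that("grouped-cell fits equal expanded per-record fits", {
  cells <- random_cells(202)
  recs <- expand_cells(cells)
  for (pair in list(list(fit_null(cells), fit_null(recs)),
                    list(fit_model1(cells), fit_model1(recs)),
                    list(fit_model2(cells), fit_model2(recs)),
                    list(fit_model3(cells, 0.5), fit_model3(recs, 0.5)))) {
    expect_equal(pair[[1]]$coefficients, pair[[2]]$coefficients,
                 tolerance = 1e-8)
    expect_equal(pair[[1]]$loglik, pair[[2]]$loglik, tolerance = 1e-8)
  }
})

test_that("model 1 on a covariate-free 2x2 gives the cross-product ratio", {
  a <- 23; b <- 411; c <- 71; d <- 2903  # carriers/non by case/control
  cells <- cells_from_counts(data.frame(
    sex = c(0, 0, 1, 1), case = c(1, 0, 1, 0), fh = 0,
    n_carrier = c(a, c, a, c), n_total = c(a + b, c + d, a + b, c + d)))
  # balanced duplication across sex keeps beta3 = 0 and the 2x2 structure
  f <- fit_model1(cells)
  expect_equal(exp(unname(f$coefficients["beta1"])), (a * d) / (b * c),
               tolerance = 1e-10)
})

test_that("independence of case and carrier gives beta1 ~ 0 and null LRT", {
  set.seed(33)
  grid <- expand.grid(sex = 0:1, case = 0:1, fh = 0:1)
  n_total <- rep(5000, 8)
  p <- plogis(-2 + 0.3 * grid$sex)  # no case or fh effect
  cells <- cells_from_counts(data.frame(
    grid, n_carrier = round(n_total * p), n_total = n_total))
  f <- fit_model1(cells)
  nl <- fit_null(cells)
  expect_lt(abs(f$coefficients["beta1"]), 1e-6)
  expect_lt(lrt(f, nl)$statistic, 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  cells <- random_cells(5)
  all_car <- cells; all_car$n_carrier <- all_car$n_total
  expect_error(fit_model1(all_car), "non-carrier")
  no_car <- cells; no_car$n_carrier <- 0
  expect_error(fit_model1(no_car), "carrier")
  no_fh <- cells
  no_fh$n_total[no_fh$fh == 1] <- 0
  no_fh$n_carrier[no_fh$fh == 1] <- 0
  expect_error(fit_model2(no_fh), "beta2")
})

test_that("model 3 with k = 0 is model 1 and k = 1 merges case with FH", {
  cells <- random_cells(77)
  f1 <- fit_model1(cells)
  f30 <- fit_model3(cells, k = 0)
  expect_equal(f30$coefficients[c("alpha", "beta1", "beta3")],
               f1$coefficients[c("alpha", "beta1", "beta3")],
               tolerance = 1e-10)
  expect_equal(f30$loglik, f1$loglik, tolerance = 1e-10)

  # k = 1 where FH and case never co-occur: composite equals max(d, f)
  cells2 <- random_cells(78)
  cells2$n_total[cells2$case == 1 & cells2$fh == 1] <- 0
  cells2$n_carrier[cells2$case == 1 & cells2$fh == 1] <- 0
  f31 <- fit_model3(cells2, k = 1)
  merged <- cells2
  merged$case <- pmax(cells2$case, cells2$fh)
  merged$fh <- 0
  f1m <- fit_model1(cells_from_counts(merged))
  expect_equal(unname(f31$coefficients["beta1"]),
               unname(f1m$coefficients["beta1"]), tolerance = 1e-8)
})

test_that("grouped ML fits match the brute-force numeric maximiser", {
  for (seed in 301:305) {
    cells <- random_cells(seed)
    for (m in c("m1", "m2", "m3")) {
      k <- if (m == "m3") 0.5 else NULL
      f <- switch(m, m1 = fit_model1(cells), m2 = fit_model2(cells),
                  m3 = fit_model3(cells, 0.5))
      X <- oracle_design(cells, m, k)
      bf <- bruteforce_ml(X, cells$n_carrier, cells$n_total)
      expect_equal(unname(f$coefficients), bf, tolerance = 1e-4,
                   info = paste("seed", seed, "model", m))
    }
  }
})

test_that("model 3 at its ML never beats model 2 at its ML", {
  for (seed in 401:410) {
    cells <- random_cells(seed)
    f2 <- fit_model2(cells)
    for (k in c(0, 0.3, 0.5, 0.8, 1)) {
      expect_lte(fit_model3(cells, k)$loglik, f2$loglik + 1e-8)
    }
  }
})

test_that("model 2 reports k_T = beta2 / beta1", {
  cells <- random_cells(55)
  f2 <- fit_model2(cells)
  expect_equal(f2$k_T,
               unname(f2$coefficients["beta2"] / f2$coefficients["beta1"]))
})

test_that("LRT degrees of freedom and statistic follow the nesting", {
  cells <- random_cells(60)
  nl <- fit_null(cells)
  expect_equal(lrt(fit_model1(cells), nl)$df, 1)
  expect_equal(lrt(fit_model2(cells), nl)$df, 2)
  expect_equal(lrt(fit_model3(cells, 0.5), nl)$df, 1)
  # statistic equals 2 * (l1 - l0) from independently evaluated likelihoods
  f2 <- fit_model2(cells)
  l1 <- bernoulli_ll(unname(f2$coefficients), oracle_design(cells, "m2"),
                     cells$n_carrier, cells$n_total)
  l0 <- bernoulli_ll(unname(nl$coefficients), oracle_design(cells, "null"),
                     cells$n_carrier, cells$n_total)
  expect_equal(lrt(f2, nl)$statistic, 2 * (l1 - l0), tolerance = 1e-8)
  # identical fits give statistic 0 and p = 1 (via two null fits)
  self <- lrt(fit_model1(cells), nl)
  expect_gte(self$statistic, 0)
  expect_error(lrt(nl, nl), "not nested")
  other <- random_cells(61)
  expect_error(lrt(fit_model1(other), nl), "different data")
})

test_that("LRT is invariant to centering and scaling of extra covariates", {
  set.seed(88)
  recs <- expand_cells(random_cells(62))
  recs$age <- rnorm(nrow(recs), 55, 8)
  f <- fit_model1(recs, covariates = "age")
  nl <- fit_null(recs, covariates = "age")
  s1 <- lrt(f, nl)$statistic
  recs$age <- (recs$age - 55) / 10
  s2 <- lrt(fit_model1(recs, covariates = "age"),
            fit_null(recs, covariates = "age"))$statistic
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("Wald test matches its definition and flags degeneracy", {
  cells <- random_cells(63)
  f <- fit_model1(cells)
  w <- wald_test(f, "beta1")
  se <- sqrt(f$vcov["beta1", "beta1"])
  expect_equal(w$z, unname(f$coefficients["beta1"]) / se)
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_equal(w$ci95, unname(f$coefficients["beta1"]) + c(-1.96, 1.96) * se)
  expect_error(wald_test(f, "nope"), "no coefficient")

  # on large simulated data Wald and LRT p agree within an order of magnitude
  set.seed(64)
  n <- rep(30000, 8)
  grid <- expand.grid(sex = 0:1, case = 0:1, fh = 0:1)
  p <- plogis(-4 + 0.3 * grid$case + 0.1 * grid$sex)
  big <- cells_from_counts(data.frame(grid, n_carrier = rbinom(8, n, p),
                                      n_total = n))
  fb <- fit_model1(big)
  pw <- wald_test(fb, "beta1")$p
  pl <- lrt(fb, fit_null(big))$p
  expect_lt(abs(log10(pw) - log10(pl)), 1)
})

test_that("optimal_k has the right limit, values, and monotonicity", {
  expect_equal(optimal_k(1e-9), 0.5)
  expect_equal(optimal_k(log(2)), log(1.5) / log(2), tolerance = 1e-12)
  expect_equal(optimal_k(log(5)), log(3) / log(5), tolerance = 1e-12)
  # continuity at 0 and strict increase for positive effects
  expect_equal(optimal_k(1e-6), 0.5, tolerance = 1e-6)
  grid <- seq(0.01, log(5), length.out = 50)
  expect_true(all(diff(optimal_k(grid)) > 0))
  expect_true(all(optimal_k(grid) > 0.5))
})

test_that("gene scan returns results, skips, and strict thresholds", {
  set.seed(91)
  n <- 4000
  phen <- data.frame(sample_id = paste0("s", 1:n),
                     case = rbinom(n, 1, 0.1), fh = rbinom(n, 1, 0.1),
                     sex = rbinom(n, 1, 0.5))
  # gene A: null; gene B: strong enrichment in cases; gene C: zero carriers
  gA <- setNames(rbinom(n, 1, 0.02), phen$sample_id)
  pB <- plogis(-4 + log(6) * (phen$case + 0.5 * phen$fh))
  gB <- setNames(rbinom(n, 1, pB), phen$sample_id)
  gC <- setNames(rep(0, n), phen$sample_id)
  scan <- run_gene_scan(list(A = gA, B = gB, C = gC), phen,
                        model = "m3", k = 0.5)
  expect_equal(nrow(scan$results), 2)
  expect_equal(scan$skipped, "C")
  rB <- scan$results[scan$results$gene == "B", ]
  expect_gt(rB$OR, 1)
  expect_true(rB$CI_low < rB$OR & rB$OR < rB$CI_high)
  expect_identical(rB$sig_followup, rB$p_lrt < 1e-3)
  # empty input succeeds with an empty table
  empty <- run_gene_scan(list(), phen)
  expect_equal(nrow(empty$results), 0)
  # shuffled carrier order changes nothing (id-joined)
  perm <- sample(n)
  scan2 <- run_gene_scan(list(B = gB[perm]), phen, model = "m3", k = 0.5)
  expect_equal(scan2$results$OR, rB$OR)
})
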