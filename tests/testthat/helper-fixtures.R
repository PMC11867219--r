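# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code under fixed seeds; no stored data.

# Random non-degenerate 8-cell cohort table (moderate carrier frequencies so
# every model is comfortably estimable).
random_cells <- function(seed) {
  set.seed(seed)
  grid <- expand.grid(sex = 0:1, case = 0:1, fh = 0:1)
  n_total <- sample(50:500, 8, replace = TRUE)
  p <- runif(8, 0.05, 0.5)
  cells_from_counts(data.frame(grid, n_carrier = rbinom(8, n_total, p),
                               n_total = n_total))
}

# Direct Bernoulli log-likelihood of a logistic model on grouped counts:
# the evaluation oracle, independent of glm.fit.
bernoulli_ll <- function(beta, X, n_carrier, n_total) {
  mu <- plogis(drop(X %*% beta))
  sum(n_carrier * log(mu) + (n_total - n_carrier) * log(1 - mu))
}

# Brute-force ML oracle: numeric maximisation of bernoulli_ll from a cold
# start, no IRLS involved.
bruteforce_ml <- function(X, n_carrier, n_total) {
  optim(rep(0, ncol(X)), function(b) -bernoulli_ll(b, X, n_carrier, n_total),
        method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))$par
}

# Design matrices mirroring the model definitions, built independently of the
# package internals.
oracle_design <- function(cells, model, k = NULL) {
  switch(model,
    "null" = cbind(1, cells$sex),
    "m1"   = cbind(1, cells$case, cells$sex),
    "m2"   = cbind(1, cells$case, cells$fh, cells$sex),
    "m3"   = cbind(1, cells$case + k * cells$fh, cells$sex))
}

# Small genotype matrix fixture: 6 samples x 5 variants over two genes.
small_genotypes <- function() {
  calls <- rbind(
    s1 = c(0, 1, 0, 0, 0),
    s2 = c(0, 0, 0, 0, 2),
    s3 = c(0, 0, 1, 0, 0),
    s4 = c(0, 0, 0, 0, 0),
    s5 = c(2, 0, 0, 1, 0),
    s6 = c(0, 0, 0, NA, 0))
  variants <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    gene = c("GENE1", "GENE1", "GENE1", "GENE2", "GENE2"),
    chrom = "1", pos = c(100, 200, 300, 5000, 5100),
    af = c(0.0005, 0.0008, 0.002, 0.0002, 0.0009))
  genotype_matrix(calls, variants)
}

# Three hand-built pedigrees (proband + two relatives each) used for the
# term-by-term score-test oracle.
hand_pedigrees <- function() {
  data.frame(
    ped_id = rep(c("p1", "p2", "p3"), each = 3),
    member_id = rep(0:2, 3),
    relationship = rep(c("self", "first_degree", "second_degree"), 3),
    status = c(1, 1, 0,  0, 1, 1,  0, 0, 0),
    age = c(50, 70, 60,  40, 80, 75,  55, 65, 85),
    genotype = c(1, NA, NA,  2, NA, NA,  0, NA, NA))
}

# Simulated singleton cohort for calibration checks: Hardy-Weinberg
# genotypes at allele frequency q, disease with prevalence pi and a
# per-allele odds ratio.
singleton_pedigrees <- function(n, q, pi, or = 1, seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 2, q)
  pd <- plogis(qlogis(pi) + log(or) * g)
  d <- rbinom(n, 1, pd)
  data.frame(ped_id = paste0("s", seq_len(n)), member_id = 0,
             relationship = "self", status = d, age = 50, genotype = g)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
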