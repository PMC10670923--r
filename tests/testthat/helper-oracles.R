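# Shared fixtures and independent oracles used across the suite.

study_ages <- c(1, 2, 3, 5, 6, 7, 9, 10, 11)

# Random admissible parameter draws, kept away from near-degenerate corners
# so finite-difference oracles stay well-conditioned.
random_params <- function(model) {
  switch(model,
    richard = c(a = runif(1, 5, 40), b = runif(1, 0.08, 0.6),
                c = runif(1, 0.4, 3)),
    gompertz = c(a = runif(1, 5, 40), b = runif(1, 1.2, 6),
                 c = runif(1, 0.4, 0.9)),
    logistic = c(Asym = runif(1, 5, 40), xmid = runif(1, 2, 8),
                 scal = runif(1, 0.8, 3)),
    asymptotic = {
      a <- runif(1, 5, 40)
      c(a = a, b = runif(1, 0, 0.3 * a), c = runif(1, -2, 0.3))
    }
  )
}

# Central finite differences, independent of the analytic derivative code.
fd_d1 <- function(model, params, t, h = 1e-5) {
  (growth_value(model, params, t + h) - growth_value(model, params, t - h)) / (2 * h)
}
# five-point stencil: O(h^4) truncation keeps the oracle's own error well
# below the 1e-4 comparison tolerance
fd_d2 <- function(model, params, t, h = 1e-3) {
  f <- function(tt) growth_value(model, params, tt)
  (-f(t + 2 * h) + 16 * f(t + h) - 30 * f(t) + 16 * f(t - h) - f(t - 2 * h)) /
    (12 * h^2)
}
fd_curvature <- function(model, params, t) {
  abs(fd_d2(model, params, t)) / (1 + fd_d1(model, params, t)^2)^1.5
}

rel_err <- function(x, ref, floor = 1e-8) abs(x - ref) / pmax(abs(ref), floor)

# Textbook one-way ANOVA from sums of squares (independent of lm()).
hand_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Noiseless series from a model on the irregular study schedule.
exact_series <- function(model, params, ages = study_ages) {
  tibble::tibble(age = ages, value = growth_value(model, params, ages))
}

# Two-class genotype matrix with a fixed split (labels AA / GG).
split_genotypes <- function(n1 = 12, n2 = 12) {
  tibble::tibble(
    clone = sprintf("clone%02d", seq_len(n1 + n2)),
    SNP1 = c(rep("A/A", n1), rep("G/G", n2))
  )
}

# Null / effect phenotypes for a two-class design: class 2's asymptote is
# scaled by (1 + effect); per-clone iid Gaussian noise on clone means.
two_class_pheno <- function(geno, effect = 0, noise = 0.02, seed = 1,
                            base = c(a = 28, b = 0.18, c = 1.6),
                            ages = study_ages) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(geno)), function(i) {
      p <- base
      if (geno$SNP1[i] == "G/G") p["a"] <- p["a"] * (1 + effect)
      tibble::tibble(
        clone = geno$clone[i], trait = "height_m", age = ages,
        value = growth_value("richard", p, ages) + rnorm(length(ages), 0, noise * base["a"])
      )
    })
  })
}
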