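test_that("self-start heuristics land near truth on noiseless series", {
  d <- exact_series("logistic", c(Asym = 28, xmid = 6, scal = 2))
  g <- initial_growth_params(d, "logistic")
  # amplitude rule is 1.05 * max(value); with the 11-year schedule that is
  # 1.05 * y(11) = 27.17, just under the true asymptote
  expect_equal(unname(g["Asym"]), 1.05 * max(d$value))
  expect_gt(g["Asym"], 26); expect_lt(g["Asym"], 29.4)
  expect_lt(abs(g["xmid"] - 6), 1)
  # amplitude guess always exceeds the largest observation
  for (model in growth_models()$model) {
    p <- random_params(model)
    s <- exact_series(model, p)
    gi <- initial_growth_params(s, model)
    amp <- if (model == "logistic") gi["Asym"] else gi["a"]
    expect_gt(amp, max(s$value))
  }
})

test_that("constant series cannot be initialized", {
  d <- tibble::tibble(age = c(1, 2, 3, 5), value = rep(7, 4))
  expect_error(initial_growth_params(d, "richard"), "constant")
})

test_that("noiseless self-generated data is recovered for every law", {
  true <- list(
    richard = c(a = 30, b = 0.2, c = 2),
    gompertz = c(a = 25, b = 3, c = 0.7),
    logistic = c(Asym = 28, xmid = 6, scal = 2),
    asymptotic = c(a = 30, b = 3, c = -1.2)
  )
  for (model in names(true)) {
    fit <- fit_growth(exact_series(model, true[[model]]), model, seed = 1)
    expect_true(fit$converged)
    expect_lt(max(rel_err(fit$params, true[[model]])), 1e-4)
    expect_lt(fit$sse, 1e-10)
  }
})

test_that("refitting data generated from a fitted model is a fixed point", {
  d <- two_class_pheno(split_genotypes(1, 0), noise = 0.02, seed = 3)
  f1 <- fit_growth(d[c("age", "value")], "richard", seed = 1)
  d2 <- exact_series("richard", f1$params)
  f2 <- fit_growth(d2, "richard", seed = 1)
  expect_lt(max(rel_err(f2$params, f1$params)), 1e-5)
})

test_that("noisy data yields positive SSE and R2 below one", {
  d <- two_class_pheno(split_genotypes(1, 0), noise = 0.5 / 28, seed = 5)
  f <- fit_growth(d[c("age", "value")], "richard", seed = 1)
  expect_gt(f$sse, 0)
  expect_lt(fit_metrics(f)$r2, 1)
})

test_that("returned SSE never exceeds the SSE at the initial guess", {
  set.seed(21)
  for (rep in 1:10) {
    p <- random_params("richard")
    d <- exact_series("richard", p)
    d$value <- d$value * exp(rnorm(nrow(d), 0, 0.05))
    init <- initial_growth_params(d, "richard")
    sse0 <- sum((d$value - growth_value("richard", init, d$age))^2)
    f <- fit_growth(d, "richard", seed = rep)
    expect_lte(f$sse, sse0 + 1e-12)
  }
})

test_that("log-likelihood follows the concentrated Gaussian identity", {
  d <- two_class_pheno(split_genotypes(1, 0), noise = 0.02, seed = 8)
  f <- fit_growth(d[c("age", "value")], "richard", seed = 1)
  expect_equal(f$loglik, -(f$n / 2) * (log(2 * pi * f$sse / f$n) + 1),
               tolerance = 1e-12)
})

test_that("metric formulas reproduce the hand-computed AIC example", {
  # n = 9, sse = 0.9, k = 4: sigma2 = 0.1, aic = 9*log(2*pi*0.1) + 9 + 8
  p <- c(a = 30, b = 0.2, c = 2)
  d <- exact_series("richard", p)
  fake <- structure(
    list(model = "richard", params = p, sse = 0.9, n = 9L,
         sigma2 = 0.1, loglik = -(9 / 2) * (log(2 * pi * 0.1) + 1),
         converged = TRUE, n_restarts_used = 0L, data = d),
    class = "growth_fit"
  )
  m <- fit_metrics(fake)
  expect_equal(m$aic, 9 * log(2 * pi * 0.1) + 9 + 8, tolerance = 1e-12)
  expect_lt(abs(m$aic - 12.817), 1e-3) # exact value 12.8176
  expect_equal(m$bic, 9 * log(2 * pi * 0.1) + 9 + 4 * log(9), tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(0.1), tolerance = 1e-12)
})

test_that("a perfect fit gives r2 = 1 and zero rmse/mae", {
  f <- fit_growth(exact_series("richard", c(a = 30, b = 0.2, c = 2)), "richard")
  m <- fit_metrics(f)
  expect_equal(m$r2, 1, tolerance = 1e-9)
  expect_lt(m$rmse, 1e-6); expect_lt(m$mae, 1e-6)
})

test_that("zero-variance series make R2 undefined", {
  p <- c(a = 30, b = 0.2, c = 2)
  fake <- structure(
    list(model = "richard", params = p, sse = 0, n = 4L, sigma2 = 1e-12,
         loglik = 0, converged = TRUE, n_restarts_used = 0L,
         data = tibble::tibble(age = c(1, 2, 3, 5), value = rep(5, 4))),
    class = "growth_fit"
  )
  expect_error(fit_metrics(fake), "undefined")
})

test_that("amplitude is recovered within 10% on average at 2% noise", {
  true <- list(
    richard = c(a = 30, b = 0.2, c = 2),
    gompertz = c(a = 25, b = 3, c = 0.7),
    logistic = c(Asym = 28, xmid = 6, scal = 2),
    asymptotic = c(a = 30, b = 3, c = -1.2)
  )
  for (model in names(true)) {
    amp_true <- growth_asymptote(model, true[[model]])
    errs <- vapply(1:5, function(r) {
      d <- exact_series(model, true[[model]])
      d$value <- withr::with_seed(r, d$value + rnorm(nrow(d), 0, 0.02 * amp_true))
      f <- fit_growth(d, model, seed = r)
      rel_err(growth_asymptote(model, f$params), amp_true)
    }, numeric(1))
    # the Chapman-Richards plateau is only weakly identified from data
    # reaching ~80% of the asymptote, so recovery is judged on average
    expect_lt(mean(errs), 0.10)
  }
})

test_that("fit_growth_curves maps over clones, traits and models", {
  suite <- make_fixture_suite(seed = 4)
  fits <- fit_growth_curves(suite$tiny$phenotypes, c("richard", "logistic"), seed = 1)
  expect_equal(nrow(fits), 6 * 2 * 2)
  expect_true(all(c("clone", "trait", "model", "aic", "r2") %in% names(fits)))
  expect_true(all(fits$converged))
  expect_s3_class(fits$fit[[1]], "growth_fit")
  # broom-style accessors on a single fit
  tf <- tidy(fits$fit[[1]])
  expect_equal(tf$term, c("a", "b", "c"))
  expect_named(glance(fits$fit[[1]]),
               c("model", "n", "sse", "loglik", "converged", "n_restarts_used",
                 "aic", "bic", "r2", "rmse", "mae"))
  au <- augment(fits$fit[[1]])
  expect_equal(au$.fitted + au$.resid, au$value)
})
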