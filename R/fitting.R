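#' Control settings for growth-curve fitting
#'
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param ftol Relative tolerance on the SSE change declaring convergence.
#' @param max_restarts Jittered restarts attempted after a failed start.
#' @param jitter_sd Standard deviation of the multiplicative lognormal
#'   jitter applied to the starting values on restart.
#' @param sigma2_floor Floor applied to the residual-variance estimate so
#'   that log-likelihoods stay finite on (numerically) perfect fits.
#' @return A list of class `growth_control`.
#' @export
growth_control <- function(max_iter = 500L, ftol = 1e-10, max_restarts = 10L,
                           jitter_sd = 0.3, sigma2_floor = 1e-12) {
  structure(
    list(max_iter = as.integer(max_iter), ftol = ftol,
         max_restarts = as.integer(max_restarts), jitter_sd = jitter_sd,
         sigma2_floor = sigma2_floor),
    class = "growth_control"
  )
}

# Bounds are enforced by reparameterization so the unconstrained
# Levenberg-Marquardt solver can be used directly:
#   positive parameters      -> log
#   gompertz c in (0, 1)     -> logit
#   logistic xmid, asymptotic c -> identity
# asymptotic b in [0, a)     -> a * logit^-1
to_unconstrained <- function(model, p) {
  switch(model,
    richard    = log(p),
    gompertz   = c(log(p[["a"]]), log(p[["b"]]), stats::qlogis(p[["c"]])),
    logistic   = c(log(p[["Asym"]]), p[["xmid"]], log(p[["scal"]])),
    asymptotic = c(log(p[["a"]]),
                   stats::qlogis(min(max(p[["b"]] / p[["a"]], 1e-8), 1 - 1e-8)),
                   p[["c"]])
  )
}

from_unconstrained <- function(model, theta) {
  p <- switch(model,
    richard    = exp(theta),
    gompertz   = c(exp(theta[1]), exp(theta[2]), stats::plogis(theta[3])),
    logistic   = c(exp(theta[1]), theta[2], exp(theta[3])),
    asymptotic = c(exp(theta[1]), exp(theta[1]) * stats::plogis(theta[2]), theta[3])
  )
  names(p) <- growth_param_names(model)
  p
}

#' Heuristic starting values for a growth-curve fit
#'
#' Self-start rules: the amplitude is guessed as `1.05 * max(value)`; the
#' logistic midpoint as the age whose value is closest to half the
#' amplitude and `scal` as a quarter of the age range; the Gompertz rate
#' parameters from a two-point fit of the log-log linearization
#' `log(log(a/y)) = log(b) + t*log(c)`; the Chapman-Richards rate from the
#' one-point inversion `b = -log(1 - (y/a)^(1/c))/t` at the series
#' midpoint with shape seeded at `c = 1.5`; the asymptotic-regression
#' offset from the first observation and its log-rate from a crude decay
#' estimate.
#'
#' @param data A data frame with numeric columns `age` and `value` for one
#'   trait series (ages strictly increasing, at least 4 points).
#' @param model Growth law identifier.
#' @return Named parameter vector satisfying the law's constraints.
#' @export
initial_growth_params <- function(data, model) {
  model <- match_growth_model(model)
  series <- validate_series(data)
  t <- series$age; y <- series$value
  if (stats::sd(y) == 0) {
    rlang::abort("Series is constant: a growth curve cannot be initialized.")
  }
  amp <- 1.05 * max(y)
  p <- switch(model,
    logistic = {
      xmid <- t[which.min(abs(y - amp / 2))]
      c(Asym = amp, xmid = xmid, scal = diff(range(t)) / 4)
    },
    gompertz = {
      # two-point fit of log(log(a/y)) linear in t; clamp into (0, 1)
      i <- c(1L, length(y))
      z <- log(pmax(log(amp / pmin(y[i], amp * (1 - 1e-6))), 1e-8))
      slope <- (z[2] - z[1]) / (t[length(t)] - t[1])
      cc <- min(max(exp(slope), 0.05), 0.95)
      b <- exp(z[1] - t[1] * log(cc))
      c(a = amp, b = max(b, 1e-3), c = cc)
    },
    richard = {
      cc <- 1.5
      mid <- ceiling(length(y) / 2)
      frac <- min(max((y[mid] / amp)^(1 / cc), 1e-6), 1 - 1e-6)
      c(a = amp, b = max(-log(1 - frac) / t[mid], 1e-3), c = cc)
    },
    asymptotic = {
      b0 <- max(y[1], 0)
      # crude decay rate from the gap closed between first and last points
      frac <- min(max((amp - y[length(y)]) / (amp - b0), 1e-6), 1 - 1e-6)
      rate <- -log(frac) / (t[length(t)] - t[1])
      c(a = amp, b = b0, c = log(max(rate, 1e-3)))
    }
  )
  validate_growth_params(model, p)
}

validate_series <- function(data) {
  if (!is.data.frame(data) || !all(c("age", "value") %in% names(data))) {
    rlang::abort("`data` must be a data frame with columns `age` and `value`.")
  }
  data <- dplyr::arrange(dplyr::as_tibble(data[c("age", "value")]), .data$age)
  if (nrow(data) < 4L) {
    rlang::abort("A trait series needs at least 4 observations to fit 3 parameters.")
  }
  if (any(duplicated(data$age))) {
    rlang::abort("Ages within one series must be strictly increasing.")
  }
  data
}

#' Fit one growth law to one trait series
#'
#' Minimizes the residual sum of squares by Levenberg-Marquardt least
#' squares on bound-free transformed parameters (see
#' [initial_growth_params()] for the starting heuristics). A failed or
#' non-improving start is retried up to `control$max_restarts` times with
#' seeded multiplicative lognormal jitter on the starting values; the best
#' SSE over all starts is kept, so the returned SSE never exceeds the SSE
#' at the initial guess. The log-likelihood is the concentrated Gaussian
#' form `-(n/2) * (log(2*pi*sse/n) + 1)`.
#'
#' @inheritParams initial_growth_params
#' @param init Optional starting parameter vector; defaults to the
#'   self-start heuristic.
#' @param seed Integer seed controlling the restart jitter.
#' @param control A [growth_control()] list.
#' @return An object of class `growth_fit`: a list with the model id,
#'   fitted `params`, `sse`, `n`, `sigma2` (`sse/n`), `loglik`,
#'   `converged`, `n_restarts_used`, and the data. Use [tidy()],
#'   [glance()], [augment()] and [autoplot()] on it.
#' @export
#' @examples
#' d <- tibble::tibble(age = c(1, 2, 3, 5, 6, 7, 9, 10, 11))
#' d$value <- growth_value("richard", c(a = 30, b = 0.2, c = 2), d$age)
#' fit <- fit_growth(d, "richard")
#' glance(fit)
fit_growth <- function(data, model, init = NULL, seed = 1L,
                       control = growth_control()) {
  model <- match_growth_model(model)
  series <- validate_series(data)
  init <- if (is.null(init)) {
    initial_growth_params(series, model)
  } else {
    validate_growth_params(model, init)
  }
  fit_growth_impl(series, model, init, seed, control)
}

# Levenberg-Marquardt driver shared by fit_growth() (unique-age series)
# and the pooled class fits (repeated ages across clones).
fit_growth_impl <- function(data, model, init, seed, control) {
  t <- data$age; y <- data$value
  resid_fn <- function(theta) {
    p <- from_unconstrained(model, theta)
    r <- y - growth_value(model, p, t)
    r[!is.finite(r)] <- 1e6
    r
  }
  run_lm <- function(theta0) {
    out <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = control$max_iter, ftol = control$ftol, ptol = 1e-12
        )
      ),
      error = function(e) NULL
    )
    if (is.null(out)) return(NULL)
    list(theta = out$par, sse = sum(out$fvec^2),
         converged = out$info %in% 1:4)
  }

  theta0 <- to_unconstrained(model, init)
  sse0 <- sum(resid_fn(theta0)^2)
  best <- run_lm(theta0)
  n_restarts <- 0L
  need_retry <- function(b) is.null(b) || !b$converged || b$sse > sse0 + 1e-12
  if (need_retry(best)) {
    withr::with_seed(seed, {
      for (k in seq_len(control$max_restarts)) {
        jit <- init * exp(stats::rnorm(3, 0, control$jitter_sd))
        jit <- tryCatch(validate_growth_params(model, jit), error = function(e) NULL)
        if (is.null(jit)) next
        n_restarts <- k
        cand <- run_lm(to_unconstrained(model, jit))
        if (!is.null(cand) && (is.null(best) || cand$sse < best$sse)) best <- cand
        if (!need_retry(best)) break
      }
    })
  }

  if (is.null(best)) {
    best <- list(theta = theta0, sse = sse0, converged = FALSE)
  }
  params <- from_unconstrained(model, best$theta)
  n <- length(y)
  sse <- min(best$sse, sse0)
  if (best$sse > sse0) params <- init # never return worse than the start
  sigma2 <- max(sse / n, control$sigma2_floor)
  structure(
    list(
      model = model, params = params, sse = sse, n = n,
      sigma2 = sigma2,
      loglik = -(n / 2) * (log(2 * pi * sigma2) + 1),
      converged = isTRUE(best$converged),
      n_restarts_used = n_restarts,
      data = dplyr::as_tibble(data[c("age", "value")])
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> %s law, n = %d\n  params: %s\n  sse = %.4g, loglik = %.4g, converged = %s\n",
    x$model, x$n,
    paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
    x$sse, x$loglik, x$converged
  ))
  invisible(x)
}

#' Fit-quality metrics for a growth-curve fit
#'
#' The five metrics used to compare growth laws. With `k = n_params + 1`
#' (the residual variance is a counted parameter) and `sigma2 = sse/n`:
#' `aic = n*log(2*pi*sigma2) + n + 2k`, `bic = n*log(2*pi*sigma2) + n +
#' k*log(n)` (the full-Gaussian-likelihood convention, matching
#' `stats::AIC()` on `nls` fits), `r2 = 1 - sse/SST` about the series
#' mean, `rmse = sqrt(sse/n)`, `mae` the mean absolute residual.
#'
#' @param fit A [fit_growth()] result.
#' @return A one-row tibble: `aic`, `bic`, `r2`, `rmse`, `mae`.
#' @export
fit_metrics <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  n <- fit$n
  k <- length(fit$params) + 1
  sst <- sum((fit$data$value - mean(fit$data$value))^2)
  if (sst == 0) {
    rlang::abort("Series has zero variance about its mean: R2 is undefined.")
  }
  resid <- fit$data$value - growth_value(fit$model, fit$params, fit$data$age)
  base <- n * log(2 * pi * fit$sigma2) + n
  tibble::tibble(
    aic = base + 2 * k,
    bic = base + k * log(n),
    r2 = 1 - fit$sse / sst,
    rmse = sqrt(fit$sse / n),
    mae = mean(abs(resid))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @rdname fit_growth
#' @param x,object A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname fit_growth
#' @export
glance.growth_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      model = x$model, n = x$n, sse = x$sse, loglik = x$loglik,
      converged = x$converged, n_restarts_used = x$n_restarts_used
    ),
    fit_metrics(x)
  )
}

#' @rdname fit_growth
#' @export
augment.growth_fit <- function(x, ...) {
  dplyr::mutate(
    x$data,
    .fitted = growth_value(x$model, x$params, .data$age),
    .resid = .data$value - .data$.fitted
  )
}

#' Fit growth laws across a long-format phenotype table
#'
#' Maps [fit_growth()] over every clone x trait x model combination of a
#' long phenotype table.
#'
#' @param data Data frame with columns `clone`, `trait`, `age`, `value`.
#' @param models Character vector of growth laws to fit.
#' @param seed Integer seed forwarded to each fit's restart jitter.
#' @param control A [growth_control()].
#' @return A tibble with one row per clone x trait x model: identifiers,
#'   a `fit` list-column of `growth_fit` objects, the fitted parameters,
#'   `sse`, `loglik`, `converged` and the five fit metrics.
#' @export
fit_growth_curves <- function(data, models = growth_model_ids(), seed = 1L,
                              control = growth_control()) {
  data <- validate_phenotypes(data)
  models <- vapply(models, match_growth_model, character(1))
  grid <- tidyr::expand_grid(
    dplyr::distinct(data, .data$clone, .data$trait),
    model = unname(models)
  )
  fits <- purrr::pmap(grid, function(clone, trait, model) {
    series <- data[data$clone == clone & data$trait == trait, c("age", "value")]
    fit_growth(series, model, seed = seed, control = control)
  })
  dplyr::bind_cols(
    grid,
    tibble::tibble(fit = fits),
    purrr::map_dfr(fits, function(f) {
      dplyr::bind_cols(
        tibble::as_tibble(as.list(f$params)),
        tibble::tibble(sse = f$sse, loglik = f$loglik, converged = f$converged),
        fit_metrics(f)
      )
    })
  )
}
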