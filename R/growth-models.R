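#' The four supported growth laws
#'
#' Catalogue of the sigmoidal growth laws used throughout the package. All
#' four have three parameters:
#'
#' * `gompertz`: `y = a * exp(-b * c^t)`, with `a > 0`, `b > 0`, `0 < c < 1`.
#' * `richard` (Chapman-Richards): `y = a * (1 - exp(-b*t))^c`, all
#'   parameters positive; sigmoid for `c > 1`.
#' * `logistic`: `y = Asym / (1 + exp((xmid - t)/scal))`, `Asym > 0`,
#'   `scal > 0`.
#' * `asymptotic` (asymptotic regression): `y = a + (b - a) * exp(-exp(c)*t)`,
#'   with `a > b >= 0`; `a` is the plateau and `b` the value at `t = 0`.
#'
#' Time `t` is age in years from planting; `y` is the trait value (height in
#' m or DBH in cm).
#'
#' @return A tibble with one row per model: `model`, `n_params`, and a
#'   list-column `param_names` giving the canonical parameter order.
#' @export
#' @examples
#' growth_models()
growth_models <- function() {
  tibble::tibble(
    model = c("gompertz", "richard", "logistic", "asymptotic"),
    n_params = 3L,
    param_names = list(
      c("a", "b", "c"),
      c("a", "b", "c"),
      c("Asym", "xmid", "scal"),
      c("a", "b", "c")
    )
  )
}

growth_model_ids <- function() growth_models()$model

growth_param_names <- function(model) {
  spec <- growth_models()
  spec$param_names[[match(model, spec$model)]]
}

match_growth_model <- function(model) {
  rlang::arg_match0(model, growth_model_ids())
}

# Coerce a params argument (named or canonical-order numeric) to a named
# vector in canonical order.
canonical_params <- function(model, params) {
  nm <- growth_param_names(model)
  params <- unlist(params, use.names = TRUE)
  if (length(params) != 3L) {
    rlang::abort(sprintf("`params` for the %s model must have length 3.", model))
  }
  if (!is.null(names(params)) && all(nm %in% names(params))) {
    params <- params[nm]
  } else {
    names(params) <- nm
  }
  params
}

#' Validate a growth-law parameter vector
#'
#' Checks the admissibility constraints of each law (positivity; `c` in
#' (0, 1) for Gompertz; `a > b >= 0` for asymptotic regression) and errors
#' naming the violated constraint.
#'
#' @param model One of `"gompertz"`, `"richard"`, `"logistic"`, `"asymptotic"`.
#' @param params Numeric vector of length 3, named or in canonical order
#'   (see [growth_models()]).
#' @return The validated parameter vector, named, invisibly usable downstream.
#' @export
validate_growth_params <- function(model, params) {
  model <- match_growth_model(model)
  p <- canonical_params(model, params)
  if (any(!is.finite(p))) {
    rlang::abort(sprintf("%s parameters must be finite.", model))
  }
  bad <- function(constraint) {
    rlang::abort(sprintf(
      "Invalid %s parameters (%s): constraint `%s` violated.",
      model, paste(sprintf("%s=%.4g", names(p), p), collapse = ", "), constraint
    ))
  }
  switch(model,
    richard = {
      if (p["a"] <= 0) bad("a > 0")
      if (p["b"] <= 0) bad("b > 0")
      if (p["c"] <= 0) bad("c > 0")
    },
    gompertz = {
      if (p["a"] <= 0) bad("a > 0")
      if (p["b"] <= 0) bad("b > 0")
      if (p["c"] <= 0 || p["c"] >= 1) bad("0 < c < 1")
    },
    logistic = {
      if (p["Asym"] <= 0) bad("Asym > 0")
      if (p["scal"] <= 0) bad("scal > 0")
    },
    asymptotic = {
      if (p["b"] < 0) bad("b >= 0")
      if (p["a"] <= p["b"]) bad("a > b")
    }
  )
  p
}

#' Evaluate a growth law
#'
#' @inheritParams validate_growth_params
#' @param t Age(s) in years, `t >= 0`; vectorized.
#' @return Numeric vector of trait values, same length as `t`.
#' @export
#' @examples
#' growth_value("richard", c(a = 30, b = 0.2, c = 2), t = 5)
growth_value <- function(model, params, t) {
  p <- validate_growth_params(model, params)
  stopifnot(all(t >= 0))
  switch(model,
    gompertz   = p["a"] * exp(-p["b"] * p["c"]^t),
    richard    = p["a"] * (1 - exp(-p["b"] * t))^p["c"],
    logistic   = p["Asym"] / (1 + exp((p["xmid"] - t) / p["scal"])),
    asymptotic = p["a"] + (p["b"] - p["a"]) * exp(-exp(p["c"]) * t)
  ) |> unname()
}

# First and second time-derivatives, analytic, as a two-column list.
# Richard with c < 1 is singular at exactly t = 0: the one-sided limit of
# dy/dt is +Inf and is returned as Inf (and d2y as -Inf).
growth_d12 <- function(model, p, t) {
  switch(model,
    gompertz = {
      u <- p["b"] * p["c"]^t
      lc <- log(p["c"])
      d1 <- -p["a"] * lc * u * exp(-u)
      d2 <- p["a"] * lc^2 * u * exp(-u) * (u - 1)
      list(d1 = unname(d1), d2 = unname(d2))
    },
    richard = {
      s <- 1 - exp(-p["b"] * t)
      a <- p["a"]; b <- p["b"]; cc <- p["c"]
      d1 <- a * cc * b * (1 - s) * s^(cc - 1)
      d2 <- a * cc * b^2 * (1 - s) * s^(cc - 2) * ((cc - 1) * (1 - s) - s)
      # one-sided limits at t = 0
      at0 <- t == 0
      if (any(at0)) {
        d1[at0] <- if (cc > 1) 0 else if (cc == 1) a * b else Inf
        d2[at0] <- if (cc > 2) 0 else if (cc == 2) 2 * a * b^2 else
          if (cc > 1) Inf else if (cc == 1) -a * b^2 else -Inf
      }
      list(d1 = unname(d1), d2 = unname(d2))
    },
    logistic = {
      z <- (p["xmid"] - t) / p["scal"]
      ez <- exp(z)
      d1 <- p["Asym"] / p["scal"] * ez / (1 + ez)^2
      d2 <- p["Asym"] / p["scal"]^2 * ez * (ez - 1) / (1 + ez)^3
      list(d1 = unname(d1), d2 = unname(d2))
    },
    asymptotic = {
      k <- exp(p["c"])
      d1 <- (p["a"] - p["b"]) * k * exp(-k * t)
      d2 <- -(p["a"] - p["b"]) * k^2 * exp(-k * t)
      list(d1 = unname(d1), d2 = unname(d2))
    }
  )
}

#' Analytic first and second time-derivatives of a growth law
#'
#' The Chapman-Richards law with `c < 1` has a singular growth rate at
#' exactly `t = 0`; the one-sided limit (`Inf`) is returned there.
#'
#' @inheritParams growth_value
#' @return A tibble with columns `t`, `dy` (growth rate, units/year) and
#'   `d2y` (acceleration, units/year^2).
#' @export
growth_deriv <- function(model, params, t) {
  p <- validate_growth_params(model, params)
  stopifnot(all(t >= 0))
  d <- growth_d12(model, p, t)
  tibble::tibble(t = t, dy = d$d1, d2y = d$d2)
}

#' Time of maximum growth rate (inflection point)
#'
#' Solves `d2y/dt2 = 0` for the age at which the growth rate peaks. Closed
#' forms exist for all supported laws: `xmid` for the logistic,
#' `log(c)/b` for Chapman-Richards (`c > 1`), `log(b)/(-log(c))` for
#' Gompertz. Laws without an interior inflection on `t > 0` (asymptotic
#' regression; Chapman-Richards with `c <= 1`; Gompertz with `b <= 1`,
#' whose inflection falls at or before planting) return `NA` with a
#' `"reason"` attribute rather than raising an error.
#'
#' @inheritParams validate_growth_params
#' @return Age in years at maximum growth, or `NA_real_` (with attribute
#'   `reason`) when no interior inflection exists.
#' @export
#' @examples
#' time_of_max_growth("richard", c(a = 30, b = 0.2, c = 2)) # log(2)/0.2
time_of_max_growth <- function(model, params) {
  p <- validate_growth_params(model, params)
  no_inflection <- function(reason) {
    structure(NA_real_, reason = reason)
  }
  switch(model,
    logistic = unname(p["xmid"]),
    richard = {
      if (p["c"] <= 1) return(no_inflection("no interior inflection: richard with c <= 1"))
      unname(log(p["c"]) / p["b"])
    },
    gompertz = {
      tstar <- unname(log(p["b"]) / (-log(p["c"])))
      if (tstar <= 0) return(no_inflection("no interior inflection: gompertz with b <= 1"))
      tstar
    },
    asymptotic = no_inflection("no interior inflection: asymptotic regression is concave")
  )
}

#' Asymptote (plateau) of a growth law
#'
#' The limit of the trait value as age grows without bound: `a` for
#' Gompertz, Chapman-Richards and asymptotic regression, `Asym` for the
#' logistic. The Gompertz law diverges for `c >= 1`, which parameter
#' validation already rejects.
#'
#' @inheritParams validate_growth_params
#' @return The plateau trait value.
#' @export
growth_asymptote <- function(model, params) {
  p <- validate_growth_params(model, params)
  unname(switch(model,
    logistic = p["Asym"],
    p["a"]
  ))
}
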