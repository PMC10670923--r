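#' Curvature of a fitted growth trajectory
#'
#' `kappa(t) = |y''| / (1 + y'^2)^(3/2)` with analytic derivatives. By
#' default curvature is computed on raw trait/age units (m or cm against
#' years), mirroring maximum-curvature staging on raw data; note that
#' curvature is *not* invariant to axis rescaling, so raw-unit results
#' depend on the measurement units. [max_curvature_point()] offers a
#' minmax-normalized mode that removes this dependence.
#'
#' @inheritParams growth_value
#' @return Numeric vector `kappa(t) >= 0`.
#' @export
curvature <- function(model, params, t) {
  p <- validate_growth_params(model, params)
  stopifnot(all(t >= 0))
  d <- growth_d12(model, p, t)
  if (any(!is.finite(d$d1)) || any(!is.finite(d$d2))) {
    rlang::abort(paste0(
      "Curvature is singular at t = ",
      paste(t[!is.finite(d$d1) | !is.finite(d$d2)], collapse = ", "),
      " (richard with c < 1 has an infinite growth rate at t = 0)."
    ))
  }
  abs(d$d2) / (1 + d$d1^2)^1.5
}

# curvature after affine axis rescaling: tau = (t-lo)/dt, yhat = y/dy
scaled_curvature <- function(model, p, t, dt, dy) {
  d <- growth_d12(model, p, t)
  abs(d$d2 * dt^2 / dy) / (1 + (d$d1 * dt / dy)^2)^1.5
}

#' Point of maximum curvature of a growth trajectory
#'
#' Finds the age maximizing the curvature of the fitted curve over the
#' decelerating limb, used to divide ontogeny into a rapid-growth and a
#' reduced-growth phase. The argmax is located on a dense grid
#' (`dt = 0.01` y) and refined by golden-section search to `1e-4` y —
#' deterministic, so identical inputs give identical results.
#'
#' When the law has an interior inflection the search window is clipped to
#' start there (the decelerating limb); a window that ends up entirely on
#' the accelerating limb is reported with `limb = "accelerating"`. An
#' argmax on the window boundary is flagged (`boundary = TRUE`) rather
#' than silently returned.
#'
#' @inheritParams growth_value
#' @param window Numeric `c(t_lo, t_hi)` search window in years. Default:
#'   from the inflection time (or 0) to `3 * span_hint`.
#' @param span_hint Observation span in years used for the default window
#'   (default 11, an eleven-year measurement series).
#' @param normalize `"raw"` (default) computes curvature on raw units;
#'   `"minmax"` rescales both axes to `[0, 1]` over the window first,
#'   making the result invariant to measurement units.
#' @param guard Keep the search on the decelerating limb (`t` past the
#'   inflection) when an interior inflection exists.
#' @return One-row tibble of class `curvature_point`: `t_mc`, `y_mc`,
#'   `kappa`, `t_lo`, `t_hi`, `boundary`, `limb`, `normalize`.
#' @export
max_curvature_point <- function(model, params, window = NULL, span_hint = 11,
                                normalize = c("raw", "minmax"), guard = TRUE) {
  normalize <- rlang::arg_match(normalize)
  p <- validate_growth_params(model, params)
  tstar <- suppressWarnings(time_of_max_growth(model, p))
  if (is.null(window)) {
    window <- c(if (is.na(tstar)) 0 else tstar, 3 * span_hint)
  }
  stopifnot(length(window) == 2, window[1] < window[2], window[1] >= 0)
  lo <- window[1]; hi <- window[2]
  limb <- "decelerating"
  if (!is.na(tstar)) {
    if (hi <= tstar) {
      limb <- "accelerating"
    } else if (guard && lo < tstar) {
      lo <- tstar
    }
  }
  # avoid the t = 0 singularity of richard with c < 1 (and c < 2 in d2)
  if (model == "richard" && p["c"] < 2 && lo == 0) lo <- 1e-6

  if (normalize == "minmax") {
    dy <- growth_value(model, p, hi) - growth_value(model, p, lo)
    if (dy <= 0) dy <- 1
    kfun <- function(t) scaled_curvature(model, p, t, dt = hi - lo, dy = dy)
  } else {
    kfun <- function(t) {
      d <- growth_d12(model, p, t)
      abs(d$d2) / (1 + d$d1^2)^1.5
    }
  }

  grid <- seq(lo, hi, by = 0.01)
  kv <- kfun(grid)
  i <- which.max(kv)
  # golden-section refinement around the grid argmax
  a <- grid[max(i - 1L, 1L)]; b <- grid[min(i + 1L, length(grid))]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- kfun(x1); f2 <- kfun(x2)
  while (b - a > 1e-4) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- kfun(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- kfun(x1)
    }
  }
  t_mc <- (a + b) / 2
  boundary <- i == 1L || i == length(grid)
  if (boundary) {
    rlang::warn(sprintf(
      "Curvature is monotone over [%.3g, %.3g]: argmax lies on the window boundary.",
      lo, hi))
    t_mc <- grid[i]
  }
  out <- tibble::tibble(
    t_mc = t_mc,
    y_mc = growth_value(model, p, t_mc),
    kappa = kfun(t_mc),
    t_lo = lo, t_hi = hi, boundary = boundary, limb = limb,
    normalize = normalize
  )
  class(out) <- c("curvature_point", class(out))
  out
}

#' Ontogenetic phase report per genotype class
#'
#' For each genotype class's fitted trajectory, reports the
#' maximum-curvature age `t_mc` dividing ontogeny into a rapid-growth
#' phase (`[0, t_mc]`) and a reduced-growth phase (beyond `t_mc`), the
#' inflection age `t_max_growth`, and the asymptote. The comparison table
#' is ordered by `t_mc`, and rows whose phase boundary lies beyond the
#' last observed age carry `extrapolated = TRUE`. Whether larger-asymptote
#' classes enter the reduced phase later is evaluated and reported (as
#' `asymptote_tmc_concordant`), not asserted.
#'
#' @param class_fits Named list of `growth_fit` objects, one per genotype
#'   class (e.g. `lr_trajectory_test()$class_fits`), or a single
#'   `growth_fit`.
#' @inheritParams max_curvature_point
#' @return A tibble ordered by `t_mc`, one row per class: `class`,
#'   `t_mc`, `y_mc`, `t_max_growth`, `asymptote`, `phase_rapid`,
#'   `phase_reduced`, `boundary`, `extrapolated`; attribute
#'   `asymptote_tmc_concordant` summarizes the ordering check.
#' @export
phase_report <- function(class_fits, window = NULL, span_hint = NULL,
                         normalize = "raw", guard = TRUE) {
  if (inherits(class_fits, "growth_fit")) {
    class_fits <- list(all = class_fits)
  }
  stopifnot(length(class_fits) >= 1, all(purrr::map_lgl(class_fits, inherits, "growth_fit")))
  rows <- purrr::imap_dfr(class_fits, function(f, lab) {
    span <- if (is.null(span_hint)) max(f$data$age) else span_hint
    mc <- max_curvature_point(f$model, f$params, window = window,
                              span_hint = span, normalize = normalize,
                              guard = guard)
    tstar <- time_of_max_growth(f$model, f$params)
    tibble::tibble(
      class = lab,
      t_mc = mc$t_mc, y_mc = mc$y_mc,
      t_max_growth = as.numeric(tstar),
      asymptote = growth_asymptote(f$model, f$params),
      phase_rapid = sprintf("[0, %.2f]", mc$t_mc),
      phase_reduced = sprintf("(%.2f, Inf)", mc$t_mc),
      boundary = mc$boundary,
      extrapolated = mc$t_mc > max(f$data$age)
    )
  })
  rows <- dplyr::arrange(rows, .data$t_mc)
  attr(rows, "asymptote_tmc_concordant") <-
    if (nrow(rows) > 1) stats::cor(rows$t_mc, rows$asymptote) > 0 else NA
  rows
}
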