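#' Compare the four growth laws across clones for one trait
#'
#' For each of the five fit metrics, every pair of laws is compared with a
#' paired two-sided t-test across clones (the clone is the pairing unit),
#' and p-values are Holm-adjusted within each metric. The winner is the
#' law with the best (lowest) mean AIC among laws that are never
#' significantly worse than another law on AIC; ties break by lower mean
#' BIC, then lower mean RMSE, then the fixed catalogue order.
#'
#' Degenerate paired t-tests (zero variance of the differences but a
#' nonzero mean difference, e.g. one law uniformly 10 AIC units worse)
#' are reported as `p = 0` with `degenerate = TRUE`: in the paired-t
#' framework a constant nonzero difference is infinitely strong evidence.
#'
#' @param fits A [fit_growth_curves()] result restricted to one trait (or
#'   containing a single trait). Clones lacking a converged fit for every
#'   law are dropped with a warning.
#' @param alpha Significance level applied to the Holm-adjusted p-values.
#' @return An object of class `model_comparison`: a list with `trait`,
#'   `metrics` (clone x model metric table), `pairwise` (tibble of the 6
#'   pairs x 5 metrics tests), `winner`, and `decision_trace` (character
#'   vector of the selection rationale).
#' @export
compare_growth_models <- function(fits, alpha = 0.05) {
  stopifnot(is.data.frame(fits))
  trait <- unique(fits$trait)
  if (length(trait) != 1L) {
    rlang::abort("`fits` must cover exactly one trait; filter before comparing.")
  }
  models <- growth_model_ids()
  missing_models <- setdiff(models, unique(fits$model))
  if (length(missing_models)) {
    rlang::abort(paste0("Missing fits for model(s): ",
                        paste(missing_models, collapse = ", ")))
  }

  metric_cols <- c("aic", "bic", "r2", "rmse", "mae")
  tab <- dplyr::select(fits, "clone", "model", "converged",
                       dplyr::all_of(metric_cols))
  ok <- tab |>
    dplyr::summarise(all_ok = all(.data$converged) && dplyr::n() == length(models),
                     .by = "clone")
  dropped <- ok$clone[!ok$all_ok]
  if (length(dropped)) {
    rlang::warn(paste0("Dropping clone(s) without converged fits for all models: ",
                       paste(dropped, collapse = ", ")))
    tab <- tab[!tab$clone %in% dropped, ]
  }
  n_clones <- length(unique(tab$clone))
  if (n_clones < 3L) {
    rlang::abort("Fewer than 3 usable clones: paired model comparison refused.")
  }

  pairs <- utils::combn(models, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(metric_cols, function(m) {
    purrr::map_dfr(pairs, function(pr) {
      x <- tab[[m]][match_clone(tab, pr[1])]
      y <- tab[[m]][match_clone(tab, pr[2])]
      d <- x - y
      if (stats::sd(d) == 0) {
        tibble::tibble(
          metric = m, model1 = pr[1], model2 = pr[2],
          mean_diff = mean(d), statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
          p = if (mean(d) == 0) 1 else 0, degenerate = mean(d) != 0
        )
      } else {
        tt <- stats::t.test(x, y, paired = TRUE)
        tibble::tibble(
          metric = m, model1 = pr[1], model2 = pr[2],
          mean_diff = unname(tt$estimate), statistic = unname(tt$statistic),
          p = tt$p.value, degenerate = FALSE
        )
      }
    })
  }) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "holm"),
                  .by = "metric")

  means <- tab |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean),
                     .by = "model") |>
    dplyr::arrange(match(.data$model, models))

  # "significantly worse on AIC": adjusted p < alpha and higher mean AIC
  aic_pairs <- pairwise[pairwise$metric == "aic", ]
  worse <- vapply(models, function(mod) {
    any(vapply(seq_len(nrow(aic_pairs)), function(i) {
      pr <- aic_pairs[i, ]
      if (pr$p_adj >= alpha) return(FALSE)
      other <- setdiff(c(pr$model1, pr$model2), mod)
      if (length(other) != 1L) return(FALSE)
      means$aic[means$model == mod] > means$aic[means$model == other]
    }, logical(1)))
  }, logical(1))

  candidates <- models[!worse]
  trace <- c(
    sprintf("trait: %s; %d clones compared", trait, n_clones),
    sprintf("non-dominated on AIC at alpha = %g: %s", alpha,
            paste(candidates, collapse = ", "))
  )
  ord <- means[means$model %in% candidates, ]
  ord <- ord[order(ord$aic, ord$bic, ord$rmse, match(ord$model, models)), ]
  winner <- ord$model[1]
  trace <- c(trace, sprintf(
    "winner: %s (mean AIC %.3f; ties broken by BIC then RMSE then catalogue order)",
    winner, ord$aic[1]
  ))

  structure(
    list(trait = trait, metrics = tab, means = means, pairwise = pairwise,
         winner = winner, alpha = alpha, decision_trace = trace),
    class = "model_comparison"
  )
}

match_clone <- function(tab, model) {
  idx <- which(tab$model == model)
  idx[order(tab$clone[idx])]
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  cat(paste0("  ", x$decision_trace, collapse = "\n"), "\n")
  invisible(x)
}

#' @rdname compare_growth_models
#' @param x,object A `model_comparison`.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) x$pairwise

#' @rdname compare_growth_models
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, winner = x$winner,
    n_clones = length(unique(x$metrics$clone)),
    n_significant_pairs = sum(x$pairwise$p_adj < x$alpha)
  )
}
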