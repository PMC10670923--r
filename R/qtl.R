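#' Minor allele frequencies of a genotype matrix
#'
#' @param geno A data frame with a `clone` column and one column per SNP
#'   holding diploid calls like `"A/G"`; missing calls are `"./."` or `NA`.
#'   Heterozygotes are unordered (`"A/G"` and `"G/A"` are the same call).
#' @return A tibble with one row per SNP: `snp`, `maf` (in `[0, 0.5]`),
#'   `n_called`, `alleles` (slash-separated, major first), and `flagged`
#'   (`TRUE` when missingness is 50% or more).
#' @export
snp_maf <- function(geno) {
  geno <- validate_genotypes(geno)
  snps <- setdiff(names(geno), "clone")
  purrr::map_dfr(snps, function(s) {
    calls <- parse_calls(geno[[s]], s)
    n_called <- sum(!is.na(calls$a1))
    if (n_called == 0) {
      rlang::abort(sprintf("SNP %s has no non-missing calls.", s))
    }
    counts <- sort(table(c(calls$a1, calls$a2)), decreasing = TRUE)
    maf <- if (length(counts) < 2) 0 else unname(counts[2]) / (2 * n_called)
    tibble::tibble(
      snp = s, maf = maf, n_called = n_called,
      alleles = paste(names(counts), collapse = "/"),
      flagged = n_called < nrow(geno) / 2
    )
  })
}

parse_calls <- function(x, snp) {
  x <- as.character(x)
  x[x %in% c("./.", ".", "", "NA")] <- NA
  parts <- stringr::str_split_fixed(x, stringr::fixed("/"), 2)
  parts[parts == ""] <- NA
  bad <- !is.na(x) & (is.na(parts[, 1]) | is.na(parts[, 2]))
  if (any(bad)) {
    rlang::abort(sprintf("SNP %s has malformed calls: %s", snp,
                         paste(unique(x[bad]), collapse = ", ")))
  }
  alleles <- unique(stats::na.omit(c(parts[, 1], parts[, 2])))
  if (length(alleles) > 2) {
    rlang::abort(sprintf("SNP %s has more than two alleles: %s", snp,
                         paste(alleles, collapse = ", ")))
  }
  list(a1 = parts[, 1], a2 = parts[, 2])
}

validate_genotypes <- function(geno) {
  if (!is.data.frame(geno) || !"clone" %in% names(geno)) {
    rlang::abort("`geno` must be a data frame with a `clone` column.")
  }
  if (anyDuplicated(geno$clone)) {
    rlang::abort("Duplicate clone ids in genotype matrix.")
  }
  dplyr::as_tibble(geno)
}

#' Partition clones into genotype classes at one SNP
#'
#' One class per observed diploid genotype (heterozygote order is
#' normalized). Classes smaller than `min_class_size` are excluded from
#' testing; if fewer than two usable classes remain (e.g. a monomorphic
#' SNP) the classing is marked untestable rather than raising an error.
#'
#' @inheritParams snp_maf
#' @param snp SNP column name.
#' @param min_class_size Smallest class size admitted to testing.
#' @return An object of class `genotype_classing`: list with `snp`,
#'   `members` (tibble `clone`, `genotype`, `usable`), `classes` (tibble
#'   `label`, `n`, `usable`), `testable`, and `merged_from` (`NULL` until
#'   [merge_similar_classes()] acts).
#' @export
genotype_classes <- function(geno, snp, min_class_size = 3L) {
  geno <- validate_genotypes(geno)
  if (!snp %in% names(geno)) {
    rlang::abort(sprintf("SNP %s not found in genotype matrix.", snp))
  }
  calls <- parse_calls(geno[[snp]], snp)
  gt <- ifelse(
    is.na(calls$a1), NA_character_,
    paste(pmin(calls$a1, calls$a2), pmax(calls$a1, calls$a2), sep = "/")
  )
  members <- tibble::tibble(clone = geno$clone, genotype = gt) |>
    dplyr::filter(!is.na(.data$genotype))
  classes <- members |>
    dplyr::count(.data$genotype, name = "n") |>
    dplyr::rename(label = "genotype") |>
    dplyr::mutate(usable = .data$n >= min_class_size)
  dropped <- classes$label[!classes$usable]
  if (length(dropped)) {
    rlang::inform(sprintf("SNP %s: class(es) below min_class_size dropped: %s",
                          snp, paste(dropped, collapse = ", ")))
  }
  members$usable <- members$genotype %in% classes$label[classes$usable]
  structure(
    list(snp = snp, members = members, classes = classes,
         min_class_size = as.integer(min_class_size),
         testable = sum(classes$usable) >= 2L, merged_from = NULL),
    class = "genotype_classing"
  )
}

#' @export
print.genotype_classing <- function(x, ...) {
  cat(sprintf("<genotype_classing> SNP %s: %s%s\n", x$snp,
              paste(sprintf("%s (n=%d%s)", x$classes$label, x$classes$n,
                            ifelse(x$classes$usable, "", ", dropped")),
                    collapse = ", "),
              if (x$testable) "" else " [untestable]"))
  invisible(x)
}

usable_members <- function(classing) {
  classing$members[classing$members$usable, c("clone", "genotype")]
}

# observations of one trait for a set of clones, as an (age, value) series
class_series <- function(pheno, clones, trait) {
  d <- pheno[pheno$clone %in% clones & pheno$trait == trait, c("age", "value")]
  d[order(d$age), ]
}

# Fit one curve to the pooled observations of a set of clones. Pooled
# observations repeat ages across clones, so the series validator (which
# demands unique ages) is bypassed via a jitter-free direct call.
fit_pooled <- function(pheno, clones, trait, model, init = NULL, seed = 1L,
                       control = growth_control()) {
  d <- class_series(pheno, clones, trait)
  fit_growth_pooled(d, model, init = init, seed = seed, control = control)
}

# fit_growth on a series that may contain repeated ages (pooled clones)
fit_growth_pooled <- function(data, model, init = NULL, seed = 1L,
                              control = growth_control()) {
  if (is.null(init)) {
    agg <- dplyr::summarise(data, value = mean(.data$value), .by = "age")
    init <- initial_growth_params(agg, model)
  }
  init <- validate_growth_params(model, init)
  fit_growth_impl(data, match_growth_model(model), init, seed, control)
}

#' Merge genotype classes with near-identical fitted trajectories
#'
#' Greedily merges the pair of usable classes whose fitted curves are
#' closest in normalized L2 distance (mean squared difference of the
#' predicted curves over the observation window, divided by the squared
#' pooled asymptote), refitting after each merge, while the distance stays
#' below `threshold`. With `threshold = 0` nothing ever merges. Mirrors
#' collapsing of genotypes whose growth patterns are indistinguishable
#' (e.g. a dominant heterozygote matching the alt homozygote).
#'
#' @param classing A [genotype_classes()] result.
#' @param pheno Long phenotype table (`clone`, `trait`, `age`, `value`).
#' @param trait Trait to fit.
#' @param model Growth law used for the class fits.
#' @param threshold Merge when normalized L2 distance is strictly below
#'   this value.
#' @param seed Seed for fit restarts.
#' @return A `genotype_classing` with merged labels (e.g. `"G/G+A/G"`) and
#'   `merged_from` recording the merge history.
#' @export
merge_similar_classes <- function(classing, pheno, trait, model = "richard",
                                  threshold = 0.002, seed = 1L) {
  stopifnot(inherits(classing, "genotype_classing"))
  pheno <- validate_phenotypes(pheno)
  if (!classing$testable) return(classing)
  members <- usable_members(classing)
  labels <- unique(members$genotype)
  history <- list()

  fit_class <- function(lab) {
    clones <- members$clone[members$genotype == lab]
    fit_pooled(pheno, clones, trait, model, seed = seed)
  }
  fits <- purrr::map(rlang::set_names(labels), fit_class)

  repeat {
    if (length(labels) < 2) break
    ages <- sort(unique(pheno$age[pheno$trait == trait]))
    grid <- seq(min(ages), max(ages), length.out = 200)
    pairs <- utils::combn(labels, 2, simplify = FALSE)
    dist <- vapply(pairs, function(pr) {
      y1 <- growth_value(model, fits[[pr[1]]]$params, grid)
      y2 <- growth_value(model, fits[[pr[2]]]$params, grid)
      asym <- mean(c(growth_asymptote(model, fits[[pr[1]]]$params),
                     growth_asymptote(model, fits[[pr[2]]]$params)))
      mean((y1 - y2)^2) / asym^2
    }, numeric(1))
    i <- which.min(dist)
    if (dist[i] >= threshold) break
    pr <- pairs[[i]]
    new_lab <- paste(pr, collapse = "+")
    history <- c(history, list(tibble::tibble(
      merged = new_lab, from1 = pr[1], from2 = pr[2], distance = dist[i]
    )))
    members$genotype[members$genotype %in% pr] <- new_lab
    labels <- unique(members$genotype)
    fits[pr] <- NULL
    fits[[new_lab]] <- fit_class(new_lab)
  }

  out <- classing
  out$members <- dplyr::left_join(
    classing$members[c("clone", "genotype", "usable")] |>
      dplyr::rename(original = "genotype"),
    dplyr::rename(members, merged_genotype = "genotype"),
    by = "clone"
  ) |>
    dplyr::transmute(
      clone = .data$clone,
      genotype = dplyr::coalesce(.data$merged_genotype, .data$original),
      usable = .data$usable
    )
  out$classes <- out$members |>
    dplyr::filter(.data$usable) |>
    dplyr::count(.data$genotype, name = "n") |>
    dplyr::rename(label = "genotype") |>
    dplyr::mutate(usable = TRUE)
  out$testable <- nrow(out$classes) >= 2L
  out$merged_from <- if (length(history)) dplyr::bind_rows(history) else NULL
  out
}

#' Likelihood-ratio test of genotype effects on a whole growth trajectory
#'
#' Compares a pooled growth-curve fit to all usable clones' observations
#' (log-likelihood `L0`) against genotype-class-wise fits (`L1`) via
#' `LR = -2 * (logL0 - logL1)`, referred to a chi-square distribution.
#'
#' Two residual-variance conventions are available for `L1`:
#' * `sigma = "shared"` (default): one residual variance pooled across
#'   classes, `df = n_params * (n_classes - 1)`. This is the convention
#'   under which the chi-square reference is calibrated (the class split
#'   frees only curve parameters).
#' * `sigma = "per-class"`: each class keeps its own concentrated
#'   variance, as independent per-class `nls` fits would. The class split
#'   then also frees `n_classes - 1` variances, so `count_sigma_df = TRUE`
#'   (df `= (n_params + 1) * (n_classes - 1)`) is the calibrated pairing;
#'   `count_sigma_df = FALSE` reproduces the curve-parameters-only df rule
#'   and is anticonservative.
#'
#' Class fits are initialized from the pooled fit (and self-started
#' restarts), which guarantees `L1 >= L0` up to solver slack.
#'
#' @inheritParams merge_similar_classes
#' @param sigma Residual-variance convention for `L1` (see Details).
#' @param count_sigma_df Count freed residual variances in the df
#'   (only meaningful with `sigma = "per-class"`).
#' @return Object of class `lr_test`: `snp`, `trait`, `model`, `logL0`,
#'   `logL1`, `lr`, `df`, `p`, `n_classes`, `class_fits` (named list of
#'   `growth_fit`), `pooled_fit`, `converged`. `tidy()` gives per-class
#'   parameters; `glance()` the one-row test summary.
#' @export
lr_trajectory_test <- function(pheno, classing, trait, model = "richard",
                               sigma = c("shared", "per-class"),
                               count_sigma_df = FALSE, seed = 1L,
                               control = growth_control()) {
  sigma <- rlang::arg_match(sigma)
  model <- match_growth_model(model)
  pheno <- validate_phenotypes(pheno)
  stopifnot(inherits(classing, "genotype_classing"))
  if (!classing$testable) {
    rlang::abort(sprintf("SNP %s is untestable (fewer than 2 usable classes).",
                         classing$snp))
  }
  members <- usable_members(classing)
  labels <- sort(unique(members$genotype))
  pooled <- fit_pooled(pheno, members$clone, trait, model, seed = seed,
                       control = control)
  class_fits <- purrr::map(rlang::set_names(labels), function(lab) {
    clones <- members$clone[members$genotype == lab]
    f_a <- fit_pooled(pheno, clones, trait, model, init = pooled$params,
                      seed = seed, control = control)
    f_b <- fit_pooled(pheno, clones, trait, model, seed = seed, control = control)
    if (f_b$sse < f_a$sse) f_b else f_a
  })
  converged <- pooled$converged && all(purrr::map_lgl(class_fits, "converged"))

  n <- pooled$n
  k <- 3L # curve parameters per class
  G <- length(labels)
  logL0 <- pooled$loglik
  if (sigma == "shared") {
    sse1 <- sum(purrr::map_dbl(class_fits, "sse"))
    s2 <- max(sse1 / n, control$sigma2_floor)
    logL1 <- -(n / 2) * (log(2 * pi * s2) + 1)
    df <- k * (G - 1L)
  } else {
    logL1 <- sum(purrr::map_dbl(class_fits, "loglik"))
    df <- (k + as.integer(count_sigma_df)) * (G - 1L)
  }
  lr <- -2 * (logL0 - logL1)
  p <- if (converged) stats::pchisq(lr, df, lower.tail = FALSE) else NA_real_
  structure(
    list(snp = classing$snp, trait = trait, model = model,
         logL0 = logL0, logL1 = logL1, lr = lr, df = as.integer(df), p = p,
         n_classes = G, sigma = sigma, class_fits = class_fits,
         pooled_fit = pooled, converged = converged),
    class = "lr_test"
  )
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf(
    "<lr_test> SNP %s, %s, %s law: LR = %.3f, df = %d, p = %.3g (%d classes)%s\n",
    x$snp, x$trait, x$model, x$lr, x$df, x$p, x$n_classes,
    if (x$converged) "" else " [non-converged fits: p withheld]"
  ))
  invisible(x)
}

#' @rdname lr_trajectory_test
#' @param x,object An `lr_test`.
#' @param ... Unused.
#' @export
tidy.lr_test <- function(x, ...) {
  purrr::imap_dfr(x$class_fits, function(f, lab) {
    dplyr::bind_cols(
      tibble::tibble(snp = x$snp, trait = x$trait, class = lab,
                     n_obs = f$n, loglik = f$loglik),
      tibble::as_tibble(as.list(f$params))
    )
  })
}

#' @rdname lr_trajectory_test
#' @export
glance.lr_test <- function(x, ...) {
  tibble::tibble(
    snp = x$snp, trait = x$trait, model = x$model, n_classes = x$n_classes,
    logL0 = x$logL0, logL1 = x$logL1, lr = x$lr, df = x$df, p = x$p,
    converged = x$converged
  )
}

#' Per-year single-marker association (one-way GLM)
#'
#' At each requested age, fits a fixed-effects linear model of the trait
#' value on genotype class as a categorical factor and reports the overall
#' F-test — equivalent to a one-way ANOVA. No structure or kinship
#' covariates are included.
#'
#' @inheritParams merge_similar_classes
#' @param ages Ages to test; defaults to all ages present for the trait.
#' @return A tibble with one row per age: `age`, `statistic` (F), `df1`,
#'   `df2`, `p`, `n`.
#' @export
per_year_glm <- function(pheno, classing, trait, ages = NULL) {
  pheno <- validate_phenotypes(pheno)
  members <- usable_members(classing)
  d <- dplyr::inner_join(pheno[pheno$trait == trait, ], members, by = "clone")
  if (is.null(ages)) ages <- sort(unique(d$age))
  purrr::map_dfr(ages, function(a) {
    da <- d[d$age == a, ]
    counts <- table(da$genotype)
    if (length(counts) < 2 || any(counts < 2)) {
      rlang::abort(sprintf(
        "Age %s: need >= 2 classes with >= 2 members each for the per-year GLM.", a))
    }
    if (nrow(da) - length(counts) < 1) {
      rlang::abort(sprintf("Age %s: zero residual degrees of freedom.", a))
    }
    fit <- stats::lm(value ~ factor(genotype), data = da)
    an <- stats::anova(fit)
    tibble::tibble(
      age = a, statistic = an$`F value`[1],
      df1 = an$Df[1], df2 = an$Df[2], p = an$`Pr(>F)`[1], n = nrow(da)
    )
  })
}

#' Multivariate association of fitted curve parameters (one-way MANOVA)
#'
#' Treats each clone's fitted parameter vector as a multivariate trait and
#' tests for genotype-class differences with Wilks' lambda,
#' `det(W)/det(W + B)`. The reported `p` uses Rao's F transformation
#' (exact for up to two response dimensions or two classes, so a
#' one-dimensional input reproduces the one-way ANOVA p-value);
#' `p_bartlett` gives Bartlett's chi-square approximation
#' `-(n - 1 - (p + g)/2) * log(lambda)` on `p*(g-1)` df.
#'
#' @param params A data frame with a `clone` column and one numeric column
#'   per fitted parameter (one row per clone, one trait).
#' @param classing A [genotype_classes()] result.
#' @return One-row tibble: `lambda`, `statistic` (Rao F), `df1`, `df2`,
#'   `p`, `chisq`, `df_chisq`, `p_bartlett`, `n`, `n_classes`.
#' @export
param_association <- function(params, classing) {
  stopifnot(is.data.frame(params), "clone" %in% names(params))
  members <- usable_members(classing)
  d <- dplyr::inner_join(dplyr::as_tibble(params), members, by = "clone")
  y <- as.matrix(d[setdiff(names(d), c("clone", "genotype"))])
  storage.mode(y) <- "double"
  g <- factor(d$genotype)
  n <- nrow(y); p <- ncol(y); G <- nlevels(g)
  if (n < G + p + 2) {
    rlang::abort("Too few clones for the parameter MANOVA (need n >= classes + dims + 2).")
  }
  grand <- colMeans(y)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(g)) {
    yi <- y[g == lev, , drop = FALSE]
    mi <- colMeans(yi)
    W <- W + crossprod(sweep(yi, 2, mi))
    B <- B + nrow(yi) * tcrossprod(mi - grand)
  }
  if (rcond(W) < 1e-12) {
    rlang::abort("Within-class covariance is singular; consider standardizing parameters.")
  }
  lambda <- det(W) / det(W + B)

  # Rao's F approximation (exact for p <= 2 or G - 1 <= 2)
  m <- G - 1
  s <- if (p^2 + m^2 - 5 > 0) sqrt((p^2 * m^2 - 4) / (p^2 + m^2 - 5)) else 1
  df1 <- p * m
  df2 <- s * (n - G - (p - m + 1) / 2) - (p * m - 2) / 2
  lam_s <- lambda^(1 / s)
  f_stat <- (1 - lam_s) / lam_s * df2 / df1
  p_f <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  chisq <- -(n - 1 - (p + G) / 2) * log(lambda)
  df_chi <- p * m
  tibble::tibble(
    lambda = lambda, statistic = f_stat, df1 = df1, df2 = df2, p = p_f,
    chisq = chisq, df_chisq = df_chi,
    p_bartlett = stats::pchisq(chisq, df_chi, lower.tail = FALSE),
    n = n, n_classes = G
  )
}

#' Chi-square test of genotype counts against a Mendelian ratio
#'
#' Pearson chi-square of the observed usable-class counts against an
#' expected segregation ratio — by default 1:2:1 for three genotype
#' classes and 1:1 for two.
#'
#' @param classing A [genotype_classes()] result with at least 2 usable
#'   classes.
#' @param ratio Expected ratio, recycled against the usable classes in
#'   label order; defaults as above.
#' @return One-row tibble: `statistic`, `df`, `p`, `n`.
#' @export
genotype_count_test <- function(classing, ratio = NULL) {
  stopifnot(inherits(classing, "genotype_classing"))
  cls <- classing$classes[classing$classes$usable, ]
  if (nrow(cls) < 2) {
    rlang::abort("Need at least 2 usable genotype classes for the count test.")
  }
  if (is.null(ratio)) {
    ratio <- if (nrow(cls) == 3) c(1, 2, 1) else rep(1, nrow(cls))
  }
  if (length(ratio) != nrow(cls)) {
    rlang::abort("`ratio` length must match the number of usable classes.")
  }
  if (any(ratio <= 0)) rlang::abort("Expected counts of zero are not allowed.")
  # order heterozygote to the middle for a 1:2:1 ratio
  labs <- cls$label
  het <- grepl("/", labs) &
    vapply(strsplit(labs, "/"), function(a) a[1] != a[2], logical(1))
  if (nrow(cls) == 3 && sum(het) == 1) {
    labs <- c(labs[!het][1], labs[het], labs[!het][2])
    cls <- cls[match(labs, cls$label), ]
  }
  res <- suppressWarnings(
    stats::chisq.test(cls$n, p = ratio / sum(ratio))
  )
  tibble::tibble(
    statistic = unname(res$statistic), df = unname(res$parameter),
    p = res$p.value, n = sum(cls$n)
  )
}
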