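#' Configuration for the synthetic clonal-trial generator
#'
#' Describes a simulated clonal field trial: diploid SNP genotypes drawn
#' under Hardy-Weinberg equilibrium, and Chapman-Richards growth
#' trajectories whose parameters shift multiplicatively with allele dose
#' at effect SNPs. Multiplicative parameter effects make genotype-class
#' trajectories diverge with age — similar early, increasingly separated
#' later — which is exactly the signal the trajectory LR test targets.
#'
#' Defaults emulate a 24-clone poplar trial measured at ages
#' 1, 2, 3, 5, 6, 7, 9, 10 and 11 years (ages 4 and 8 unmeasured), three
#' ramets per clone averaged to clone means, and base trajectories whose
#' 11-year height (~22 m) and DBH (~30 cm) sit inside typical
#' field ranges (height 12-28 m, DBH 19.8-36.3 cm).
#'
#' @param n_clones Number of clones.
#' @param snp_specs Tibble with columns `snp`, `maf` (in (0, 0.5]),
#'   `effect_target` (`"a"`, `"b"`, `"c"` or `"none"`), `effect_size`
#'   (relative parameter shift per alt allele, > -1), `dominance`
#'   (`"additive"`, `"dominant"`, `"recessive"`), and optionally `ref`,
#'   `alt` alleles. Default: one neutral SNP at MAF 0.3.
#' @param base_params Named list of per-trait Chapman-Richards parameter
#'   vectors; defaults `height_m = c(a = 28, b = 0.18, c = 1.6)` (meters),
#'   `dbh_cm = c(a = 33, b = 0.26, c = 1.35)` (centimeters).
#' @param noise_sd Measurement noise standard deviation per ramet.
#' @param noise_type `"relative"` (default; `noise_sd` is a fraction of
#'   the clone's asymptote) or `"absolute"` (trait units).
#' @param ages Measurement ages in years, strictly increasing.
#' @param n_ramets Ramets per clone, averaged to the clone mean.
#' @param seed Integer seed; every output is a pure function of
#'   config + seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 24L,
                       snp_specs = NULL,
                       base_params = list(
                         height_m = c(a = 28, b = 0.18, c = 1.6),
                         dbh_cm = c(a = 33, b = 0.26, c = 1.35)
                       ),
                       noise_sd = 0.02,
                       noise_type = c("relative", "absolute"),
                       ages = c(1, 2, 3, 5, 6, 7, 9, 10, 11),
                       n_ramets = 3L,
                       seed = 1L) {
  noise_type <- rlang::arg_match(noise_type)
  if (is.null(snp_specs)) {
    snp_specs <- tibble::tibble(
      snp = "SNP1", maf = 0.3, effect_target = "none",
      effect_size = 0, dominance = "additive"
    )
  }
  snp_specs <- dplyr::as_tibble(snp_specs)
  needed <- c("snp", "maf", "effect_target", "effect_size", "dominance")
  if (!all(needed %in% names(snp_specs))) {
    rlang::abort(paste0("`snp_specs` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (!all(snp_specs$maf > 0 & snp_specs$maf <= 0.5)) {
    rlang::abort("Every `maf` must lie in (0, 0.5].")
  }
  if (!all(snp_specs$effect_size > -1)) {
    rlang::abort("Every `effect_size` must exceed -1.")
  }
  if (!all(snp_specs$effect_target %in% c("a", "b", "c", "none"))) {
    rlang::abort("`effect_target` must be one of a, b, c, none.")
  }
  if (!all(snp_specs$dominance %in% c("additive", "dominant", "recessive"))) {
    rlang::abort("`dominance` must be additive, dominant or recessive.")
  }
  if (!("ref" %in% names(snp_specs))) snp_specs$ref <- "A"
  if (!("alt" %in% names(snp_specs))) snp_specs$alt <- "G"
  if (is.unsorted(ages, strictly = TRUE)) {
    rlang::abort("`ages` must be strictly increasing.")
  }
  for (tr in names(base_params)) {
    validate_growth_params("richard", base_params[[tr]])
  }
  structure(
    list(n_clones = as.integer(n_clones), snp_specs = snp_specs,
         base_params = base_params, noise_sd = noise_sd,
         noise_type = noise_type, ages = ages,
         n_ramets = as.integer(n_ramets), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a diploid genotype matrix under Hardy-Weinberg equilibrium
#'
#' Per SNP, genotypes are drawn iid with probabilities
#' `(1-q)^2, 2q(1-q), q^2` for ref-hom, het, alt-hom, where `q` is the
#' minor (alt) allele frequency.
#'
#' @param config A [sim_config()].
#' @return A tibble: `clone` plus one `"X/Y"` call column per SNP.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    out <- tibble::tibble(clone = sprintf("clone%02d", seq_len(config$n_clones)))
    for (i in seq_len(nrow(config$snp_specs))) {
      s <- config$snp_specs[i, ]
      q <- s$maf
      gt <- sample(
        c(paste(s$ref, s$ref, sep = "/"), paste(s$ref, s$alt, sep = "/"),
          paste(s$alt, s$alt, sep = "/")),
        config$n_clones, replace = TRUE,
        prob = c((1 - q)^2, 2 * q * (1 - q), q^2)
      )
      out[[s$snp]] <- gt
    }
    out
  })
}

# alt-allele dose after dominance coding, on the multiplicative scale:
# params scale by (1 + effect)^dose
dominance_dose <- function(n_alt, dominance) {
  switch(dominance,
    additive  = n_alt,
    dominant  = as.numeric(n_alt >= 1) * 2,
    recessive = as.numeric(n_alt == 2) * 2
  )
}

# per-clone parameter vectors for one trait given the genotype matrix
clone_params <- function(genotypes, config, trait) {
  base <- validate_growth_params("richard", config$base_params[[trait]])
  specs <- config$snp_specs
  purrr::map(seq_len(nrow(genotypes)), function(i) {
    p <- base
    for (j in seq_len(nrow(specs))) {
      s <- specs[j, ]
      if (s$effect_target == "none" || s$effect_size == 0) next
      call <- genotypes[[s$snp]][i]
      if (is.na(call) || call %in% c("./.", "")) next
      n_alt <- sum(strsplit(call, "/", fixed = TRUE)[[1]] == s$alt)
      dose <- dominance_dose(n_alt, s$dominance)
      p[s$effect_target] <- p[s$effect_target] * (1 + s$effect_size)^dose
    }
    tryCatch(validate_growth_params("richard", p), error = function(e) {
      rlang::abort(paste0("SNP effects push clone ", genotypes$clone[i],
                          " outside admissible parameters: ", conditionMessage(e)))
    })
  })
}

#' Simulate growth trajectories for a genotyped clone set
#'
#' Each clone's Chapman-Richards parameters are the trait's base
#' parameters scaled by `(1 + effect_size)^dose` across effect SNPs (dose
#' = dominance-coded alt-allele count). Each ramet observes the model
#' value plus iid Gaussian noise; ramets are averaged to clone means
#' unless `ramets = TRUE`.
#'
#' @param genotypes A [simulate_genotypes()] tibble.
#' @param config The same [sim_config()].
#' @param ramets Return ramet-level rows (with a `ramet` column) instead
#'   of clone means.
#' @return Long tibble: `clone`, `trait`, `age`, `value` (plus `ramet`).
#' @export
simulate_trajectories <- function(genotypes, config, ramets = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- validate_genotypes(genotypes)
  withr::with_seed(config$seed + 1L, {
    rows <- purrr::map_dfr(names(config$base_params), function(trait) {
      pars <- clone_params(genotypes, config, trait)
      purrr::map_dfr(seq_len(nrow(genotypes)), function(i) {
        mu <- growth_value("richard", pars[[i]], config$ages)
        sd_i <- if (config$noise_type == "relative") {
          config$noise_sd * pars[[i]]["a"]
        } else {
          config$noise_sd
        }
        obs <- matrix(
          stats::rnorm(length(mu) * config$n_ramets, mean = mu, sd = sd_i),
          nrow = length(mu)
        )
        tibble::tibble(
          clone = genotypes$clone[i], trait = trait,
          ramet = rep(seq_len(config$n_ramets), each = length(mu)),
          age = rep(config$ages, config$n_ramets),
          value = as.vector(obs)
        )
      })
    })
    if (!ramets) {
      rows <- dplyr::summarise(rows, value = mean(.data$value),
                               .by = c("clone", "trait", "age"))
    }
    rows
  })
}

#' Canned synthetic datasets for tests and examples
#'
#' Deterministic bundle of small datasets: `null24` (24 clones, one
#' neutral SNP), `effect20` (24 clones, one additive SNP shifting the
#' asymptote by 20% per alt allele), `monomorphic` (a SNP with a single
#' genotype, hence untestable), and `tiny` (6 clones, smoke-test sized).
#' Each element holds `config`, `genotypes` and `phenotypes`. With `dir`
#' set, the genotype/phenotype tables are also written as CSV.
#'
#' @param seed Integer master seed.
#' @param dir Optional directory for CSV output.
#' @return Named list of dataset bundles.
#' @export
make_fixture_suite <- function(seed = 1L, dir = NULL) {
  mk <- function(cfg) {
    g <- simulate_genotypes(cfg)
    list(config = cfg, genotypes = g, phenotypes = simulate_trajectories(g, cfg))
  }
  suite <- list(
    null24 = mk(sim_config(seed = seed)),
    effect20 = mk(sim_config(
      snp_specs = tibble::tibble(
        snp = "SNP1", maf = 0.45, effect_target = "a",
        effect_size = 0.2, dominance = "additive"
      ),
      seed = seed + 1L
    )),
    monomorphic = mk(sim_config(
      snp_specs = tibble::tibble(
        snp = "SNP1", maf = 1e-9, effect_target = "none",
        effect_size = 0, dominance = "additive"
      ),
      seed = seed + 2L
    )),
    tiny = mk(sim_config(n_clones = 6L, seed = seed + 3L))
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(suite)) {
      readr::write_csv(suite[[nm]]$genotypes,
                       file.path(dir, paste0(nm, "_genotypes.csv")))
      readr::write_csv(suite[[nm]]$phenotypes,
                       file.path(dir, paste0(nm, "_phenotypes.csv")))
    }
  }
  suite
}
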