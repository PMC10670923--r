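#' Read and validate a long-format phenotype table
#'
#' Expects a CSV with header `clone,trait,age,value` (an optional `ramet`
#' column is kept when present). Ages may skip years — schedule gaps are
#' data, not schema. Duplicate `(clone, trait, age)` rows (or
#' `(clone, trait, ramet, age)` when ramet-level) are an error; schema
#' violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  validate_phenotypes(tab)
}

validate_phenotypes <- function(tab) {
  if (!is.data.frame(tab)) rlang::abort("Phenotypes must be a data frame.")
  tab <- dplyr::as_tibble(tab)
  needed <- c("clone", "trait", "age", "value")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    rlang::abort(paste0("Phenotype table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (nrow(tab) == 0) rlang::abort("Phenotype table is empty.")
  bad_age <- which(!is.finite(tab$age) | tab$age < 0)
  if (length(bad_age)) {
    rlang::abort(paste0("Non-finite or negative ages at row(s): ",
                        paste(utils::head(bad_age, 5), collapse = ", ")))
  }
  bad_val <- which(!is.finite(tab$value))
  if (length(bad_val)) {
    rlang::abort(paste0("Non-finite values at row(s): ",
                        paste(utils::head(bad_val, 5), collapse = ", ")))
  }
  keys <- c("clone", "trait", if ("ramet" %in% names(tab)) "ramet", "age")
  dup <- which(duplicated(tab[keys]))
  if (length(dup)) {
    rlang::abort(paste0("Duplicate (", paste(keys, collapse = ", "),
                        ") at row(s): ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  tab
}

#' Read a genotype matrix from CSV or minimal VCF
#'
#' CSV: rows are clones (first column `clone`), one column per SNP with
#' diploid calls `"A/G"`, missing `"./."`. VCF (`.vcf`): only the GT
#' field is consumed; `0/1` codes are mapped through the declared REF/ALT
#' alleles (requires the vcfR package).
#'
#' @param path File path (`.csv` or `.vcf`).
#' @return A tibble: `clone` plus one call column per SNP.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      rlang::abort("Reading VCF requires the vcfR package.")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- vcfR::getFIX(v)
    snp_ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                      paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"])
    decode <- function(code, ref, alt) {
      if (is.na(code)) return(NA_character_)
      idx <- strsplit(gsub("\\|", "/", code), "/", fixed = FALSE)[[1]]
      if (length(idx) != 2 || any(idx == ".")) return(NA_character_)
      al <- c(ref, alt)[as.integer(idx) + 1L]
      paste(sort(al), collapse = "/")
    }
    out <- tibble::tibble(clone = colnames(gt))
    for (i in seq_len(nrow(gt))) {
      out[[snp_ids[i]]] <- unname(vapply(
        gt[i, ], decode, character(1),
        ref = fix[i, "REF"], alt = fix[i, "ALT"]
      ))
    }
    return(validate_genotypes(out))
  }
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_genotypes(tab)
}

#' Descriptive statistics of a phenotype table
#'
#' Per year and trait: mean, min, max; a one-way ANOVA across clones
#' (ramet-level replication required — with clone means only there is no
#' within-clone replicate and the ANOVA is skipped with a warning); and
#' the Pearson correlation of each year's values with the final year.
#'
#' @param pheno Long phenotype table (optionally with a `ramet` column).
#' @return List of tibbles: `summary`, `anova`, `correlations`.
#' @export
descriptives <- function(pheno) {
  pheno <- validate_phenotypes(pheno)
  if (length(unique(pheno$clone)) < 2 || length(unique(pheno$age)) < 2) {
    rlang::abort("Descriptives need at least 2 clones and 2 ages.")
  }
  summ <- pheno |>
    dplyr::summarise(
      mean = mean(.data$value), min = min(.data$value), max = max(.data$value),
      n = dplyr::n(), .by = c("trait", "age")
    ) |>
    dplyr::arrange(.data$trait, .data$age)

  has_ramets <- "ramet" %in% names(pheno) &&
    any(dplyr::count(pheno, .data$clone, .data$trait, .data$age)$n > 1)
  anova_tab <- if (has_ramets) {
    pheno |>
      dplyr::group_by(.data$trait, .data$age) |>
      dplyr::group_modify(function(d, key) {
        an <- stats::anova(stats::lm(value ~ factor(clone), data = d))
        tibble::tibble(statistic = an$`F value`[1], df1 = an$Df[1],
                       df2 = an$Df[2], p = an$`Pr(>F)`[1])
      }) |>
      dplyr::ungroup()
  } else {
    rlang::warn("Single observation per clone-year: clone ANOVA skipped.")
    tibble::tibble(trait = character(), age = numeric(), statistic = numeric(),
                   df1 = integer(), df2 = integer(), p = numeric())
  }

  means <- pheno |>
    dplyr::summarise(value = mean(.data$value), .by = c("clone", "trait", "age"))
  cors <- means |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(d, key) {
      final <- max(d$age)
      ref <- d[d$age == final, c("clone", "value")]
      purrr::map_dfr(sort(unique(d$age)), function(a) {
        cur <- d[d$age == a, c("clone", "value")]
        j <- dplyr::inner_join(cur, ref, by = "clone", suffix = c("", "_final"))
        ct <- stats::cor.test(j$value, j$value_final)
        tibble::tibble(age = a, final_age = final, r = unname(ct$estimate),
                       p = ct$p.value, n = nrow(j))
      })
    }) |>
    dplyr::ungroup()

  list(summary = summ, anova = anova_tab, correlations = cors)
}

#' Pipeline run configuration
#'
#' @param phenotypes,genotypes File paths (CSV; genotypes may be VCF) or
#'   in-memory data frames.
#' @param traits Traits to analyze; default all in the phenotype table.
#' @param models Candidate growth laws.
#' @param min_class_size Smallest genotype class admitted to testing.
#' @param merge_threshold Normalized L2 distance below which genotype
#'   classes with near-identical trajectories are merged; 0 disables.
#' @param sigma,count_sigma_df LR-test residual-variance convention and
#'   df rule; see [lr_trajectory_test()].
#' @param normalize Curvature mode for staging; see [max_curvature_point()].
#' @param alpha Significance level.
#' @param correction `"none"` (raw p-values, default) or `"BH"`
#'   (Benjamini-Hochberg across SNPs per trait).
#' @param seed Integer seed.
#' @param out_dir Output directory for CSV reports and the run manifest;
#'   `NULL` suppresses writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(phenotypes, genotypes = NULL, traits = NULL,
                       models = growth_model_ids(), min_class_size = 3L,
                       merge_threshold = 0, sigma = "shared",
                       count_sigma_df = FALSE, normalize = "raw",
                       alpha = 0.05, correction = c("none", "BH"),
                       seed = 1L, out_dir = NULL) {
  correction <- rlang::arg_match(correction)
  stopifnot(alpha > 0, alpha < 1)
  for (x in list(phenotypes, genotypes)) {
    if (is.character(x) && !is.null(x) && !file.exists(x)) {
      rlang::abort(paste0("File not found: ", x))
    }
  }
  structure(
    list(phenotypes = phenotypes, genotypes = genotypes, traits = traits,
         models = models, min_class_size = as.integer(min_class_size),
         merge_threshold = merge_threshold, sigma = sigma,
         count_sigma_df = count_sigma_df, normalize = normalize,
         alpha = alpha, correction = correction, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full trajectory-mapping pipeline
#'
#' Stages, in order: descriptive statistics; per-clone growth-curve fits
#' for every candidate law; model selection per trait; per-SNP trajectory
#' LR tests (with optional class merging), genotype-count tests and MAF;
#' per-year GLM association; multivariate association of the fitted
#' parameters; and maximum-curvature staging per genotype class of each
#' tested SNP. A stage failure is recorded in the manifest and dependent
#' stages are skipped; independent stages continue. With `out_dir` set,
#' every table is written as CSV together with a JSON run manifest
#' (config hash, package version, seed, per-stage status).
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with elements
#'   `descriptives`, `fits`, `selection` (per trait), `winner`,
#'   `qtl` (per SNP x trait tibble), `per_year`, `param_assoc`,
#'   `staging`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pheno <- if (is.character(config$phenotypes)) {
    read_phenotypes(config$phenotypes)
  } else {
    validate_phenotypes(config$phenotypes)
  }
  geno <- if (is.null(config$genotypes)) NULL else if (is.character(config$genotypes)) {
    read_genotypes(config$genotypes)
  } else {
    validate_genotypes(config$genotypes)
  }
  traits <- config$traits %||% sort(unique(pheno$trait))
  manifest <- list(
    package = "trajqtl",
    version = as.character(utils::packageVersion("trajqtl")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    units = list(age = "years from planting", height = "m",
                 dbh = "cm at 1.3 m"),
    stages = list()
  )
  note <- function(stage, status, detail = "") {
    manifest$stages[[stage]] <<- list(status = status, detail = detail)
  }
  try_stage <- function(stage, expr) {
    tryCatch({ v <- expr; note(stage, "ok"); v },
             error = function(e) { note(stage, "failed", conditionMessage(e)); NULL })
  }

  clone_means <- pheno |>
    dplyr::summarise(value = mean(.data$value), .by = c("clone", "trait", "age"))

  desc <- try_stage("descriptives", suppressWarnings(descriptives(pheno)))
  fits <- try_stage("fits", fit_growth_curves(clone_means, config$models,
                                              seed = config$seed))
  selection <- NULL; winner <- NULL
  if (!is.null(fits)) {
    selection <- try_stage("model_selection", {
      sel <- purrr::map(
        rlang::set_names(traits),
        function(tr) compare_growth_models(fits[fits$trait == tr, ],
                                           alpha = config$alpha)
      )
      sel
    })
    if (!is.null(selection)) {
      winners <- purrr::map_chr(selection, "winner")
      # one law for all traits: the winner common to, or most frequent over, traits
      winner <- names(sort(table(winners), decreasing = TRUE))[1]
      note("winner", "ok", winner)
    }
  }

  qtl <- per_year <- param_assoc <- staging <- NULL
  if (!is.null(geno) && !is.null(winner)) {
    snps <- setdiff(names(geno), "clone")
    maf_tab <- try_stage("maf", snp_maf(geno))
    qtl_rows <- list(); py_rows <- list(); pa_rows <- list(); st_rows <- list()
    for (s in snps) {
      cl <- suppressMessages(genotype_classes(geno, s, config$min_class_size))
      for (tr in traits) {
        cl_tr <- cl
        if (config$merge_threshold > 0 && cl$testable) {
          cl_tr <- merge_similar_classes(cl, clone_means, tr, winner,
                                         threshold = config$merge_threshold,
                                         seed = config$seed)
        }
        if (!cl_tr$testable) {
          qtl_rows[[paste(s, tr)]] <- tibble::tibble(
            snp = s, trait = tr, model = winner, n_classes = sum(cl_tr$classes$usable),
            logL0 = NA_real_, logL1 = NA_real_, lr = NA_real_, df = NA_integer_,
            p = NA_real_, converged = NA, testable = FALSE
          )
          next
        }
        lt <- lr_trajectory_test(clone_means, cl_tr, tr, winner,
                                 sigma = config$sigma,
                                 count_sigma_df = config$count_sigma_df,
                                 seed = config$seed)
        qtl_rows[[paste(s, tr)]] <- dplyr::mutate(glance(lt), testable = TRUE)
        py <- tryCatch(
          dplyr::mutate(per_year_glm(clone_means, cl_tr, tr), snp = s, trait = tr,
                        .before = 1),
          error = function(e) NULL
        )
        if (!is.null(py)) py_rows[[paste(s, tr)]] <- py
        # per-clone fitted parameter vectors feed the multivariate association
        clone_par <- dplyr::select(
          fits[fits$trait == tr & fits$model == winner, ],
          "clone", dplyr::all_of(growth_param_names(winner))
        )
        pa <- tryCatch(
          dplyr::mutate(param_association(clone_par, cl_tr), snp = s, trait = tr,
                        .before = 1),
          error = function(e) NULL
        )
        if (!is.null(pa)) pa_rows[[paste(s, tr)]] <- pa
        st <- tryCatch(
          dplyr::mutate(
            suppressWarnings(phase_report(lt$class_fits,
                                          normalize = config$normalize)),
            snp = s, trait = tr, .before = 1),
          error = function(e) NULL
        )
        if (!is.null(st)) st_rows[[paste(s, tr)]] <- st
      }
    }
    qtl <- dplyr::bind_rows(qtl_rows)
    if (!is.null(qtl) && nrow(qtl) && config$correction == "BH") {
      qtl <- dplyr::mutate(qtl, p_adj = stats::p.adjust(.data$p, "BH"),
                           .by = "trait")
    }
    if (!is.null(maf_tab) && !is.null(qtl) && nrow(qtl)) {
      qtl <- dplyr::left_join(qtl, maf_tab[c("snp", "maf")], by = "snp")
    }
    per_year <- dplyr::bind_rows(py_rows)
    param_assoc <- dplyr::bind_rows(pa_rows)
    staging <- dplyr::bind_rows(st_rows)
    note("qtl", "ok", sprintf("%d SNP x trait tests", nrow(qtl %||% tibble::tibble())))
  } else if (is.null(geno)) {
    note("qtl", "skipped", "no genotypes supplied")
  } else {
    note("qtl", "skipped", "model selection failed upstream")
  }

  result <- structure(
    list(descriptives = desc, fits = fits, selection = selection,
         winner = winner, qtl = qtl, per_year = per_year,
         param_assoc = param_assoc, staging = staging, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_reports(result, config$out_dir)
  result
}

write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && nrow(x)) readr::write_csv(x, file.path(out_dir, name))
  }
  if (!is.null(result$descriptives)) {
    wr(result$descriptives$summary, "descriptives_summary.csv")
    wr(result$descriptives$anova, "descriptives_anova.csv")
    wr(result$descriptives$correlations, "descriptives_correlations.csv")
  }
  if (!is.null(result$fits)) {
    wr(dplyr::select(result$fits, -"fit"), "fits.csv")
  }
  if (!is.null(result$selection)) {
    wr(purrr::map_dfr(result$selection, tidy, .id = "trait"), "model_selection_tests.csv")
    wr(purrr::map_dfr(result$selection, glance), "model_selection_winners.csv")
  }
  wr(result$qtl, "qtl_lr_tests.csv")
  wr(result$per_year, "per_year_glm.csv")
  wr(result$param_assoc, "param_association.csv")
  wr(result$staging, "staging.csv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  winner:", x$winner %||% "(model selection not run)", "\n")
  if (!is.null(x$qtl)) {
    sig <- sum(x$qtl$p < 0.05, na.rm = TRUE)
    cat(sprintf("  qtl: %d SNP x trait tests, %d with p < 0.05\n", nrow(x$qtl), sig))
  }
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  stage %-16s %s\n", s, x$manifest$stages[[s]]$status))
  }
  invisible(x)
}
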