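pipeline_log <- function(path, stage, params, seed) {
  lines <- c(
    sprintf("pipeline: %s", stage),
    sprintf("package: clutchvis %s",
            as.character(utils::packageVersion("clutchvis"))),
    sprintf("seed: %s", seed),
    sprintf("config_hash: %s", rlang::hash(params)),
    "parameters:",
    vapply(names(params), function(nm) {
      sprintf("  %s: %s", nm, paste(format(params[[nm]]), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run the egg-colour visual-modelling pipeline end to end
#'
#' read -> average replicates -> regrid -> triangular smooth -> quantum
#' catches -> proportional catches -> pairwise JNDs -> disjoint random
#' pairing -> Welch tests, writing the report artifacts to `out_dir`:
#' `clutch_variation_report.tsv`, `quantum_catches.tsv`, `jnd_pairs.tsv`,
#' `egg_manifest.tsv` and a deterministic `run_log.txt` carrying the seed,
#' parameters and a config hash.
#'
#' @param out_dir Output directory (created if missing).
#' @param spectra Raw replicate spectra: a long tibble, a path to a wide
#'   delimited file, or `NULL` to simulate the default synthetic data set
#'   under `seed`.
#' @param receptors A [receptor_set()], or `NULL` for the built-in
#'   template sensitivities and default noise parameters.
#' @param light Illuminant tibble, or `NULL` for the flat preset.
#' @param grid Working wavelength grid.
#' @param smooth_width Triangular smoothing base width in nm (default 30).
#' @param seed Integer seed for simulation and the random pairing.
#'
#' @return Invisibly, a list with the report tibble, catches, JND pairs
#'   and the file paths written.
#' @export
run_color_pipeline <- function(out_dir, spectra = NULL, receptors = NULL,
                               light = NULL, grid = wl_grid(),
                               smooth_width = 30, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(grid = range(as.numeric(grid)), step = median(diff(as.numeric(grid))),
                 smooth_width = smooth_width, seed = seed,
                 simulated = is.null(spectra))
  if (is.null(spectra)) {
    spectra <- simulate_egg_spectra(grid = grid, seed = seed)
  } else if (is.character(spectra)) {
    spectra <- read_spectra(spectra, dialect = "wide", kind = "reflectance")
  }
  if (is.null(receptors)) {
    receptors <- receptor_set(simulate_sensitivities(grid = grid))
  }
  if (is.null(light)) light <- illuminant_flat(grid)

  averaged <- average_replicates(spectra)
  averaged <- regrid_spectra(averaged, grid)
  smoothed <- smooth_triangular(averaged, width = smooth_width)
  catches <- quantum_catch(smoothed, receptors, light)
  pairs <- pairwise_jnds(catches, receptors)
  report <- clutch_variation_report(smoothed, receptors, light, seed = seed)

  paths <- c(
    report = file.path(out_dir, "clutch_variation_report.tsv"),
    catches = file.path(out_dir, "quantum_catches.tsv"),
    jnd = file.path(out_dir, "jnd_pairs.tsv"),
    manifest = file.path(out_dir, "egg_manifest.tsv"),
    log = file.path(out_dir, "run_log.txt")
  )
  readr::write_tsv(tibble::as_tibble(report), paths[["report"]], progress = FALSE)
  readr::write_tsv(catches, paths[["catches"]], progress = FALSE)
  readr::write_tsv(pairs, paths[["jnd"]], progress = FALSE)
  readr::write_tsv(spectra_manifest(averaged), paths[["manifest"]],
                   progress = FALSE)
  pipeline_log(paths[["log"]], "color", params, seed)
  invisible(list(report = report, catches = catches, pairs = pairs,
                 paths = paths))
}

#' Run the egg-rejection analysis pipeline end to end
#'
#' tabulate -> exact and Monte-Carlo Fisher tests (three-arm table and the
#' IV-vs-DV two-arm table) -> Cramér's V -> chi-square power at the
#' observed sample size -> required sample size at the target power ->
#' binomial logistic regression. Writes `contingency.tsv`,
#' `fisher_report.tsv`, `power_report.tsv`, `glm_coefficients.tsv` and a
#' deterministic `run_log.txt` to `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param records Outcome tibble, a path to a delimited outcome file, or
#'   `NULL` to simulate the default synthetic experiment under `seed`.
#' @param replicates Monte-Carlo Fisher replicates (default 2000).
#' @param alpha Significance level for the power analysis (default 0.05).
#' @param target_power Target power for the sample-size solve (default
#'   0.8).
#' @param seed Integer seed for simulation and the Monte-Carlo test.
#'
#' @return Invisibly, a list with the contingency table, Fisher results,
#'   power report, the GLM fit and the file paths written.
#' @export
run_rejection_pipeline <- function(out_dir, records = NULL,
                                   replicates = 2000, alpha = 0.05,
                                   target_power = 0.8, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(replicates = replicates, alpha = alpha,
                 target_power = target_power, seed = seed,
                 simulated = is.null(records))
  if (is.null(records)) {
    records <- simulate_outcomes(seed = seed)
  } else if (is.character(records)) {
    records <- read_outcomes(records)
  }
  validate_outcomes(records)
  present <- intersect(TREATMENT_LEVELS, unique(as.character(records$treatment)))
  if (length(present) < 2) {
    abort(paste0("Need at least two treatment arms; missing level(s): ",
                 paste(setdiff(TREATMENT_LEVELS, present), collapse = ", ")))
  }
  tab <- tabulate_outcomes(records)
  tab_used <- tab[rowSums(tab) > 0, , drop = FALSE]
  f_exact <- fisher_exact_test(tab_used)
  f_mc <- fisher_mc_test(tab_used, replicates = replicates, seed = seed)
  two <- tab[c("IV", "DV"), , drop = FALSE]
  f2_exact <- if (all(rowSums(two) > 0)) fisher_exact_test(two) else NULL
  f2_mc <- if (all(rowSums(two) > 0)) {
    fisher_mc_test(two, replicates = replicates, seed = seed)
  } else NULL
  eff <- cramers_v(tab_used)
  eff$alpha <- alpha
  eff$power <- chisq_power(eff$w, eff$N, eff$df, alpha)
  need <- required_n(eff$w, power = target_power, df = eff$df, alpha = alpha)
  fit <- fit_rejection_glm(records)

  fisher_tbl <- tibble::tibble(
    comparison = c("IV/DV/UNM", if (!is.null(f2_exact)) "IV vs DV"),
    p_exact = c(f_exact$p_exact, if (!is.null(f2_exact)) f2_exact$p_exact),
    p_mc = c(f_mc$p_mc, if (!is.null(f2_mc)) f2_mc$p_mc),
    replicates = replicates
  )
  power_tbl <- tibble::tibble(
    chi2 = eff$chi2, V = eff$V, w = eff$w, df = eff$df, N = eff$N,
    alpha = alpha, power = eff$power,
    target_power = target_power,
    required_n_exact = need$n_exact, required_n = need$n
  )
  paths <- c(
    contingency = file.path(out_dir, "contingency.tsv"),
    fisher = file.path(out_dir, "fisher_report.tsv"),
    power = file.path(out_dir, "power_report.tsv"),
    glm = file.path(out_dir, "glm_coefficients.tsv"),
    log = file.path(out_dir, "run_log.txt")
  )
  cont_tbl <- tibble::as_tibble(as.data.frame.matrix(tab),
                                rownames = "treatment")
  readr::write_tsv(cont_tbl, paths[["contingency"]], progress = FALSE)
  readr::write_tsv(fisher_tbl, paths[["fisher"]], progress = FALSE)
  readr::write_tsv(power_tbl, paths[["power"]], progress = FALSE)
  if (fit$converged) {
    readr::write_tsv(tidy(fit), paths[["glm"]], progress = FALSE)
  } else {
    readr::write_tsv(tibble::tibble(note = "model did not converge"),
                     paths[["glm"]], progress = FALSE)
  }
  pipeline_log(paths[["log"]], "rejection", params, seed)
  invisible(list(table = tab, fisher = fisher_tbl, power = power_tbl,
                 fit = fit, paths = paths))
}
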