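TREATMENT_LEVELS <- c("IV", "DV", "UNM")
OUTCOME_LEVELS <- c("reject", "accept")

validate_outcomes <- function(records) {
  need <- c("nest_id", "treatment", "outcome")
  if (!all(need %in% names(records))) {
    abort("Outcome records need columns nest_id, treatment, outcome.")
  }
  bad_t <- setdiff(unique(as.character(records$treatment)), TREATMENT_LEVELS)
  if (length(bad_t) > 0) {
    abort(paste0("Unknown treatment level(s): ", paste(bad_t, collapse = ", ")))
  }
  bad_o <- setdiff(unique(as.character(records$outcome)), OUTCOME_LEVELS)
  if (length(bad_o) > 0) {
    abort(paste0("Unknown outcome level(s): ", paste(bad_o, collapse = ", ")))
  }
  if ("stage" %in% names(records)) {
    bad_s <- setdiff(unique(as.character(records$stage)),
                     c("laying", "incubation"))
    if (length(bad_s) > 0) {
      abort(paste0("Unknown stage level(s): ", paste(bad_s, collapse = ", ")))
    }
  }
  invisible(records)
}

#' Cross-tabulate rejection outcomes by treatment
#'
#' Collapses nest-level records to a treatment x outcome contingency table
#' in fixed label order: rows `IV, DV, UNM` (increased variation, decreased
#' variation, unmanipulated control), columns `reject, accept`. Empty
#' levels are retained as zero rows.
#'
#' @param records Tibble of nest records with at least `nest_id`,
#'   `treatment`, `outcome`.
#'
#' @return An integer matrix with treatment rows and outcome columns.
#' @export
tabulate_outcomes <- function(records) {
  if (nrow(records) == 0) abort("No records to tabulate.")
  validate_outcomes(records)
  t_f <- factor(as.character(records$treatment), levels = TREATMENT_LEVELS)
  o_f <- factor(as.character(records$outcome), levels = OUTCOME_LEVELS)
  tab <- table(treatment = t_f, outcome = o_f)
  m <- matrix(as.integer(tab), nrow = length(TREATMENT_LEVELS),
              dimnames = dimnames(tab))
  m
}

# log-probability of a margin-fixed r x c table under the multivariate
# hypergeometric (all column-label permutations equally likely)
log_table_prob <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
    sum(lgamma(tab + 1))
}

#' Fisher's exact test of a contingency table
#'
#' Two-sided exact test by the probability-ordering rule: the p-value sums
#' the probabilities, under fixed margins, of every table no more probable
#' than the one observed.
#'
#' @param tab Contingency table (matrix of non-negative counts).
#'
#' @return An object of class `"fisher_result"` with `p_exact`; see also
#'   [fisher_mc_test()].
#' @export
#'
#' @examples
#' fisher_exact_test(matrix(c(3, 0, 0, 3), 2))$p_exact
fisher_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) abort("Empty table.")
  if (sum(tab) > 500) {
    abort("Table too large for exact enumeration; use fisher_mc_test().")
  }
  ft <- fisher.test(tab)
  structure(
    list(p_exact = unname(ft$p.value), p_mc = NULL, replicates = NULL,
         seed = NULL, table = tab),
    class = "fisher_result"
  )
}

#' Monte-Carlo Fisher test of a contingency table
#'
#' Samples margin-fixed tables (equivalent to uniformly permuting column
#' labels against row labels) and estimates the two-sided probability-
#' ordering p-value as `(1 + B) / (replicates + 1)`, where `B` counts
#' simulated tables no more probable than the observed one. Never returns
#' exactly zero; deterministic given `seed`.
#'
#' @param tab Contingency table (matrix of non-negative counts).
#' @param replicates Number of simulated tables (default 2000).
#' @param seed Optional integer seed.
#'
#' @return An object of class `"fisher_result"` with `p_mc`, `replicates`
#'   and `seed` recorded.
#' @export
fisher_mc_test <- function(tab, replicates = 2000, seed = NULL) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) abort("Empty table.")
  if (replicates < 1) abort("`replicates` must be at least 1.")
  obs <- log_table_prob(tab)
  with_seed(seed, {
    sims <- r2dtable(replicates, rowSums(tab), colSums(tab))
    lp <- vapply(sims, log_table_prob, numeric(1))
    b <- sum(lp <= obs + 1e-10)
    structure(
      list(p_exact = NULL, p_mc = (1 + b) / (replicates + 1),
           replicates = as.integer(replicates),
           seed = if (is.null(seed)) NA_integer_ else seed, table = tab),
      class = "fisher_result"
    )
  })
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("<fisher_result>\n")
  if (!is.null(x$p_exact)) cat(sprintf("  exact p = %.4g\n", x$p_exact))
  if (!is.null(x$p_mc)) {
    cat(sprintf("  Monte-Carlo p = %.4g (%d replicates)\n",
                x$p_mc, x$replicates))
  }
  invisible(x)
}

#' @rdname fisher_exact_test
#' @param x A `fisher_result`.
#' @param ... Unused.
#' @export
tidy.fisher_result <- function(x, ...) {
  tibble::tibble(
    p_exact = if (is.null(x$p_exact)) NA_real_ else x$p_exact,
    p_mc = if (is.null(x$p_mc)) NA_real_ else x$p_mc,
    replicates = if (is.null(x$replicates)) NA_integer_ else x$replicates
  )
}

#' Cramér's V and the chi-square effect size of a table
#'
#' Pearson's chi-square (no continuity correction) with
#' `V = sqrt(chi2 / (N * (min(r, c) - 1)))`; for a two-column table the
#' chi-square effect size `w` equals `V`. Zero-margin rows or columns are
#' dropped with a warning.
#'
#' @param tab Contingency table (matrix of non-negative counts).
#'
#' @return An object of class `"effect_power"` with `chi2`, `V`, `w`,
#'   `df`, `N` (and `alpha`/`power` slots filled by [chisq_power()]).
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  drop_r <- rowSums(tab) == 0
  drop_c <- colSums(tab) == 0
  if (any(drop_r) || any(drop_c)) {
    warn("Dropping zero-margin rows/columns before computing Cramér's V.")
    tab <- tab[!drop_r, !drop_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("Need at least a 2x2 table.")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1)))
  structure(
    list(chi2 = chi2, V = v, w = if (ncol(tab) == 2) v else sqrt(chi2 / n),
         df = (nrow(tab) - 1) * (ncol(tab) - 1), N = n,
         alpha = NA_real_, power = NA_real_),
    class = "effect_power"
  )
}

#' @export
print.effect_power <- function(x, ...) {
  cat(sprintf("<effect_power> chi2 = %.3f, V = %.3f, w = %.3f, df = %d, N = %d",
              x$chi2, x$V, x$w, x$df, x$N))
  if (!is.na(x$power)) cat(sprintf(", power = %.3f (alpha %.2g)", x$power, x$alpha))
  cat("\n")
  invisible(x)
}

#' @rdname cramers_v
#' @param x An `effect_power` object.
#' @param ... Unused.
#' @export
tidy.effect_power <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, V = x$V, w = x$w, df = x$df, N = x$N,
                 alpha = x$alpha, power = x$power)
}

#' Power of the chi-square test at a given effect size
#'
#' `power = P[X > q]` with `X ~` noncentral chi-square with `df` degrees of
#' freedom and noncentrality `N * w^2`, and `q` the `1 - alpha` quantile of
#' the central chi-square. At `w = 0` this returns `alpha` exactly.
#'
#' @param w Chi-square effect size (Cramér's V for a two-column table).
#' @param n Total sample size.
#' @param df Degrees of freedom of the test (2 for a 3x2 design).
#' @param alpha Significance level (default 0.05).
#'
#' @return The power, a probability.
#' @export
#'
#' @examples
#' chisq_power(0.16, 45, df = 2)
chisq_power <- function(w, n, df, alpha = 0.05) {
  if (w < 0) abort("`w` must be non-negative.")
  if (n < 1) abort("`n` must be at least 1.")
  if (w == 0) return(alpha)  # central null: power is alpha by definition
  q <- qchisq(1 - alpha, df)
  pchisq(q, df, ncp = n * w^2, lower.tail = FALSE)
}

#' Sample size needed for a target chi-square power
#'
#' Root-solves the continuous relaxation of [chisq_power()] in `n`.
#'
#' @param w Effect size (> 0).
#' @param power Target power in (0, 1), default 0.8.
#' @param df Degrees of freedom.
#' @param alpha Significance level.
#'
#' @return A list with `n_exact` (continuous solution) and `n` (rounded
#'   up to the next whole observation).
#' @export
#'
#' @examples
#' required_n(0.16, 0.8, df = 2)
required_n <- function(w, power = 0.8, df, alpha = 0.05) {
  if (!(power > 0 && power < 1)) abort("`power` must be in (0, 1).")
  if (w <= 0) {
    abort("Effect size 0 cannot attain power above alpha.")
  }
  f <- function(n) chisq_power(w, n, df, alpha) - power
  upper <- 10
  while (f(upper) < 0 && upper < 1e9) upper <- upper * 10
  root <- uniroot(f, c(1, upper), tol = 1e-8)$root
  list(n_exact = root, n = ceiling(root))
}

#' Binomial logistic regression of egg rejection
#'
#' Fits `reject(1) / accept(0)` on treatment (reference level `DV`, so the
#' reported contrasts are IV and the unmanipulated control), nesting stage
#' (laying = 0, incubation = 1), Julian date, clutch size, and year as a
#' nominal fixed effect. Fitting is by iteratively reweighted least
#' squares (relative deviance change below 1e-8, at most 100 iterations).
#' A year term with a single observed level is dropped automatically.
#'
#' @param records Outcome tibble with columns `nest_id`, `treatment`,
#'   `outcome`, `julian_date`, `stage`, `clutch_size`, `year`.
#' @param terms Character vector of predictors to include; default all of
#'   `treatment`, `stage`, `julian_date`, `clutch_size`, `year`.
#'
#' @return An object of class `"rejection_glm"` wrapping the [stats::glm()]
#'   fit, with [tidy()] and [glance()] methods. If the fit does not
#'   converge or shows signs of complete separation, coefficients are
#'   withheld and the `converged` flag is `FALSE`.
#' @export
fit_rejection_glm <- function(records,
                              terms = c("treatment", "stage", "julian_date",
                                        "clutch_size", "year")) {
  validate_outcomes(records)
  miss <- setdiff(terms, names(records))
  if (length(miss) > 0) {
    abort(paste0("Missing model columns: ", paste(miss, collapse = ", ")))
  }
  d <- tibble::as_tibble(records)
  d$reject <- as.integer(as.character(d$outcome) == "reject")
  if ("treatment" %in% terms) {
    d$treatment <- relevel(factor(as.character(d$treatment),
                                  levels = TREATMENT_LEVELS), ref = "DV")
  }
  if ("stage" %in% terms) {
    d$stage <- as.integer(as.character(d$stage) == "incubation")
  }
  if ("year" %in% terms) {
    d$year <- factor(as.character(d$year))
    if (nlevels(d$year) < 2) terms <- setdiff(terms, "year")
  }
  fml <- as.formula(paste("reject ~", paste(terms, collapse = " + ")))
  fit <- glm(fml, family = binomial(), data = d,
             control = glm.control(epsilon = 1e-8, maxit = 100))
  # huge SEs flag quasi-complete separation
  separated <- any(sqrt(diag(vcov(fit))) > 50)
  structure(
    list(fit = fit, converged = fit$converged && !separated,
         separated = separated, n = nrow(d), terms = terms),
    class = "rejection_glm"
  )
}

#' @export
print.rejection_glm <- function(x, ...) {
  cat(sprintf("<rejection_glm> n = %d, terms: %s\n", x$n,
              paste(x$terms, collapse = " + ")))
  if (!x$converged) {
    cat("  fit did not converge (or separation detected); coefficients withheld\n")
  } else {
    print(tidy(x))
  }
  invisible(x)
}

#' @rdname fit_rejection_glm
#' @param x A `rejection_glm` object.
#' @param ... Unused.
#' @export
tidy.rejection_glm <- function(x, ...) {
  if (!x$converged) {
    abort("Model did not converge (or separation detected); coefficients withheld.")
  }
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @rdname fit_rejection_glm
#' @export
glance.rejection_glm <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    deviance = x$fit$deviance,
    null.deviance = x$fit$null.deviance,
    AIC = x$fit$aic,
    iterations = x$fit$iter,
    converged = x$converged
  )
}

#' Read a behavioural outcome table
#'
#' @param path Delimited text (TSV/CSV) with header columns `nest_id`,
#'   `treatment`, `outcome`, and optionally `julian_date`, `stage`,
#'   `clutch_size`, `year`.
#' @return A validated tibble of outcome records.
#' @export
read_outcomes <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_outcomes(out)
  tibble::as_tibble(out)
}

#' Plot rejection rates by treatment arm
#'
#' @param records Outcome tibble.
#' @return A ggplot of per-arm rejection proportions with binomial
#'   standard-error bars and sample sizes printed inside the bars.
#' @export
plot_rejection_rates <- function(records) {
  validate_outcomes(records)
  d <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(records), .data$treatment),
    n = dplyr::n(),
    p = mean(as.character(.data$outcome) == "reject"),
    .groups = "drop"
  )
  d$se <- sqrt(d$p * (1 - d$p) / d$n)
  d$treatment <- factor(d$treatment, levels = TREATMENT_LEVELS)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment, y = .data$p)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$p, ymax = pmin(1, .data$p + .data$se)),
      width = 0.15) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n, y = .data$p / 2)) +
    ggplot2::labs(x = "treatment", y = "proportion rejected") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
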