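#' Proportional quantum catches
#'
#' Normalises each egg's four single-cone catches to sum to one, giving the
#' proportion of total receptor catch attributable to each photoreceptor
#' class. The achromatic catch is excluded from the normalisation.
#'
#' @param catches Tibble from [quantum_catch()].
#'
#' @return A tibble with `egg_id` (and `clutch_id` if present) and
#'   `Pr_UVS`, `Pr_SWS`, `Pr_MWS`, `Pr_LWS`; each row sums to 1.
#' @export
proportional_catches <- function(catches) {
  Q <- as.matrix(catches[, paste0("Q_", RECEPTOR_ORDER)])
  tot <- rowSums(Q)
  if (any(tot <= 0)) {
    abort(sprintf("All-zero quantum catches for egg '%s'.",
                  catches$egg_id[which(tot <= 0)[1]]))
  }
  P <- Q / tot
  out <- catches[, intersect(c("egg_id", "clutch_id"), names(catches))]
  out[paste0("Pr_", RECEPTOR_ORDER)] <- as.data.frame(P)
  tibble::as_tibble(out)
}

#' Draw disjoint egg pairs from the full pairwise set
#'
#' To avoid pseudoreplication when comparing within- and between-clutch
#' discriminability, each egg may enter the analysis only once. Pairs are
#' drawn by a uniformly random greedy maximal matching: repeatedly pick a
#' pair uniformly at random among pairs whose eggs are both still unused,
#' then retire both eggs; with `e` eggs in one pool this returns
#' `floor(e / 2)` pairs. Deterministic given `seed`.
#'
#' With the default `"uniform"` strategy every admissible pair is equally
#' likely at each draw. Because within-clutch pairs are a vanishing
#' fraction of all pairs, a uniform matching over a realistic data set
#' contains almost no within-clutch comparisons; the `"balanced"` strategy
#' therefore first draws one random within-clutch pair from every clutch
#' with at least two unused eggs, then matches the remaining eggs across
#' clutches, so both comparison types are represented.
#'
#' @param pairs Tibble from [pairwise_jnds()] (the complete pairwise set).
#' @param seed Optional integer seed.
#' @param strategy `"uniform"` (default) or `"balanced"`.
#'
#' @return The selected subset of `pairs`, each egg appearing at most once.
#' @export
sample_disjoint_pairs <- function(pairs, seed = NULL,
                                  strategy = c("uniform", "balanced")) {
  strategy <- match.arg(strategy)
  if (nrow(pairs) == 0) return(pairs)
  with_seed(seed, {
    greedy <- function(available) {
      used <- character(0)
      picked <- integer(0)
      while (any(available)) {
        cand <- which(available)
        take <- if (length(cand) == 1) cand else sample(cand, 1)
        picked <- c(picked, take)
        used <- c(used, pairs$egg_a[take], pairs$egg_b[take])
        available <- available &
          !(pairs$egg_a %in% used | pairs$egg_b %in% used)
      }
      picked
    }
    if (strategy == "uniform") {
      picked <- greedy(rep(TRUE, nrow(pairs)))
    } else {
      picked <- integer(0)
      used <- character(0)
      for (cl in sample(unique(pairs$clutch_a[pairs$same_clutch]))) {
        cand <- which(pairs$same_clutch & pairs$clutch_a == cl &
                        !(pairs$egg_a %in% used) & !(pairs$egg_b %in% used))
        if (length(cand) == 0) next
        take <- if (length(cand) == 1) cand else sample(cand, 1)
        picked <- c(picked, take)
        used <- c(used, pairs$egg_a[take], pairs$egg_b[take])
      }
      # remaining eggs matched across clutches; same-clutch pairs only if
      # nothing else is admissible
      repeat {
        free <- !(pairs$egg_a %in% used) & !(pairs$egg_b %in% used)
        cand <- which(free & !pairs$same_clutch)
        if (length(cand) == 0) cand <- which(free)
        if (length(cand) == 0) break
        take <- if (length(cand) == 1) cand else sample(cand, 1)
        picked <- c(picked, take)
        used <- c(used, pairs$egg_a[take], pairs$egg_b[take])
      }
    }
    pairs[sort(picked), ]
  })
}

#' Welch's heteroscedastic one-way test
#'
#' One-way comparison of group means that does not assume equal variances;
#' its denominator degrees of freedom are generally non-integer. With
#' `var_equal = TRUE` the classical one-way ANOVA is used instead.
#'
#' @param data A data frame.
#' @param response Column with the response variable (tidy-eval).
#' @param group Column with the grouping factor (tidy-eval).
#' @param var_equal Assume equal variances (classical ANOVA)? Default
#'   `FALSE`.
#'
#' @return An object of class `"welch_test"` with fields `statistic`
#'   (the F value), `df1`, `df2`, `p.value`, `method` and a `group_stats`
#'   tibble (n, mean, sd, se per group). Has [tidy()] and [glance()]
#'   methods.
#' @export
#'
#' @examples
#' welch_oneway(iris, Sepal.Length, Species)
welch_oneway <- function(data, response, group, var_equal = FALSE) {
  y <- dplyr::pull(data, {{ response }})
  g <- dplyr::pull(data, {{ group }})
  welch_core(y, g, var_equal = var_equal)
}

welch_core <- function(y, g, var_equal = FALSE) {
  g <- factor(g)
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Need at least two groups.")
  ns <- tapply(y, g, length)
  if (any(ns < 2)) abort("Every group needs at least two observations.")
  vs <- tapply(y, g, var)
  if (!var_equal && any(vs <= 0)) {
    abort("A group has zero variance; jitter the values or exclude the group.")
  }
  ft <- oneway.test(y ~ g, var.equal = var_equal)
  stats_tbl <- tibble::tibble(
    group = levels(g),
    n = as.integer(ns),
    mean = as.numeric(tapply(y, g, mean)),
    sd = sqrt(as.numeric(vs)),
    se = sqrt(as.numeric(vs) / as.numeric(ns))
  )
  structure(
    list(
      statistic = unname(ft$statistic),
      df1 = unname(ft$parameter[1]),
      df2 = unname(ft$parameter[2]),
      p.value = unname(ft$p.value),
      method = if (var_equal) "one-way ANOVA" else "Welch one-way test",
      group_stats = stats_tbl
    ),
    class = "welch_test"
  )
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("%s: F(%g, %.2f) = %.3f, p = %.4g\n",
              x$method, x$df1, x$df2, x$statistic, x$p.value))
  print(x$group_stats)
  invisible(x)
}

#' @rdname welch_oneway
#' @param x A `welch_test` object.
#' @param ... Unused.
#' @export
tidy.welch_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df1 = x$df1, df2 = x$df2,
    p.value = x$p.value, method = x$method
  )
}

#' @rdname welch_oneway
#' @export
glance.welch_test <- function(x, ...) tidy(x)

#' Within- versus between-clutch variation report
#'
#' Runs the full variation analysis on processed (averaged, smoothed,
#' regridded) egg spectra: per-receptor Welch tests of the proportional
#' catches across clutches, a Welch test of the achromatic catch across
#' clutches, and a two-group Welch test of chromatic JNDs for
#' within-clutch versus between-clutch egg pairs drawn by
#' [sample_disjoint_pairs()] with the `"balanced"` strategy (one random
#' within-clutch pair per clutch, remaining eggs matched across clutches),
#' so both comparison types carry enough pairs for a two-group test.
#' Clutches with fewer than two eggs are
#' excluded from the across-clutch tests (and counted in the attributes).
#'
#' @param spectra Averaged reflectance spectra (long tibble with `egg_id`,
#'   `clutch_id`, `wavelength`, `value`) on the receptor grid.
#' @param receptors A [receptor_set()].
#' @param light Illuminant on the same grid; default flat.
#' @param seed Integer seed controlling the random disjoint pairing.
#'
#' @return A tibble of class `"clutch_variation_report"` with columns
#'   `response`, `group`, `mean`, `se`, `df1`, `df2`, `statistic`,
#'   `p.value`. Attributes: `n_eggs`, `n_clutches`, `n_pairs`,
#'   `n_within`, `n_between`, `n_clutches_excluded`, `seed`.
#' @export
clutch_variation_report <- function(spectra, receptors, light = NULL,
                                    seed = NULL) {
  catches <- quantum_catch(spectra, receptors, light)
  if (dplyr::n_distinct(catches$clutch_id) < 2) {
    abort("Need at least two clutches.")
  }
  props <- proportional_catches(catches)
  counts <- table(catches$clutch_id)
  keep_clutch <- names(counts)[counts >= 2]
  n_excl <- sum(counts < 2)
  props_k <- props[props$clutch_id %in% keep_clutch, ]
  catches_k <- catches[catches$clutch_id %in% keep_clutch, ]
  if (dplyr::n_distinct(props_k$clutch_id) < 2) {
    abort("Fewer than two clutches with two or more eggs.")
  }

  one_row <- function(response, wt, mean, se, group = NA_character_) {
    tibble::tibble(response = response, group = group, mean = mean, se = se,
                   df1 = wt$df1, df2 = wt$df2,
                   statistic = wt$statistic, p.value = wt$p.value)
  }
  rows <- lapply(RECEPTOR_ORDER, function(r) {
    col <- paste0("Pr_", r)
    wt <- welch_core(props_k[[col]], props_k$clutch_id)
    one_row(r, wt, mean(props_k[[col]]),
            sd(props_k[[col]]) / sqrt(nrow(props_k)))
  })
  wt_a <- welch_core(catches_k$Q_A, catches_k$clutch_id)
  rows <- c(rows, list(one_row("Achrom", wt_a, mean(catches_k$Q_A),
                               sd(catches_k$Q_A) / sqrt(nrow(catches_k)))))

  pairs <- pairwise_jnds(catches, receptors)
  chosen <- sample_disjoint_pairs(pairs, seed = seed, strategy = "balanced")
  chosen$comparison <- ifelse(chosen$same_clutch, "within", "between")
  if (length(unique(chosen$comparison)) < 2 ||
      any(table(chosen$comparison) < 2)) {
    abort("Disjoint pairing yielded fewer than two within- or between-clutch pairs; JND comparison not possible.")
  }
  wt_j <- welch_core(chosen$ds, chosen$comparison)
  gs <- wt_j$group_stats
  jnd_rows <- tibble::tibble(
    response = "Chrom JNDs",
    group = gs$group,
    mean = gs$mean,
    se = gs$se,
    df1 = c(wt_j$df1, NA),
    df2 = c(wt_j$df2, NA),
    statistic = c(wt_j$statistic, NA),
    p.value = c(wt_j$p.value, NA)
  )
  out <- dplyr::bind_rows(c(rows, list(jnd_rows)))
  structure(
    out,
    class = c("clutch_variation_report", class(out)),
    n_eggs = nrow(catches),
    n_clutches = dplyr::n_distinct(catches$clutch_id),
    n_clutches_excluded = n_excl,
    n_pairs = nrow(chosen),
    n_within = sum(chosen$comparison == "within"),
    n_between = sum(chosen$comparison == "between"),
    seed = if (is.null(seed)) NA_integer_ else seed
  )
}

#' Plot within- vs between-clutch chromatic discriminability
#'
#' @param pairs Tibble from [pairwise_jnds()] or [sample_disjoint_pairs()].
#' @return A ggplot: JND distributions by comparison type, with the 1-JND
#'   discriminability threshold marked.
#' @export
plot_jnd_pairs <- function(pairs) {
  pairs$comparison <- ifelse(pairs$same_clutch, "within clutch", "between clutch")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$comparison, y = .data$ds)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(Delta * S ~ "(JND)")) +
    ggplot2::theme_minimal()
}

#' Plot spectra coloured by clutch
#'
#' @param spectra Long spectra tibble with `wavelength`, `value` and
#'   (optionally) `clutch_id` / `egg_id`.
#' @return A ggplot of the curves.
#' @export
plot_spectra <- function(spectra) {
  keys <- intersect(c("id", "egg_id"), names(spectra))
  grp <- if (length(keys) > 0) keys[1] else NULL
  p <- ggplot2::ggplot(spectra,
                       ggplot2::aes(x = .data$wavelength, y = .data$value))
  if (!is.null(grp) && "clutch_id" %in% names(spectra)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(group = .data[[grp]], colour = .data$clutch_id),
      alpha = 0.7, show.legend = FALSE)
  } else if (!is.null(grp)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data[[grp]]), alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "wavelength (nm)", y = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.clutch_variation_report <- function(object, ...) {
  df <- object[object$response != "Chrom JNDs", ]
  jnd <- object[object$response == "Chrom JNDs", ]
  df$label <- df$response
  jnd$label <- paste("JND", jnd$group)
  both <- dplyr::bind_rows(df, jnd)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2) +
    ggplot2::facet_wrap(~ .data$label, scales = "free", nrow = 1) +
    ggplot2::labs(x = NULL, y = "mean ± SE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
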