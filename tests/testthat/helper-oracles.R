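# independent oracles, kept deliberately naive

# Welch heteroscedastic one-way F, brute force from the defining formulas
welch_brute <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 1)
  m <- vapply(groups, mean, 1)
  s2 <- vapply(groups, var, 1)
  w <- n / s2
  W <- sum(w)
  xb <- sum(w * m) / W
  L <- sum((1 - w / W)^2 / (n - 1))
  f <- (sum(w * (m - xb)^2) / (k - 1)) / (1 + 2 * (k - 2) * L / (k^2 - 1))
  df2 <- (k^2 - 1) / (3 * L)
  list(F = f, df1 = k - 1, df2 = df2,
       p = pf(f, k - 1, df2, lower.tail = FALSE))
}

# two-sample Welch t statistic and Welch-Satterthwaite df, closed form
welch_two_sample <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df)
}

# two-sided Fisher p for a 2x2 table by full enumeration of margin-fixed
# tables under the hypergeometric, probability-ordering rule
fisher_2x2_enum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  pr <- vapply(a_range, function(a) {
    exp(lchoose(rs[1], a) + lchoose(rs[2], cs[1] - a) - lchoose(n, cs[1]))
  }, 1)
  p_obs <- pr[a_range == a_obs]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# dichromatic receptor-noise distance, closed form
dichromatic_jnd <- function(qa, qb, omega, rx, ry) {
  dfx <- log(qa[[rx]] / qb[[rx]])
  dfy <- log(qa[[ry]] / qb[[ry]])
  abs(dfx - dfy) / sqrt(omega[[rx]]^2 + omega[[ry]]^2)
}

# hypergeometric log-probability of a margin-fixed r x c table
log_prob_rc <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# small toy receptor set on a coarse grid, used where speed matters
toy_receptors <- function(grid = wl_grid(300, 700, 5), width = 40,
                          ...) {
  receptor_set(
    simulate_sensitivities(grid = grid, width = width,
                           emulate_padding = FALSE),
    ...
  )
}

# constant-reflectance spectra tibble for a set of eggs
flat_spectra <- function(levels, grid = wl_grid(300, 700, 5),
                         clutch = NULL) {
  if (is.null(clutch)) clutch <- rep("c1", length(levels))
  purrr::map_dfr(seq_along(levels), function(i) {
    tibble::tibble(egg_id = sprintf("e%02d", i), clutch_id = clutch[i],
                   wavelength = as.numeric(grid), value = levels[i])
  })
}
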