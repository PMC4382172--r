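#' Simulate clutch-structured blue-green egg spectra
#'
#' Generates raw replicate reflectance spectra with the nested variance
#' structure of a field data set: clutch peak-position (hue) centres are
#' drawn around `peak_center_mean` with between-clutch standard deviation
#' `between_sd`; egg centres around their clutch centre with within-clutch
#' standard deviation `within_sd`; each replicate measurement adds
#' independent spectrometer noise. Reflectance is a baseline plus one
#' Gaussian peak (blue-green by default), clipped to `[0, 1]`. Defaults
#' mirror a robin-like design: 23 clutches, 3 eggs each, 9 measurements
#' per egg (3 per probe position), with between-clutch hue variation
#' exceeding within-clutch variation.
#'
#' @param n_clutches Number of clutches (default 23).
#' @param eggs_per_clutch Eggs per clutch: one integer or a vector of
#'   length `n_clutches` (default 3).
#' @param replicates Measurements per egg (default 9), cycled over probe
#'   positions blunt / middle / sharp.
#' @param grid Wavelength grid (default [wl_grid()]).
#' @param baseline Baseline reflectance (default 0.05).
#' @param peak_center_mean Mean peak wavelength in nm (default 500,
#'   blue-green).
#' @param between_sd,within_sd Between- and within-clutch standard
#'   deviations of the peak centre in nm (defaults 10 and 4).
#' @param peak_width Gaussian peak standard deviation in nm (default 50).
#' @param peak_height Peak reflectance above baseline (default 0.55).
#' @param noise_sd Replicate measurement noise standard deviation on the
#'   reflectance scale (default 0.005).
#' @param seed Optional integer seed; output is bit-reproducible given it.
#'
#' @return A long spectra tibble (`id`, `egg_id`, `clutch_id`, `position`,
#'   `replicate`, `kind`, `wavelength`, `value`) ready for
#'   [average_replicates()].
#' @export
#'
#' @examples
#' raw <- simulate_egg_spectra(n_clutches = 2, replicates = 3, seed = 1)
#' dplyr::n_distinct(raw$egg_id)
simulate_egg_spectra <- function(n_clutches = 23, eggs_per_clutch = 3,
                                 replicates = 9, grid = wl_grid(),
                                 baseline = 0.05, peak_center_mean = 500,
                                 between_sd = 10, within_sd = 4,
                                 peak_width = 50, peak_height = 0.55,
                                 noise_sd = 0.005, seed = NULL) {
  if (between_sd < 0 || within_sd < 0 || noise_sd < 0) {
    abort("Standard deviations must be non-negative.")
  }
  if (baseline < 0 || baseline + peak_height > 1) {
    abort("Peak parameters must keep reflectance within [0, 1].")
  }
  if (length(eggs_per_clutch) == 1) {
    eggs_per_clutch <- rep(eggs_per_clutch, n_clutches)
  }
  if (length(eggs_per_clutch) != n_clutches) {
    abort("`eggs_per_clutch` must have length 1 or n_clutches.")
  }
  grid <- as.numeric(grid)
  with_seed(seed, {
    clutch_centers <- rnorm(n_clutches, peak_center_mean, between_sd)
    clutch_of_egg <- rep(seq_len(n_clutches), eggs_per_clutch)
    n_eggs <- length(clutch_of_egg)
    egg_centers <- rnorm(n_eggs, clutch_centers[clutch_of_egg], within_sd)
    base <- vapply(egg_centers, function(cc) {
      pmin(1, pmax(0, baseline +
                     peak_height * exp(-(grid - cc)^2 / (2 * peak_width^2))))
    }, numeric(length(grid)))  # wavelengths x eggs
    positions <- rep(c("blunt", "middle", "sharp"), length.out = replicates)
    rep_within_pos <- stats::ave(seq_len(replicates), positions,
                                 FUN = seq_along)
    pieces <- vector("list", n_eggs * replicates)
    k <- 0L
    for (e in seq_len(n_eggs)) {
      egg_id <- sprintf("e%02d", e)
      clutch_id <- sprintf("c%02d", clutch_of_egg[e])
      for (r in seq_len(replicates)) {
        k <- k + 1L
        v <- pmax(0, base[, e] + rnorm(length(grid), 0, noise_sd))
        pieces[[k]] <- tibble::tibble(
          id = paste(egg_id, clutch_id, positions[r], rep_within_pos[r],
                     sep = "_"),
          egg_id = egg_id, clutch_id = clutch_id,
          position = positions[r], replicate = as.integer(rep_within_pos[r]),
          kind = "reflectance", wavelength = grid, value = v
        )
      }
    }
    dplyr::bind_rows(pieces)
  })
}

# Govardovskii-style A1 visual-pigment template (alpha + beta bands)
a1_template <- function(wl, lmax) {
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  bb <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((wl - lmb) / bb)^2)
  pmax(0, alpha + beta)
}

#' Simulate photoreceptor spectral sensitivities
#'
#' Builds four unimodal cone sensitivity curves peaking at the supplied
#' wavelengths, normalised to unit peak, as a stand-in for digitised
#' spectral-sensitivity measurements. Shapes: `"gaussian"` (fixed-width
#' normal) or `"a1_template"` (the standard A1 visual-pigment nomogram
#' with alpha and beta bands). With `emulate_padding` the 300--330 nm
#' region is forced to zero, mimicking sensitivity data digitised from
#' 330 nm upward and zero-padded down to 300 nm.
#'
#' @param lambda_max Named peak wavelengths in nm for `UVS, SWS, MWS,
#'   LWS`; defaults are thrush-like (373, 454, 504, 557).
#' @param shape `"gaussian"` or `"a1_template"`.
#' @param grid Wavelength grid (default [wl_grid()]).
#' @param width Gaussian standard deviation in nm (gaussian shape only).
#' @param emulate_padding Zero the 300--330 nm region? Default `TRUE`.
#'
#' @return A long tibble (`receptor`, `wavelength`, `value`) for
#'   [receptor_set()].
#' @export
#'
#' @examples
#' sens <- simulate_sensitivities()
#' receptor_set(sens)
simulate_sensitivities <- function(lambda_max = c(UVS = 373, SWS = 454,
                                                  MWS = 504, LWS = 557),
                                   shape = c("gaussian", "a1_template"),
                                   grid = wl_grid(), width = 40,
                                   emulate_padding = TRUE) {
  shape <- match.arg(shape)
  grid <- as.numeric(grid)
  lambda_max <- lambda_max[RECEPTOR_ORDER]
  if (anyNA(lambda_max)) abort("`lambda_max` must be named over UVS, SWS, MWS, LWS.")
  if (any(lambda_max < min(grid) | lambda_max > max(grid))) {
    abort("Every lambda_max must lie within the grid.")
  }
  out <- purrr::map_dfr(RECEPTOR_ORDER, function(r) {
    lm <- lambda_max[[r]]
    v <- switch(shape,
      gaussian = exp(-(grid - lm)^2 / (2 * width^2)),
      a1_template = a1_template(grid, lm)
    )
    v <- v / max(v)
    tibble::tibble(receptor = r, wavelength = grid, value = v)
  })
  if (emulate_padding) {
    out$value[out$wavelength >= 300 & out$wavelength <= 330] <- 0
  }
  out
}

#' Simulate a three-arm egg-rejection experiment
#'
#' Independent Bernoulli rejection outcomes per nest with configurable
#' per-arm rejection probabilities and covariates (Julian date, nesting
#' stage, clutch size, year). Defaults describe a weak-effect three-arm
#' design of 15 nests per arm across three breeding seasons.
#'
#' @param n_per_group Named nest counts for `IV, DV, UNM` (default 15
#'   each).
#' @param p_reject Named per-arm rejection probabilities (default
#'   IV 0.67, DV 0.73, UNM 0.81).
#' @param julian_range Inclusive day-of-year range for parasitism dates
#'   (default 100--200).
#' @param p_incubation Probability a nest is parasitised during incubation
#'   rather than laying (default 0.5).
#' @param clutch_sizes Integer clutch sizes sampled uniformly (default
#'   2:4).
#' @param years Year labels sampled uniformly (default three seasons).
#' @param seed Optional integer seed.
#'
#' @return A tibble of nest records (`nest_id`, `treatment`, `outcome`,
#'   `julian_date`, `stage`, `clutch_size`, `year`).
#' @export
#'
#' @examples
#' simulate_outcomes(seed = 1)
simulate_outcomes <- function(n_per_group = c(IV = 15, DV = 15, UNM = 15),
                              p_reject = c(IV = 0.67, DV = 0.73, UNM = 0.81),
                              julian_range = c(100, 200),
                              p_incubation = 0.5,
                              clutch_sizes = 2:4,
                              years = c("2012", "2013", "2014"),
                              seed = NULL) {
  n_per_group <- n_per_group[TREATMENT_LEVELS]
  p_reject <- p_reject[TREATMENT_LEVELS]
  if (anyNA(n_per_group) || anyNA(p_reject)) {
    abort("`n_per_group` and `p_reject` must be named over IV, DV, UNM.")
  }
  if (any(p_reject < 0 | p_reject > 1)) abort("Probabilities must be in [0, 1].")
  if (any(n_per_group < 0)) abort("Group sizes must be non-negative.")
  with_seed(seed, {
    treatment <- rep(TREATMENT_LEVELS, times = n_per_group)
    n <- length(treatment)
    tibble::tibble(
      nest_id = sprintf("n%03d", seq_len(n)),
      treatment = treatment,
      outcome = ifelse(rbinom(n, 1, p_reject[treatment]) == 1,
                       "reject", "accept"),
      julian_date = sample(seq(julian_range[1], julian_range[2]), n,
                           replace = TRUE),
      stage = ifelse(runif(n) < p_incubation, "incubation", "laying"),
      clutch_size = sample(clutch_sizes, n, replace = TRUE),
      year = sample(years, n, replace = TRUE)
    )
  })
}
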