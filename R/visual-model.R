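#' Per-receptor quantum catches for each egg
#'
#' For each egg, the quantum catch of cone class *i* is the rectangular-rule
#' integral of reflectance x irradiance x sensitivity over the working
#' grid: `Q_i = sum_l R(l) I(l) S_i(l) dl`. The achromatic catch `Q_A` uses
#' the summed MWS + LWS sensitivity, a stand-in for the double-cone /
#' luminance channel of the avian retina.
#'
#' @param spectra Averaged reflectance spectra: long tibble with `egg_id`
#'   (and optionally `clutch_id`), `wavelength`, `value`, all on the
#'   receptor set's grid.
#' @param receptors A [receptor_set()].
#' @param light Illuminant tibble (`wavelength`, `value`) on the same grid;
#'   default [illuminant_flat()].
#'
#' @return A tibble with one row per egg: `egg_id`, `clutch_id` (if
#'   present), `Q_UVS`, `Q_SWS`, `Q_MWS`, `Q_LWS`, `Q_A`.
#' @export
quantum_catch <- function(spectra, receptors, light = NULL) {
  if (!"egg_id" %in% names(spectra)) abort("`spectra` must have an `egg_id` column.")
  if (any(spectra$value < 0)) abort("Negative reflectance encountered.")
  sens <- receptors$sensitivities
  grid <- sort(unique(sens$wavelength))
  if (is.null(light)) light <- illuminant_flat(grid)
  step <- median(diff(grid))
  Smat <- vapply(RECEPTOR_ORDER, function(r) {
    s <- sens[sens$receptor == r, ]
    s$value[order(s$wavelength)]
  }, numeric(length(grid)))
  li <- light[order(light$wavelength), ]
  if (!isTRUE(all.equal(as.numeric(li$wavelength), grid))) {
    abort("Illuminant is not on the receptor grid; regrid first.")
  }
  has_clutch <- "clutch_id" %in% names(spectra)
  key <- if (has_clutch) c("egg_id", "clutch_id") else "egg_id"
  wide <- tidyr::pivot_wider(
    spectra[, c(key, "wavelength", "value")],
    names_from = "wavelength", values_from = "value"
  )
  wl_cols <- setdiff(names(wide), key)
  if (!isTRUE(all.equal(sort(as.numeric(wl_cols)), grid))) {
    abort("Egg spectra are not on the receptor grid; regrid first.")
  }
  R <- as.matrix(wide[, as.character(grid)])
  RI <- sweep(R, 2, li$value, `*`)
  Q <- (RI %*% Smat) * step
  QA <- (RI %*% (Smat[, "MWS"] + Smat[, "LWS"])) * step
  if (any(rowSums(Q) == 0)) {
    warn("All-zero quantum catches for at least one egg; chromatic contrasts will be undefined.")
  }
  out <- wide[, key]
  out$Q_UVS <- as.numeric(Q[, "UVS"])
  out$Q_SWS <- as.numeric(Q[, "SWS"])
  out$Q_MWS <- as.numeric(Q[, "MWS"])
  out$Q_LWS <- as.numeric(Q[, "LWS"])
  out$Q_A <- as.numeric(QA)
  tibble::as_tibble(out)
}

# log receptor contrasts for one pair -> tetrachromatic RNL distance;
# df is a matrix with one row per pair, columns UVS,SWS,MWS,LWS
delta_s_from_contrasts <- function(df, e) {
  e1 <- e[["UVS"]]; e2 <- e[["SWS"]]; e3 <- e[["MWS"]]; e4 <- e[["LWS"]]
  f1 <- df[, 1]; f2 <- df[, 2]; f3 <- df[, 3]; f4 <- df[, 4]
  num <- (e1 * e2)^2 * (f4 - f3)^2 +
    (e1 * e3)^2 * (f4 - f2)^2 +
    (e1 * e4)^2 * (f3 - f2)^2 +
    (e2 * e3)^2 * (f4 - f1)^2 +
    (e2 * e4)^2 * (f3 - f1)^2 +
    (e3 * e4)^2 * (f2 - f1)^2
  den <- (e1 * e2 * e3)^2 + (e1 * e2 * e4)^2 +
    (e1 * e3 * e4)^2 + (e2 * e3 * e4)^2
  sqrt(num / den)
}

catch_vec <- function(q) {
  if (is.data.frame(q)) q <- unlist(q[1, paste0("Q_", RECEPTOR_ORDER)])
  names(q) <- sub("^Q_", "", names(q))
  q <- q[RECEPTOR_ORDER]
  if (anyNA(q)) abort("Quantum catches must be named over UVS, SWS, MWS, LWS.")
  q
}

#' Chromatic discriminability (JND) between two quantum-catch vectors
#'
#' Receptor-noise-limited perceptual distance for a tetrachromat. With log
#' receptor contrasts `df_i = ln(Q_i(a) / Q_i(b))` and noise `omega_i`, the
#' distance is the standard tetrachromatic form whose numerator sums the
#' six receptor-pair opponent terms and whose denominator sums the four
#' receptor-triple noise products. Values above 1 JND are conventionally
#' discriminable.
#'
#' @param a,b Named quantum-catch vectors over `UVS, SWS, MWS, LWS`
#'   (or one-row tibbles from [quantum_catch()]); all catches must be
#'   strictly positive.
#' @param noise Named noise vector from [receptor_noise()].
#'
#' @return The chromatic distance in JND units (non-negative scalar).
#' @export
chromatic_jnd <- function(a, b, noise) {
  qa <- catch_vec(a)
  qb <- catch_vec(b)
  if (any(qa <= 0)) abort("Non-positive quantum catch in `a`; log contrast undefined.")
  if (any(qb <= 0)) abort("Non-positive quantum catch in `b`; log contrast undefined.")
  df <- matrix(log(qa / qb), nrow = 1,
               dimnames = list(NULL, RECEPTOR_ORDER))
  as.numeric(delta_s_from_contrasts(df, noise[RECEPTOR_ORDER]))
}

#' Achromatic discriminability (JND) between two eggs
#'
#' Luminance-channel contrast: `|ln(Q_A(a) / Q_A(b))| / achromatic_weber`.
#'
#' @param a,b Achromatic catches `Q_A` (positive scalars, or one-row
#'   tibbles from [quantum_catch()]).
#' @param achromatic_weber Weber fraction of the achromatic channel.
#'
#' @return The achromatic distance in JND units.
#' @export
achromatic_jnd <- function(a, b, achromatic_weber = 0.1) {
  if (is.data.frame(a)) a <- a$Q_A[1]
  if (is.data.frame(b)) b <- b$Q_A[1]
  if (a <= 0 || b <= 0) abort("Achromatic catch must be positive.")
  abs(log(a / b)) / achromatic_weber
}

#' All pairwise chromatic and achromatic JNDs
#'
#' Computes the discriminability of every unordered pair of eggs and labels
#' each pair as within-clutch or between-clutch.
#'
#' @param catches Tibble from [quantum_catch()] with `egg_id` and
#'   `clutch_id`.
#' @param receptors A [receptor_set()] (supplies the noise vector and the
#'   achromatic Weber fraction).
#'
#' @return A tibble with one row per pair: `egg_a`, `egg_b`, `clutch_a`,
#'   `clutch_b`, `same_clutch`, `ds` (chromatic JND), `dl` (achromatic
#'   JND).
#' @export
pairwise_jnds <- function(catches, receptors) {
  if (nrow(catches) < 2) abort("Need at least two eggs.")
  if (!"clutch_id" %in% names(catches)) abort("`catches` must have `clutch_id`.")
  noise <- receptor_noise(receptors)
  Q <- as.matrix(catches[, paste0("Q_", RECEPTOR_ORDER)])
  colnames(Q) <- RECEPTOR_ORDER
  if (any(Q <= 0)) {
    bad <- catches$egg_id[which(rowSums(Q <= 0) > 0)[1]]
    abort(sprintf("Non-positive quantum catch for egg '%s'.", bad))
  }
  idx <- combn(nrow(catches), 2)
  ia <- idx[1, ]; ib <- idx[2, ]
  df <- log(Q[ia, , drop = FALSE] / Q[ib, , drop = FALSE])
  ds <- delta_s_from_contrasts(df, noise)
  dl <- abs(log(catches$Q_A[ia] / catches$Q_A[ib])) / receptors$achromatic_weber
  tibble::tibble(
    egg_a = catches$egg_id[ia],
    egg_b = catches$egg_id[ib],
    clutch_a = catches$clutch_id[ia],
    clutch_b = catches$clutch_id[ib],
    same_clutch = catches$clutch_id[ia] == catches$clutch_id[ib],
    ds = as.numeric(ds),
    dl = as.numeric(dl)
  )
}
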