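RECEPTOR_ORDER <- c("UVS", "SWS", "MWS", "LWS")

#' Default relative cone densities for a UVS-type passerine retina
#'
#' Relative proportions of the four single-cone classes
#' (UVS : SWS : MWS : LWS = 1.0 : 1.78 : 2.21 : 1.96), the values used for
#' thrush-like UVS species in receptor-noise modelling.
#'
#' @return A named numeric vector over `UVS, SWS, MWS, LWS`.
#' @export
default_cone_densities <- function() {
  c(UVS = 1.0, SWS = 1.78, MWS = 2.21, LWS = 1.96)
}

#' Bundle cone sensitivities with noise parameters
#'
#' A receptor set holds the four single-cone spectral sensitivities on a
#' common grid together with the parameters of the receptor-noise-limited
#' model: relative cone densities, the Weber fraction anchoring the noise of
#' the reference receptor, and the Weber fraction of the achromatic
#' (double-cone-like) channel.
#'
#' @param sensitivities Long tibble with columns `receptor`
#'   (`UVS/SWS/MWS/LWS`), `wavelength`, `value`; all four curves on one
#'   grid, values non-negative.
#' @param densities Named relative cone proportions (positive); default
#'   [default_cone_densities()].
#' @param weber Weber fraction of the reference receptor (default 0.1).
#' @param reference Receptor whose noise equals `weber` (default `"LWS"`,
#'   the most abundant-cone convention; the choice rescales all chromatic
#'   JNDs by one global constant).
#' @param achromatic_weber Weber fraction of the achromatic channel
#'   (default 0.1).
#'
#' @return An object of class `"receptor_set"`.
#' @export
receptor_set <- function(sensitivities,
                         densities = default_cone_densities(),
                         weber = 0.1,
                         reference = "LWS",
                         achromatic_weber = 0.1) {
  need <- c("receptor", "wavelength", "value")
  if (!all(need %in% names(sensitivities))) {
    abort("`sensitivities` needs columns receptor, wavelength, value.")
  }
  if (!setequal(unique(sensitivities$receptor), RECEPTOR_ORDER)) {
    abort("Sensitivities must cover exactly UVS, SWS, MWS, LWS.")
  }
  if (any(sensitivities$value < 0)) abort("Sensitivities must be non-negative.")
  grids <- split(sensitivities$wavelength, sensitivities$receptor)
  if (length(unique(vapply(grids, function(g) paste(g, collapse = ","), ""))) != 1) {
    abort("All four sensitivity curves must share one wavelength grid.")
  }
  densities <- densities[RECEPTOR_ORDER]
  if (anyNA(densities) || any(densities <= 0)) {
    abort("`densities` must be positive and named over UVS, SWS, MWS, LWS.")
  }
  if (weber <= 0 || achromatic_weber <= 0) abort("Weber fractions must be positive.")
  reference <- match.arg(reference, RECEPTOR_ORDER)
  structure(
    list(
      sensitivities = tibble::as_tibble(sensitivities[order(
        match(sensitivities$receptor, RECEPTOR_ORDER), sensitivities$wavelength), need]),
      densities = densities,
      weber = weber,
      reference = reference,
      achromatic_weber = achromatic_weber
    ),
    class = "receptor_set"
  )
}

#' @export
print.receptor_set <- function(x, ...) {
  wl <- unique(x$sensitivities$wavelength)
  cat("<receptor_set>\n")
  cat(sprintf("  grid: %g-%g nm (%d points)\n", min(wl), max(wl), length(wl)))
  cat(sprintf("  densities: %s\n",
              paste(sprintf("%s=%.2f", names(x$densities), x$densities),
                    collapse = ", ")))
  cat(sprintf("  weber = %g (reference %s), achromatic weber = %g\n",
              x$weber, x$reference, x$achromatic_weber))
  invisible(x)
}

#' Read receptor sensitivity curves from delimited text
#'
#' Expects a wavelength column followed by one column per receptor named
#' `UVS`, `SWS`, `MWS`, `LWS`.
#'
#' @param path Delimited text file (TSV or CSV).
#' @return A long tibble (`receptor`, `wavelength`, `value`) suitable for
#'   [receptor_set()].
#' @export
read_sensitivities <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  wl_col <- names(raw)[1]
  if (!all(RECEPTOR_ORDER %in% names(raw))) {
    abort("Sensitivity file must have columns UVS, SWS, MWS, LWS.")
  }
  long <- tidyr::pivot_longer(raw[, c(wl_col, RECEPTOR_ORDER)],
                              -dplyr::all_of(wl_col),
                              names_to = "receptor", values_to = "value")
  dplyr::rename(long, wavelength = dplyr::all_of(wl_col))
}

#' Read an ambient irradiance curve
#'
#' @param path Delimited text with a wavelength column and one irradiance
#'   column (photon flux, arbitrary units).
#' @param name Label for the illuminant.
#' @return A tibble (`wavelength`, `value`) with attribute `name`.
#' @export
read_illuminant <- function(path, name = basename(path)) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  out <- tibble::tibble(wavelength = as.numeric(raw[[1]]),
                        value = as.numeric(raw[[2]]))
  if (any(out$value < 0)) abort("Irradiance must be non-negative.")
  attr(out, "name") <- name
  out
}

#' Flat ("ideal white") illuminant
#'
#' A spectrally flat photon-flux irradiance, the conventional neutral
#' stand-in when a measured ambient spectrum is unavailable. Under a single
#' shared illuminant the chromatic JND is invariant to the illuminant's
#' overall scale, so the unit height is immaterial.
#'
#' @param grid Wavelength grid (default [wl_grid()]).
#' @return A tibble (`wavelength`, `value`) with `value = 1` everywhere.
#' @export
illuminant_flat <- function(grid = wl_grid()) {
  out <- tibble::tibble(wavelength = as.numeric(grid), value = 1)
  attr(out, "name") <- "ideal white"
  out
}

#' Receptor noise from densities and the Weber fraction
#'
#' In the receptor-noise-limited model the noise of channel *i* scales
#' inversely with the square root of its relative cone density:
#' `omega_i = weber * sqrt(eta_ref / eta_i)`, so the reference receptor's
#' noise equals the Weber fraction exactly.
#'
#' @param receptors A [receptor_set()].
#' @return A named numeric vector `omega` over `UVS, SWS, MWS, LWS`.
#' @export
#'
#' @examples
#' rs_sens <- simulate_sensitivities()
#' receptor_noise(receptor_set(rs_sens))
receptor_noise <- function(receptors) {
  eta <- receptors$densities
  if (any(eta <= 0)) abort("Cone densities must be positive.")
  eta_ref <- eta[[receptors$reference]]
  receptors$weber * sqrt(eta_ref / eta)
}
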