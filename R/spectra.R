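#' Wavelength grid
#'
#' The common working grid onto which reflectance, sensitivity and
#' irradiance curves are interpolated before visual modelling. The default
#' spans the full avian visual range, 300--700 nm at 1 nm.
#'
#' @param start,stop Grid limits in nanometres; `start < stop`.
#' @param step Grid spacing in nanometres; positive.
#'
#' @return A numeric vector of wavelengths with class `"wl_grid"`.
#' @export
#'
#' @examples
#' wl_grid()[1:5]
wl_grid <- function(start = 300, stop = 700, step = 1) {
  if (!(start < stop)) abort("`start` must be < `stop`.")
  if (step <= 0) abort("`step` must be positive.")
  structure(seq(start, stop, by = step), class = c("wl_grid", "numeric"))
}

# id columns = everything that is not the curve itself
spc_key_cols <- function(spectra) {
  setdiff(names(spectra), c("wavelength", "value"))
}

spc_split <- function(spectra) {
  keys <- spc_key_cols(spectra)
  if (length(keys) == 0) return(list(spectra))
  split(spectra, interaction(spectra[keys], drop = TRUE, lex.order = TRUE))
}

#' Validate a spectra tibble
#'
#' Checks the structural invariants every curve must satisfy: per spectrum,
#' strictly increasing wavelengths within 250--800 nm, finite values, and
#' (for reflectance) non-negative values.
#'
#' @param spectra A tibble with columns `wavelength`, `value` and any number
#'   of identifier columns (e.g. `egg_id`, `clutch_id`, `kind`).
#'
#' @return `spectra`, invisibly, if valid; otherwise an error.
#' @export
validate_spectra <- function(spectra) {
  if (!all(c("wavelength", "value") %in% names(spectra))) {
    abort("`spectra` must have `wavelength` and `value` columns.")
  }
  if (!is.numeric(spectra$wavelength) || !is.numeric(spectra$value)) {
    abort("`wavelength` and `value` must be numeric.")
  }
  if (any(!is.finite(spectra$value))) abort("Spectral values must be finite.")
  if (any(spectra$wavelength < 250 | spectra$wavelength > 800)) {
    abort("Wavelengths must lie within [250, 800] nm.")
  }
  for (s in spc_split(spectra)) {
    if (any(diff(s$wavelength) <= 0)) {
      abort("Wavelengths must be strictly increasing within each spectrum.")
    }
  }
  if ("kind" %in% names(spectra)) {
    refl <- spectra$value[spectra$kind == "reflectance"]
    if (any(refl < 0)) abort("Reflectance values must be non-negative.")
  }
  invisible(spectra)
}

parse_spectrum_header <- function(x) {
  # convention: eggID_clutchID_position_replicate, e.g. "e1_c1_blunt_2"
  parts <- strsplit(x, "_", fixed = TRUE)
  tibble::tibble(
    id = x,
    egg_id = vapply(parts, function(p) if (length(p) >= 1) p[[1]] else NA_character_, ""),
    clutch_id = vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, ""),
    position = vapply(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_, ""),
    replicate = suppressWarnings(as.integer(
      vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_, "")
    ))
  )
}

#' Read spectra from delimited text
#'
#' Reads reflectance, sensitivity or irradiance curves from tab- or
#' comma-delimited text. The wide dialect has a wavelength column followed
#' by one column per measurement, with measurement metadata encoded in the
#' column header as `eggID_clutchID_position_replicate`; the long dialect has
#' one row per (id, wavelength, value). Values on a percent scale (any value
#' greater than 2 in the file) are divided by 100 unless `unit` overrides
#' the auto-detection.
#'
#' @param path Path to a delimited text file (TSV or CSV, sniffed from the
#'   first line).
#' @param dialect `"wide"` or `"long"`.
#' @param kind One of `"reflectance"`, `"sensitivity"`, `"irradiance"`.
#' @param unit `"auto"` (default), `"percent"` or `"proportion"`. Only
#'   meaningful for reflectance.
#'
#' @return A long tibble with columns `id`, `egg_id`, `clutch_id`,
#'   `position`, `replicate`, `kind`, `wavelength`, `value`.
#' @export
read_spectra <- function(path, dialect = c("wide", "long"),
                         kind = c("reflectance", "sensitivity", "irradiance"),
                         unit = c("auto", "percent", "proportion")) {
  dialect <- match.arg(dialect)
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (dialect == "wide") {
    wl_col <- names(raw)[1]
    for (j in seq_along(raw)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(raw[[j]])))) &
                     !is.na(raw[[j]]))
      if (length(bad) > 0 || anyNA(raw[[j]])) {
        bad <- if (length(bad) > 0) bad[1] else which(is.na(raw[[j]]))[1]
        abort(sprintf("Non-numeric cell at row %d, column '%s' of %s.",
                      bad, names(raw)[j], path))
      }
      raw[[j]] <- as.numeric(raw[[j]])
    }
    long <- tidyr::pivot_longer(raw, -dplyr::all_of(wl_col),
                                names_to = "id", values_to = "value")
    long <- dplyr::rename(long, wavelength = dplyr::all_of(wl_col))
  } else {
    need <- c("id", "wavelength", "value")
    if (!all(need %in% names(raw))) {
      abort("Long dialect requires columns `id`, `wavelength`, `value`.")
    }
    for (cl in c("wavelength", "value")) {
      v <- suppressWarnings(as.numeric(as.character(raw[[cl]])))
      if (anyNA(v)) {
        abort(sprintf("Non-numeric cell at row %d, column '%s' of %s.",
                      which(is.na(v))[1], cl, path))
      }
      raw[[cl]] <- v
    }
    long <- raw[, need]
  }
  # monotonicity is checked in file order, before any sorting
  for (sid in unique(long$id)) {
    wl_file <- long$wavelength[long$id == sid]
    if (any(diff(wl_file) <= 0)) {
      abort(sprintf("Wavelengths not strictly increasing for spectrum '%s'.",
                    sid))
    }
  }
  meta <- parse_spectrum_header(unique(long$id))
  out <- dplyr::left_join(long, meta, by = "id")
  out$kind <- kind
  out <- dplyr::arrange(
    dplyr::select(out, "id", "egg_id", "clutch_id", "position", "replicate",
                  "kind", "wavelength", "value"),
    .data$id, .data$wavelength
  )
  if (kind == "reflectance") {
    in_percent <- switch(unit,
      auto = any(out$value > 2),
      percent = TRUE,
      proportion = FALSE
    )
    if (in_percent) out$value <- out$value / 100
  }
  validate_spectra(out)
  tibble::as_tibble(out)
}

#' Write spectra to wide TSV
#'
#' @param spectra A long spectra tibble (see [read_spectra()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  keys <- spc_key_cols(spectra)
  id_col <- if ("id" %in% keys) "id" else keys[1]
  wide <- tidyr::pivot_wider(
    spectra[, c(id_col, "wavelength", "value")],
    names_from = dplyr::all_of(id_col), values_from = "value"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Average replicate measurements into one spectrum per egg
#'
#' Field practice is to measure each egg several times (here nine: three at
#' each of the blunt pole, middle, and sharp pole) and average the
#' measurements pointwise into a single spectrum per egg. The average is a
#' flat mean over all replicates in a group.
#'
#' @param spectra Long spectra tibble.
#' @param group_by Metadata columns defining a group (default egg and
#'   clutch id). Position and replicate labels are dropped.
#'
#' @return A tibble with one spectrum per group and an `n_averaged` column
#'   recording how many measurements went into each mean.
#' @export
average_replicates <- function(spectra, group_by = c("egg_id", "clutch_id")) {
  missing_cols <- setdiff(group_by, names(spectra))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing grouping columns: ", paste(missing_cols, collapse = ", ")))
  }
  # every spectrum in a group must sit on the identical wavelength set:
  # each wavelength then appears exactly n_spectra times in the group
  spec_cols <- setdiff(spc_key_cols(spectra), c(group_by, "kind"))
  groups <- split(spectra, interaction(spectra[group_by], drop = TRUE))
  grid_ok <- vapply(groups, function(g) {
    ns <- if (length(spec_cols) > 0) nrow(unique(g[spec_cols])) else 1L
    tab <- table(g$wavelength)
    all(tab == ns) && nrow(g) == length(tab) * ns
  }, logical(1))
  if (!all(grid_ok)) {
    abort("Spectra within a group are on different wavelength grids; regrid first.")
  }
  keep_kind <- "kind" %in% names(spectra)
  out <- dplyr::summarise(
    dplyr::group_by(spectra,
                    dplyr::across(dplyr::all_of(c(group_by, "wavelength")))),
    value = mean(.data$value),
    n_averaged = dplyr::n(),
    .groups = "drop"
  )
  # guard: equal replicate count at every wavelength of a group
  chk <- dplyr::summarise(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(group_by))),
    ok = dplyr::n_distinct(.data$n_averaged) == 1, .groups = "drop"
  )
  if (!all(chk$ok)) {
    abort("Spectra within a group are on different wavelength grids; regrid first.")
  }
  if (keep_kind) out$kind <- spectra$kind[1]
  dplyr::arrange(out, dplyr::across(dplyr::all_of(group_by)), .data$wavelength)
}

#' Interpolate spectra onto a wavelength grid
#'
#' Linear interpolation onto `grid`; no extrapolation is performed, so the
#' grid must lie inside each spectrum's measured range.
#'
#' @param spectra Long spectra tibble.
#' @param grid A [wl_grid()] or numeric vector of target wavelengths.
#'
#' @return The spectra resampled onto `grid`, same identifier columns.
#' @export
regrid_spectra <- function(spectra, grid = wl_grid()) {
  grid <- as.numeric(grid)
  keys <- spc_key_cols(spectra)
  pieces <- lapply(spc_split(spectra), function(s) {
    if (min(grid) < min(s$wavelength) || max(grid) > max(s$wavelength)) {
      abort(sprintf(
        "Grid [%g, %g] outside data range [%g, %g]; no extrapolation (use pad_sensitivity() for sensitivity curves).",
        min(grid), max(grid), min(s$wavelength), max(s$wavelength)))
    }
    v <- approx(s$wavelength, s$value, xout = grid, method = "linear")$y
    out <- s[rep(1L, length(grid)), keys, drop = FALSE]
    out$wavelength <- grid
    out$value <- v
    out
  })
  tibble::as_tibble(dplyr::bind_rows(pieces))
}

#' Pad a sensitivity curve over an uncovered wavelength region
#'
#' Digitised photoreceptor sensitivities often start at 330 nm while the
#' visual model needs 300--700 nm; the conventional fix is to set the
#' sensitivity over 300--330 nm to zero. This fills `from`--`to` with
#' `value` on the spectrum's own grid spacing.
#'
#' @param spectra Long spectra tibble of kind `"sensitivity"`.
#' @param from,to Region limits in nm.
#' @param value Fill value (default 0).
#' @param overwrite If `FALSE` (default), a region overlapping existing
#'   support (beyond a shared boundary point) is an error.
#'
#' @return The padded spectra on the union grid.
#' @export
pad_sensitivity <- function(spectra, from = 300, to = 330, value = 0,
                            overwrite = FALSE) {
  if ("kind" %in% names(spectra) && any(spectra$kind != "sensitivity")) {
    abort("pad_sensitivity() expects sensitivity curves.")
  }
  keys <- spc_key_cols(spectra)
  pieces <- lapply(spc_split(spectra), function(s) {
    step <- median(diff(s$wavelength))
    region <- seq(from, to, by = step)
    existing <- intersect(region, s$wavelength)
    if (length(existing) > 1 && !overwrite) {
      abort("Pad region overlaps existing support; set `overwrite = TRUE` to replace.")
    }
    if (overwrite) {
      inside <- s$wavelength >= from & s$wavelength <= to
      s$value[inside] <- value
    }
    add_wl <- setdiff(region, s$wavelength)
    if (length(add_wl) > 0) {
      add <- s[rep(1L, length(add_wl)), keys, drop = FALSE]
      add$wavelength <- add_wl
      add$value <- value
      s <- dplyr::bind_rows(s, add)
    }
    dplyr::arrange(s, .data$wavelength)
  })
  tibble::as_tibble(dplyr::bind_rows(pieces))
}

#' Triangular smoothing of spectra
#'
#' Moving weighted average with a symmetric triangular kernel of total base
#' `width` nanometres (weights maximal at the centre, decaying linearly to
#' zero at half the base width), renormalised to unit mass near the
#' boundaries. The default 30 nm attenuates spectrometer noise before
#' visual modelling. Requires a uniform grid.
#'
#' @param spectra Long spectra tibble on a uniform grid.
#' @param width Kernel base width in nm (default 30).
#'
#' @return Smoothed spectra. If `width` is smaller than two grid steps the
#'   input is returned unchanged with a warning.
#' @export
smooth_triangular <- function(spectra, width = 30) {
  if (width <= 0) abort("`width` must be positive.")
  keys <- spc_key_cols(spectra)
  pieces <- lapply(spc_split(spectra), function(s) {
    d <- diff(s$wavelength)
    step <- d[1]
    if (any(abs(d - step) > 1e-8)) {
      abort("smooth_triangular() requires a uniform wavelength grid; regrid first.")
    }
    if (width < 2 * step) {
      warn("Smoothing width smaller than two grid steps; returning input unchanged.")
      return(s)
    }
    half <- width / 2
    m <- floor(half / step)
    offs <- (-m):m
    w <- pmax(0, 1 - abs(offs) * step / half)
    w <- w / sum(w)
    n <- nrow(s)
    x <- s$value
    sm <- numeric(n)
    for (i in seq_len(n)) {
      j <- i + offs
      ok <- j >= 1 & j <= n
      sm[i] <- sum(w[ok] * x[j[ok]]) / sum(w[ok])
    }
    s$value <- sm
    s
  })
  tibble::as_tibble(dplyr::bind_rows(pieces))
}

#' Per-egg manifest of averaged spectra
#'
#' @param averaged Output of [average_replicates()].
#' @return A tibble with one row per egg: egg id, clutch id, number of
#'   measurements averaged.
#' @export
spectra_manifest <- function(averaged) {
  dplyr::distinct(
    averaged,
    dplyr::across(dplyr::any_of(c("egg_id", "clutch_id", "n_averaged")))
  )
}
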