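write_wide <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

test_that("wide files parse into one spectrum per column with header metadata", {
  path <- write_wide(tibble::tibble(
    wl = c(400, 401, 402),
    e1_c1_blunt_1 = c(0.1, 0.2, 0.3),
    e1_c1_blunt_2 = c(0.2, 0.3, 0.4)
  ))
  sp <- read_spectra(path, dialect = "wide", kind = "reflectance")
  expect_equal(dplyr::n_distinct(sp$id), 2)
  expect_setequal(unique(sp$egg_id), "e1")
  expect_setequal(unique(sp$position), "blunt")
  expect_equal(sort(unique(sp$replicate)), c(1L, 2L))
  expect_equal(sp$value[sp$id == "e1_c1_blunt_1"], c(0.1, 0.2, 0.3))
})

test_that("long dialect and descending/non-numeric inputs behave per contract", {
  long <- tibble::tibble(id = "e1_c1_m_1", wavelength = c(400, 401),
                         value = c(0.1, 0.2))
  p1 <- write_wide(long)
  sp <- read_spectra(p1, dialect = "long", kind = "reflectance")
  expect_equal(nrow(sp), 2)

  desc <- tibble::tibble(wl = c(700, 500, 300), a_b_m_1 = c(0.1, 0.2, 0.3))
  expect_error(read_spectra(write_wide(desc), "wide", "reflectance"),
               "increasing")

  bad <- tibble::tibble(wl = c("400", "x"), a_b_m_1 = c("0.1", "0.2"))
  expect_error(read_spectra(write_wide(bad), "wide", "reflectance"),
               "Non-numeric")
})

test_that("percent-scale reflectance is auto-detected and rescaled", {
  pct <- tibble::tibble(wl = 400:402, a_b_m_1 = c(5, 50, 95))
  sp <- read_spectra(write_wide(pct), "wide", "reflectance")
  expect_equal(sp$value, c(0.05, 0.50, 0.95))
  # proportion-scale data left alone
  prop <- tibble::tibble(wl = 400:402, a_b_m_1 = c(0.05, 0.5, 0.95))
  sp2 <- read_spectra(write_wide(prop), "wide", "reflectance")
  expect_equal(sp2$value, c(0.05, 0.50, 0.95))
  # override wins over detection
  sp3 <- read_spectra(write_wide(prop), "wide", "reflectance",
                      unit = "percent")
  expect_equal(sp3$value, c(0.0005, 0.005, 0.0095))
})

test_that("replicate averaging is a pointwise mean, permutation-invariant", {
  grid <- 400:410
  mk <- function(egg, rep, vals) {
    tibble::tibble(egg_id = egg, clutch_id = "c1", replicate = rep,
                   wavelength = grid, value = vals)
  }
  nine <- dplyr::bind_rows(lapply(1:9, function(r) mk("e1", r, rep(0.3, 11))))
  avg <- average_replicates(nine)
  expect_equal(avg$value, rep(0.3, 11))
  expect_equal(unique(avg$n_averaged), 9L)

  two <- dplyr::bind_rows(mk("e1", 1, rep(0.2, 11)), mk("e1", 2, rep(0.4, 11)))
  expect_equal(average_replicates(two)$value, rep(0.3, 11))

  set.seed(42)
  noisy <- dplyr::bind_rows(lapply(1:500, function(r) {
    mk("e1", r, 0.3 + rnorm(11, 0, 0.05))
  }))
  avg_n <- average_replicates(noisy)
  expect_true(all(abs(avg_n$value - 0.3) < 4 * 0.05 / sqrt(500)))

  shuffled <- noisy[sample(nrow(noisy)), ]
  expect_equal(average_replicates(shuffled)$value, avg_n$value)
})

test_that("averaging refuses mismatched grids within a group", {
  a <- tibble::tibble(egg_id = "e1", clutch_id = "c1", replicate = 1,
                      wavelength = 400:405, value = 0.1)
  b <- tibble::tibble(egg_id = "e1", clutch_id = "c1", replicate = 2,
                      wavelength = 500:505, value = 0.1)
  expect_error(average_replicates(dplyr::bind_rows(a, b)), "regrid")
})

test_that("regridding interpolates linearly, round-trips, and never extrapolates", {
  s <- tibble::tibble(egg_id = "e1", wavelength = c(400, 500),
                      value = c(0, 1))
  out <- regrid_spectra(s, c(450))
  expect_equal(out$value, 0.5)

  knots <- tibble::tibble(egg_id = "e1",
                          wavelength = c(400, 420, 460, 500),
                          value = c(0.1, 0.5, 0.2, 0.9))
  fine <- regrid_spectra(knots, seq(400, 500, by = 1))
  back <- regrid_spectra(fine, knots$wavelength)
  expect_equal(back$value, knots$value, tolerance = 1e-12)

  same <- regrid_spectra(knots, knots$wavelength)
  expect_equal(same$value, knots$value)
  twice <- regrid_spectra(regrid_spectra(knots, 400:500), 400:500)
  expect_equal(twice, regrid_spectra(knots, 400:500))

  expect_error(regrid_spectra(knots, 300:500), "outside")
})

test_that("sensitivity padding fills 300-330 nm with zeros and guards overlap", {
  s <- tibble::tibble(receptor = "LWS", kind = "sensitivity",
                      wavelength = 330:700,
                      value = exp(-(330:700 - 557)^2 / 5000))
  padded <- pad_sensitivity(s, 300, 330, value = 0)
  expect_equal(range(padded$wavelength), c(300, 700))
  below <- padded$value[padded$wavelength < 330]
  expect_true(all(below == 0))
  expect_equal(sum(padded$value[padded$wavelength >= 300 &
                                  padded$wavelength <= 330][-31]), 0)
  expect_error(pad_sensitivity(padded, 300, 330), "overlap")
  over <- pad_sensitivity(padded, 300, 340, value = 0, overwrite = TRUE)
  expect_true(all(over$value[over$wavelength <= 340] == 0))
})

test_that("triangular smoothing has unit-mass kernel and preserves structure", {
  grid <- 300:700
  const <- tibble::tibble(egg_id = "e1", wavelength = grid, value = 0.42)
  expect_equal(smooth_triangular(const, 30)$value, rep(0.42, length(grid)))

  spike <- tibble::tibble(egg_id = "e1", wavelength = grid,
                          value = as.numeric(grid == 500))
  sm <- smooth_triangular(spike, 30)
  expect_equal(sum(sm$value), 1, tolerance = 1e-9)  # mass conserved
  nz <- sm$wavelength[sm$value > 0]
  expect_true(all(nz >= 485 & nz <= 515))           # base ~30 nm
  expect_equal(sm$value[sm$wavelength == 500], max(sm$value))
  # symmetric, linearly decaying wings
  expect_equal(sm$value[sm$wavelength == 495], sm$value[sm$wavelength == 505])
  expect_gt(sm$value[sm$wavelength == 499], sm$value[sm$wavelength == 490])

  ramp <- tibble::tibble(egg_id = "e1", wavelength = grid,
                         value = (grid - 300) / 400)
  smr <- smooth_triangular(ramp, 30)
  interior <- smr$wavelength >= 320 & smr$wavelength <= 680
  expect_equal(smr$value[interior], ramp$value[interior], tolerance = 1e-12)

  # values stay inside the input envelope
  set.seed(7)
  rough <- tibble::tibble(egg_id = "e1", wavelength = grid,
                          value = runif(length(grid)))
  smx <- smooth_triangular(rough, 30)
  expect_true(all(smx$value >= min(rough$value) - 1e-12))
  expect_true(all(smx$value <= max(rough$value) + 1e-12))

  expect_warning(out <- smooth_triangular(const, 1.5), "unchanged")
  expect_equal(out$value, const$value)
})
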