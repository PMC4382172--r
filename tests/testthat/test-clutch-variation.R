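test_that("proportional catches normalise single-cone catches to one", {
  q <- tibble::tibble(egg_id = c("a", "b"), clutch_id = c("c1", "c2"),
                      Q_UVS = c(1, 2), Q_SWS = c(1, 4), Q_MWS = c(1, 6),
                      Q_LWS = c(1, 8), Q_A = c(2, 14))
  p <- proportional_catches(q)
  expect_equal(unlist(p[1, paste0("Pr_", c("UVS", "SWS", "MWS", "LWS"))]),
               c(Pr_UVS = 0.25, Pr_SWS = 0.25, Pr_MWS = 0.25, Pr_LWS = 0.25))
  expect_equal(rowSums(p[, paste0("Pr_", c("UVS", "SWS", "MWS", "LWS"))]),
               c(1, 1), tolerance = 1e-9)
  q0 <- q; q0[1, 3:6] <- 0
  expect_error(proportional_catches(q0), "All-zero")
})

test_that("random proportional catches always sum to one", {
  set.seed(3)
  for (i in 1:50) {
    q <- tibble::tibble(egg_id = "e", Q_UVS = runif(1), Q_SWS = runif(1),
                        Q_MWS = runif(1), Q_LWS = runif(1), Q_A = runif(1))
    p <- proportional_catches(q)
    expect_equal(sum(p[1, paste0("Pr_", c("UVS", "SWS", "MWS", "LWS"))]), 1,
                 tolerance = 1e-9)
  }
})

make_pairs <- function(n_eggs, clutch_of = NULL) {
  if (is.null(clutch_of)) clutch_of <- rep("c1", n_eggs)
  ids <- sprintf("e%02d", seq_len(n_eggs))
  idx <- utils::combn(n_eggs, 2)
  tibble::tibble(
    egg_a = ids[idx[1, ]], egg_b = ids[idx[2, ]],
    clutch_a = clutch_of[idx[1, ]], clutch_b = clutch_of[idx[2, ]],
    same_clutch = clutch_of[idx[1, ]] == clutch_of[idx[2, ]],
    ds = runif(ncol(idx)), dl = runif(ncol(idx))
  )
}

test_that("disjoint pairing uses each egg once and is seed-deterministic", {
  set.seed(1)
  p4 <- make_pairs(4)
  sel <- sample_disjoint_pairs(p4, seed = 10)
  expect_equal(nrow(sel), 2)
  expect_equal(sort(c(sel$egg_a, sel$egg_b)), sprintf("e%02d", 1:4))

  # 70 eggs -> 35 disjoint comparisons
  p70 <- make_pairs(70, rep(sprintf("c%02d", 1:23), length.out = 70))
  sel70 <- sample_disjoint_pairs(p70, seed = 4)
  expect_equal(nrow(sel70), 35)
  expect_equal(anyDuplicated(c(sel70$egg_a, sel70$egg_b)), 0)

  # odd pool: floor(e/2) pairs
  p5 <- make_pairs(5)
  expect_equal(nrow(sample_disjoint_pairs(p5, seed = 2)), 2)

  expect_identical(sample_disjoint_pairs(p70, seed = 99),
                   sample_disjoint_pairs(p70, seed = 99))
  expect_identical(
    sample_disjoint_pairs(p70, seed = 99, strategy = "balanced"),
    sample_disjoint_pairs(p70, seed = 99, strategy = "balanced"))
  expect_equal(nrow(sample_disjoint_pairs(p70[0, ], seed = 1)), 0)
})

test_that("balanced pairing represents every clutch within, rest between", {
  set.seed(2)
  clutches <- rep(sprintf("c%02d", 1:6), each = 4)
  p <- make_pairs(24, clutches)
  sel <- sample_disjoint_pairs(p, seed = 3, strategy = "balanced")
  expect_equal(nrow(sel), 12)
  expect_equal(anyDuplicated(c(sel$egg_a, sel$egg_b)), 0)
  expect_equal(sum(sel$same_clutch), 6)   # one within pair per clutch
  expect_equal(sum(!sel$same_clutch), 6)
})

test_that("welch_oneway matches the brute-force formulas and the t-test identity", {
  set.seed(5)
  g <- list(rnorm(8, 0, 1), rnorm(12, 0.5, 2), rnorm(6, 1, 0.5))
  df <- tibble::tibble(y = unlist(g),
                       grp = rep(c("a", "b", "c"), vapply(g, length, 1)))
  wt <- welch_oneway(df, y, grp)
  oracle <- welch_brute(g)
  expect_equal(wt$statistic, oracle$F, tolerance = 1e-10)
  expect_equal(wt$df1, oracle$df1)
  expect_equal(wt$df2, oracle$df2, tolerance = 1e-10)
  expect_equal(wt$p.value, oracle$p, tolerance = 1e-10)

  # k = 2: F equals the squared Welch t, df2 the Welch-Satterthwaite df
  x <- rnorm(9, 0, 1); y <- rnorm(14, 0.8, 2.5)
  df2 <- tibble::tibble(v = c(x, y),
                        g = rep(c("x", "y"), c(length(x), length(y))))
  wt2 <- welch_oneway(df2, v, g)
  tt <- welch_two_sample(x, y)
  expect_equal(wt2$statistic, tt$t^2, tolerance = 1e-10)
  expect_equal(wt2$df2, tt$df, tolerance = 1e-10)

  # identical group means -> F = 0
  same <- tibble::tibble(v = rep(c(1, 2, 3), 2),
                         g = rep(c("a", "b"), each = 3))
  expect_equal(welch_oneway(same, v, g)$statistic, 0)

  # guards
  expect_error(welch_oneway(tibble::tibble(v = 1:4, g = "a"), v, g), "two groups")
  zv <- tibble::tibble(v = c(1, 1, 1, 2, 3, 4),
                       g = rep(c("a", "b"), each = 3))
  expect_error(welch_oneway(zv, v, g), "zero variance")
})

test_that("classical equal-variance ANOVA option approaches Welch for balanced data", {
  set.seed(8)
  n <- 200
  df <- tibble::tibble(v = c(rnorm(n, 0, 1), rnorm(n, 0.2, 1)),
                       g = rep(c("a", "b"), each = n))
  fw <- welch_oneway(df, v, g)$statistic
  fc <- welch_oneway(df, v, g, var_equal = TRUE)$statistic
  expect_equal(fw, fc, tolerance = 0.02)
})

test_that("tidy and glance methods return one-row summaries", {
  wt <- welch_oneway(iris, Sepal.Length, Species)
  td <- tidy(wt)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "df1", "df2", "p.value", "method"))
  expect_equal(glance(wt), td)
})

test_that("clutch_variation_report assembles the full table", {
  raw <- simulate_egg_spectra(n_clutches = 6, eggs_per_clutch = 3,
                              replicates = 3, grid = wl_grid(300, 700, 5),
                              between_sd = 12, within_sd = 2, seed = 21)
  sm <- smooth_triangular(average_replicates(raw), 30)
  rs <- toy_receptors()
  rep <- clutch_variation_report(sm, rs, seed = 9)
  expect_equal(rep$response,
               c("UVS", "SWS", "MWS", "LWS", "Achrom",
                 "Chrom JNDs", "Chrom JNDs"))
  expect_true(all(rep$p.value >= 0 & rep$p.value <= 1, na.rm = TRUE))
  expect_true(all(rep$df2 %% 1 != 0, na.rm = TRUE))  # Welch: non-integer den. df
  expect_equal(attr(rep, "n_eggs"), 18)
  expect_equal(attr(rep, "n_clutches"), 6)
  # strong between-clutch structure: between mean JND above within mean
  jnd <- rep[rep$response == "Chrom JNDs", ]
  expect_gt(jnd$mean[jnd$group == "between"], jnd$mean[jnd$group == "within"])

  one_clutch <- dplyr::mutate(sm, clutch_id = "c01")
  expect_error(clutch_variation_report(one_clutch, rs), "two clutches")
})
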