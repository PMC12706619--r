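test_that("bland_altman on a constant offset and a hand-computed pair", {
  manual <- c(0.25, 0.28, 0.30, 0.33, 0.36)
  ba <- bland_altman(manual + 0.01, manual)
  expect_equal(ba$bias, 0.01)
  expect_equal(ba$sd, 0)
  expect_equal(ba$loa_low, 0.01)
  expect_equal(ba$loa_high, 0.01)
  expect_equal(ba$mae, 0.01)
  expect_identical(ba$n, 5L)

  # differences {+0.02, -0.02}: sd with the n-1 denominator
  ba2 <- bland_altman(c(0.32, 0.28), c(0.30, 0.30))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, sqrt((0.02^2 + 0.02^2) / 1))
  expect_equal(ba2$loa_high, 1.96 * 0.0282842712474619, tolerance = 1e-10)
  expect_equal(ba2$loa_low, -ba2$loa_high)
  expect_equal(ba2$mae, 0.02)

  expect_error(bland_altman(1:3, 1:4), "length")
  expect_error(bland_altman(1, 2), "at least 2")
  expect_error(bland_altman(c(1, NA), c(1, 2)), "finite")
})

test_that("pairing is positional: permuting one vector changes the statistics", {
  set.seed(4)
  manual <- runif(8, 0.25, 0.4)
  auto <- manual + rnorm(8, 0.005, 0.01)
  f <- bland_altman(auto, manual)
  r <- bland_altman(auto, rev(manual))
  # the bias (a difference of means) is permutation-invariant by algebra,
  # but the spread and absolute error of the pairing are not
  expect_equal(r$bias, f$bias)
  expect_false(isTRUE(all.equal(f$sd, r$sd)))
  expect_false(isTRUE(all.equal(f$mae, r$mae)))
})

test_that("bland_altman is antisymmetric under swapping the methods", {
  set.seed(9)
  a <- runif(20); b <- a + rnorm(20, 0.01, 0.02)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(r$bias, -f$bias)
  expect_equal(r$sd, f$sd)
  expect_equal(r$loa_low, -f$loa_high)
  expect_equal(r$loa_high, -f$loa_low)
  expect_equal(r$mae, f$mae)
})

test_that("pearson_r on exact lines, a hand case, and degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(x, rep(2, 4)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  # invariance under positive affine rescaling
  set.seed(2)
  y <- rnorm(15); z <- rnorm(15)
  expect_equal(pearson_r(3 * y + 7, z), pearson_r(y, z))
})

test_that("wilcoxon signed-rank matches hand enumeration on tiny inputs", {
  # differences {+1, +2, +3}: W = 6, p = 2/8
  w <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(w$statistic, 6)
  expect_equal(w$p_two_sided, 0.25)
  expect_identical(w$method, "exact")

  # tied magnitudes {+1, -1}: mid-ranks give W = 1.5, p = 1
  w2 <- wilcoxon_signed_rank(c(1, 0), c(0, 1))
  expect_equal(w2$statistic, 1.5)
  expect_equal(w2$p_two_sided, 1)

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "length")
})

test_that("exact p equals full enumeration; normal approximation is close", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0, 2), 1)
    d <- d[d != 0]
    if (length(d) < 2) next
    w <- wilcoxon_signed_rank(d, rep(0, length(d)))
    o <- oracle_wilcoxon_enum(d)
    expect_equal(w$statistic, o$W)
    expect_equal(w$p_two_sided, o$p, tolerance = 1e-12)
  }
  set.seed(8)
  d12 <- round(rnorm(12, 0.3, 1), 2)
  d12 <- d12[d12 != 0]
  exact <- wilcoxon_signed_rank(d12, rep(0, length(d12)))
  expect_equal(exact$p_two_sided,
               oracle_wilcoxon_enum(d12)$p, tolerance = 1e-12)
  approx <- wilcoxon_signed_rank(d12, rep(0, length(d12)), exact_limit = 5)
  expect_identical(approx$method, "normal_approx")
  expect_lte(abs(approx$p_two_sided - exact$p_two_sided), 0.02)
})

test_that("tie-free exact p agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    d <- sample(1:20, n) * sample(c(-1, 1), n, replace = TRUE)  # no ties
    w <- wilcoxon_signed_rank(d, rep(0, length(d)))
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(w$statistic, unname(ref$statistic))
    expect_equal(w$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("covariate screen flags perfect dependence and clears identical groups", {
  age <- seq(60, 90, length.out = 40)
  scr <- covariate_bias_screen(0.001 * age, data.frame(age = age))
  expect_equal(scr$stat, 1, tolerance = 1e-12)
  expect_lt(scr$p, 1e-10)

  sex <- rep(c(0, 1), each = 20)
  err <- rep(c(0.01, 0.02, 0.03, 0.04), 10)   # identical distribution per group
  scr2 <- covariate_bias_screen(err, data.frame(sex = sex))
  expect_identical(scr2$type, "binary")
  expect_equal(scr2$stat, 0)
  expect_equal(scr2$p, 1)
})

test_that("covariate screen keeps its type-I error near the nominal level", {
  set.seed(42)
  reject <- replicate(200, {
    err <- abs(rnorm(200, 0, 0.01))
    age <- runif(200, 55, 90)
    covariate_bias_screen(err, data.frame(age = age))$p < 0.05
  })
  expect_gte(mean(reject), 0.02)
  expect_lte(mean(reject), 0.09)
})

test_that("perturbation_report output contract and the all-equal degenerate case", {
  cases <- sprintf("c%02d", 1:6)
  grid <- expand.grid(case_id = cases, axis = c("pitch", "yaw"),
                      angle_deg = c(-10, 10), stringsAsFactors = FALSE)
  study <- rbind(
    transform(grid, mode = "blind", ei = 0.3, ei_baseline = 0.3),
    transform(grid, mode = "corrected", ei = 0.3, ei_baseline = 0.3))
  rep <- perturbation_report(study)
  expect_identical(names(rep),
                   c("axis", "angle_deg", "median_abs_err", "iqr", "W", "p",
                     "monotone_axis"))
  expect_true(all(rep$median_abs_err == 0))
  expect_true(all(rep$monotone_axis))
  expect_true(all(is.na(rep$p)))   # all-zero differences: test degenerate

  f <- tempfile(fileext = ".csv")
  utils::write.csv(rep, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), nrow(rep))
})

test_that("simulated pairs recover injected agreement parameters", {
  sim <- simulate_paired_measurements(190, 0.0068, 0.0112, seed = 1)
  ba <- bland_altman(sim$auto, sim$manual)
  expect_lte(abs(ba$bias - 0.0068), 3 * 0.0112 / sqrt(190))
  sim0 <- simulate_paired_measurements(50, 0.004, 0, seed = 2)
  ba0 <- bland_altman(sim0$auto, sim0$manual)
  expect_equal(ba0$bias, 0.004)
  expect_equal(ba0$sd, 0)
})
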