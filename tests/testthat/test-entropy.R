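# Regularity metrics against brute-force oracles, closed-form cases and
# asymptotic properties.

test_that("coarse-graining averages non-overlapping blocks", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  x <- rnorm(100)
  expect_identical(coarse_grain(x, 1), x)
  expect_length(coarse_grain(rnorm(2560), 14), 182)
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))  # tail dropped
  expect_error(coarse_grain(1:10, 0), "positive")
})

test_that("sample entropy matches the brute-force template counter", {
  x <- rep(c(1, -1), 5)
  expect_equal(sample_entropy(x, m = 2, r_frac = 0.5),
               oracle_sample_entropy(x, 2, 0.5 * sd(x)), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:5) {
    y <- rnorm(150 + 10 * i)
    expect_equal(sample_entropy(y, 2, 0.2),
                 oracle_sample_entropy(y, 2, 0.2 * sd(y)), tolerance = 1e-10)
    expect_equal(sample_entropy(y, 3, 0.3),
                 oracle_sample_entropy(y, 3, 0.3 * sd(y)), tolerance = 1e-10)
  }
  expect_equal(sample_entropy(rep(5, 50), 2), 0)  # all templates match
  # no matches at all -> undefined, reported missing
  expect_warning(v <- sample_entropy(c(0, 1e6, -1e6, 2e6, -2e6, 3e6, -3e6, 4e6),
                                     m = 2, r = 1e-12), "undefined")
  expect_true(is.na(v))
})

test_that("permutation entropy counts ordinal patterns correctly", {
  x <- c(4, 7, 9, 10, 6, 11, 3)
  # 6 motifs of length 2: 4 ascents, 2 descents -> H = H(2/3, 1/3)
  h_expected <- -(4 / 6) * log2(4 / 6) - (2 / 6) * log2(2 / 6)
  expect_equal(permutation_entropy(x, m = 2, normalized = FALSE), h_expected,
               tolerance = 1e-12)
  expect_equal(h_expected, 0.9182958, tolerance = 1e-6)
  expect_equal(permutation_entropy(x, m = 2, normalized = FALSE),
               oracle_permutation_entropy(x, 2, normalized = FALSE),
               tolerance = 1e-12)
  expect_equal(permutation_entropy(1:500, m = 3), 0)   # single pattern
  set.seed(32)
  for (i in 1:5) {
    y <- rnorm(120)
    expect_equal(permutation_entropy(y, 3, 1),
                 oracle_permutation_entropy(y, 3, 1), tolerance = 1e-10)
    expect_equal(permutation_entropy(y, 4, 2),
                 oracle_permutation_entropy(y, 4, 2), tolerance = 1e-10)
  }
  set.seed(33)
  expect_gt(permutation_entropy(runif(1e5), m = 3), 0.99)
  expect_error(permutation_entropy(rnorm(100), m = 8), "not supported")
})

test_that("dispersion entropy matches the brute-force symbolizer", {
  x8 <- c(0, 1, 0, 1, 2, 2, 1, 0)
  expect_equal(dispersion_entropy(x8, m = 2, c = 2, map = "linear"),
               oracle_dispersion_entropy(x8, 2, 2, "linear"), tolerance = 1e-12)
  expect_equal(dispersion_entropy(rep(3, 40), m = 2, c = 6), 0)
  set.seed(34)
  for (i in 1:5) {
    y <- rnorm(180)
    expect_equal(dispersion_entropy(y, 2, 6, "NCDF"),
                 oracle_dispersion_entropy(y, 2, 6, "NCDF"), tolerance = 1e-10)
    expect_equal(dispersion_entropy(y, 3, 4, "linear"),
                 oracle_dispersion_entropy(y, 3, 4, "linear"), tolerance = 1e-10)
  }
  set.seed(35)
  expect_gt(dispersion_entropy(rnorm(2e5), 2, 6, normalized = TRUE), 0.98)
})

test_that("multiscale curves reduce to mono-scale values at scale 1", {
  set.seed(36)
  x <- rnorm(600)
  p <- complexity_params(scales = c(1, 2, 5))
  ms <- multiscale(x, "PE", p)
  expect_equal(unname(ms["s1"]),
               permutation_entropy(x, p$pe_m, p$pe_tau))
  ms_se <- multiscale(x, "SE", p)
  expect_equal(unname(ms_se["s1"]), sample_entropy(x, p$se_m, p$se_r))
  ms_de <- multiscale(x, "DE", p)
  expect_equal(unname(ms_de["s1"]),
               dispersion_entropy(x, p$de_m, p$de_c, p$de_map))
  # too-short coarse series yield missing values, not errors
  short <- multiscale(rnorm(60), "SE", complexity_params(scales = c(1, 14)))
  expect_true(is.na(short["s14"]))
})

test_that("white-noise multiscale sample entropy declines with scale", {
  set.seed(37)
  p <- complexity_params(scales = c(1, 3, 6))
  curves <- replicate(50, multiscale(rnorm(600), "SE", p))
  m <- rowMeans(curves)
  expect_true(all(diff(m) < 0))
})

test_that("metrics are invariant to offset, and to scale where claimed", {
  set.seed(38)
  x <- rnorm(300)
  expect_equal(sample_entropy(x + 100, 2, 0.2), sample_entropy(x, 2, 0.2))
  expect_equal(permutation_entropy(x + 100, 3), permutation_entropy(x, 3))
  expect_equal(dispersion_entropy(x + 100, 2, 6), dispersion_entropy(x, 2, 6))
  expect_equal(higuchi_fd(x + 100), higuchi_fd(x))
  # positive rescaling: PE and SE (r proportional to SD) unchanged
  expect_equal(permutation_entropy(3.7 * x, 3), permutation_entropy(x, 3))
  expect_equal(sample_entropy(3.7 * x, 2, 0.2), sample_entropy(x, 2, 0.2))
})
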