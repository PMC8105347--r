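test_that("a centered circle is a pure first harmonic", {
  for (r in c(1, 2.5)) {
    ef <- efourier(circle_outline(r, 360), 5)
    expect_equal(ef$a[1], r, tolerance = 1e-4)
    expect_equal(ef$d[1], r, tolerance = 1e-4)
    expect_lt(abs(ef$b[1]), 1e-10)
    expect_lt(abs(ef$c[1]), 1e-10)
    expect_gt(harmonic_power(ef)$cumulative[1], 0.9999)
  }
})

test_that("ellipse coefficients match a numeric-integration oracle", {
  # oracle: Fourier integrals of the curvilinear-abscissa parameterization
  # of x = 2 cos t, y = sin t, by dense trapezoid quadrature
  th <- seq(0, 2 * pi, length.out = 200001)
  x <- 2 * cos(th); y <- sin(th)
  ds <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(ds)); P <- s[length(s)]
  mid <- function(v) (v[-1] + v[-length(v)]) / 2
  sm <- mid(s)
  oracle <- function(f, w) 2 / P * sum(f * w(2 * pi * sm / P) * ds)
  a1 <- oracle(mid(x), cos); b1 <- oracle(mid(x), sin)
  c1 <- oracle(mid(y), cos); d1 <- oracle(mid(y), sin)
  a3 <- 2 / P * sum(mid(x) * cos(3 * 2 * pi * sm / P) * ds)

  keep <- seq(1, 200000, by = 10)
  r <- resample_outline(outline(cbind(x[keep], y[keep])), 360, check = FALSE)
  ef <- efourier(r, 5)
  expect_equal(ef$a[1], a1, tolerance = 1e-3)
  expect_equal(ef$b[1], b1, tolerance = 1e-6)
  expect_equal(ef$c[1], c1, tolerance = 1e-6)
  expect_equal(ef$d[1], d1, tolerance = 1e-3)
  expect_equal(ef$a[3], a3, tolerance = 1e-2)
  # arc-length parameterization concentrates power in harmonic 1, with a
  # small odd-harmonic remainder characteristic of the 2:1 ellipse
  pw <- harmonic_power(ef)
  expect_gt(pw$cumulative[1], 0.99)
  expect_equal(pw$power[2], 0, tolerance = 1e-10)
})

test_that("coefficients round-trip through reconstruction at protocol sampling", {
  row <- smooth_row5()
  for (k in c(360, 2000)) {
    shp <- inverse_efourier(row_to_eft(row), k = k)
    ef <- efourier(shp, 5)
    rec <- c(ef$a, ef$b, ef$c, ef$d)
    expect_lt(max(abs(rec - row) / abs(row)), 1e-3)
  }
})

test_that("harmonic count limits and degenerate coefficients error", {
  o <- circle_outline(1, 30)
  expect_error(efourier(o, 16), "points/2")
  z <- row_to_eft(rep(0, 20))
  expect_error(harmonic_power(z), "zero")
})

test_that("translation only moves the center terms", {
  set.seed(7)
  row <- smooth_row5()
  shp <- inverse_efourier(row_to_eft(row), k = 360)
  shifted <- seedmorph:::transform_outline(shp, translate = c(3.2, -1.7))
  e1 <- efourier(shp, 5); e2 <- efourier(shifted, 5)
  expect_equal(c(e2$a, e2$b, e2$c, e2$d), c(e1$a, e1$b, e1$c, e1$d),
               tolerance = 1e-10)
  expect_equal(e2$a0, e1$a0 + 3.2, tolerance = 1e-10)
  expect_equal(e2$c0, e1$c0 - 1.7, tolerance = 1e-10)
})

test_that("a single-harmonic reconstruction is an exact ellipse", {
  row <- smooth_row5()
  o <- inverse_efourier(row_to_eft(row), k = 200, H_use = 1)
  p <- unclass(o)
  A <- cbind(p[, 1]^2, p[, 1] * p[, 2], p[, 2]^2, p[, 1], p[, 2], 1)
  sv <- svd(A)$d
  expect_lt(sv[6] / sv[1], 1e-6)  # conic fit residual
})

test_that("truncation error decreases monotonically with harmonics used", {
  set.seed(12)
  row8 <- c(0.45, -0.04, 0.02, -0.015, 0.010, -0.006, 0.004, -0.003,
            0.02, 0.03, -0.02, 0.012, -0.008, 0.005, -0.004, 0.002,
            -0.02, 0.04, 0.02, -0.012, 0.009, -0.005, 0.003, -0.002,
            0.50, 0.03, -0.02, 0.010, -0.007, 0.004, -0.003, 0.002)
  cf <- row_to_eft(row8)
  full <- unclass(inverse_efourier(cf, k = 720, H_use = 8))
  errs <- vapply(1:7, function(H) {
    sqrt(mean((unclass(inverse_efourier(cf, k = 720, H_use = H)) - full)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("cumulative power fractions and the retention rule are arithmetic", {
  # powers (8, 1, 0.5, 0.5): realized with a = sqrt(2 * power), b = c = d = 0
  cf <- structure(list(a = sqrt(2 * c(8, 1, 0.5, 0.5)), b = rep(0, 4),
                       c = rep(0, 4), d = rep(0, 4), a0 = 0, c0 = 0,
                       H = 4L, perimeter = NA_real_), class = "eft")
  pw <- harmonic_power(cf)
  expect_equal(pw$cumulative, c(0.8, 0.9, 0.95, 1.0))
  expect_equal(choose_harmonics(list(cf), 0.95)$H_star, 3L)

  only1 <- structure(list(a = c(2, 0, 0), b = rep(0, 3), c = rep(0, 3),
                          d = c(2, 0, 0), a0 = 0, c0 = 0, H = 3L,
                          perimeter = NA_real_), class = "eft")
  expect_equal(harmonic_power(only1)$cumulative, rep(1, 3))
  expect_equal(choose_harmonics(list(only1), 0.999)$H_star, 1L)
  expect_error(choose_harmonics(list(cf), 1.5), "threshold")
})

test_that("a 5-harmonic synthetic population retains at most 5 harmonics", {
  pop <- simulate_population(fixed_taxon(n_seeds = 12, coeff_sd = 0.01,
                                         length_logsd = 0.05,
                                         width_logsd = 0.05),
                             noise_spec(0.05, 0.003, 0.005, seed = 3),
                             render = FALSE)
  res <- resample_from_ldk2(pop)
  cfs <- lapply(res, efourier, H = 8)
  expect_lte(choose_harmonics(cfs, 0.95)$H_star, 5L)
})

test_that("total power is stable against a high-harmonic reference", {
  row <- smooth_row5()
  shp <- inverse_efourier(row_to_eft(row), k = 720)
  p5 <- sum(harmonic_power(efourier(shp, 5))$power)
  p40 <- sum(harmonic_power(efourier(shp, 40))$power)
  expect_equal(p5, p40, tolerance = 1e-6)
})

test_that("coefficient tables lay out column-major by letter and round-trip", {
  row <- smooth_row5()
  cf <- row_to_eft(row)
  mat <- coeff_matrix(list(s1 = cf, s2 = cf))
  expect_equal(colnames(mat),
               c(paste0("a", 1:5), paste0("b", 1:5),
                 paste0("c", 1:5), paste0("d", 1:5)))
  back <- row_to_eft(mat[1, ])
  expect_equal(back$a, cf$a)
  expect_equal(back$d, cf$d)
  f <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(mat, f)
  head1 <- readLines(f, n = 1)
  expect_match(head1, "^\"?id\"?,\"?a1\"?")
})
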