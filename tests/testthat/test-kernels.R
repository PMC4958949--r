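test_that("shear_spec normalizes and validates", {
  s <- shear_spec(45)
  expect_equal(s$u^2 + s$v^2, 1, tolerance = 1e-12)
  s2 <- shear_spec(u = 3, v = 4)
  expect_equal(c(s2$u, s2$v), c(0.6, 0.8))
  expect_error(shear_spec(u = 0, v = 0), "nonzero")
})

test_that("gaussian derivative kernel has the symmetries and zero sum of a Gaussian x-derivative", {
  k <- make_gaussian_derivative(0.5, shear_spec(0), half_width = 2)
  v <- k$values
  # antisymmetric under x -> -x (columns), symmetric under y -> -y (rows)
  expect_equal(v, -v[, ncol(v):1], tolerance = 1e-12)
  expect_equal(v, v[nrow(v):1, ], tolerance = 1e-12)
  expect_lt(abs(sum(v)), 1e-12)
  # zero-sum holds for any sigma/shear
  for (sg in c(0.5, 1, 2)) for (ang in c(0, 45, 90)) {
    kk <- make_gaussian_derivative(sg, shear_spec(ang))
    expect_lt(abs(sum(kk$values)), 1e-12)
  }
  expect_error(make_gaussian_derivative(-1, shear_spec(0)), "positive")
  expect_error(make_gaussian_derivative(2, shear_spec(0), half_width = 2),
               "half_width")
})

test_that("gaussian derivative matches a numerical derivative of the closed-form Gaussian", {
  # oracle: differentiate the shifted 2D Gaussian w.r.t. the shift along
  # the shear, by central differences of the closed form
  sigma <- 0.5; hw <- 2
  for (ang in c(0, 45)) {
    sh <- shear_spec(ang)
    k <- make_gaussian_derivative(sigma, sh, hw)
    gauss <- function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
    h <- 1e-6
    # d/dh G(p - h u) at h = 0, sampled at p, by central differences
    oracle <- outer(-hw:hw, -hw:hw, function(y, x)
      (gauss(x - h * sh$u, y - h * sh$v) - gauss(x + h * sh$u, y + h * sh$v)) /
        (2 * h))
    expect_equal(k$values, oracle, tolerance = 1e-6)
  }
})

test_that("dirac difference places +1/-1 at +/-offset and kills constants", {
  k <- make_dirac_difference(shear_spec(0), offset = 1)
  v <- k$values
  expect_identical(sum(v != 0), 2L)
  expect_equal(v[2, 3], 1)   # (+1, 0): +shear side
  expect_equal(v[2, 1], -1)  # (-1, 0)
  expect_equal(sum(v), 0)
  const <- matrix(3.7, 16, 16)
  expect_equal(simulate_dic(const, k), matrix(0, 16, 16), tolerance = 1e-14)
  expect_error(make_dirac_difference(shear_spec(0), offset = 5, half_width = 2),
               "offset larger")
})

test_that("dirac difference (offset 1) approximates the sigma = 0.5 gaussian derivative", {
  for (ang in c(0, 90)) {
    kd <- make_dirac_difference(shear_spec(ang), offset = 1)
    kg <- make_gaussian_derivative(0.5, shear_spec(ang),
                                   half_width = kd$half_width + 1)
    vd <- as.vector(dicrecon:::embed_kernel(kd$values, kg$half_width))
    expect_gt(stats::cor(vd, as.vector(kg$values)), 0.9)
  }
  # on the diagonal the unit offset falls between pixels; the bilinear
  # spread still correlates positively but the fine-sigma match is looser
  kd <- make_dirac_difference(shear_spec(45), offset = 1)
  kg <- make_gaussian_derivative(0.5, shear_spec(45), half_width = 2)
  expect_gt(stats::cor(as.vector(dicrecon:::embed_kernel(kd$values, 2)),
                       as.vector(kg$values)), 0.5)
})

test_that("sub-pixel dirac offsets interpolate bilinearly and stay zero-sum", {
  k <- make_dirac_difference(shear_spec(0), offset = 0.5, half_width = 1)
  expect_equal(sum(k$values), 0)
  # +1 at x = 0.5 splits equally between x = 0 and x = 1
  expect_equal(k$values[2, 2], 0)      # overlapping +/- cancel at center
  expect_equal(k$values[2, 3], 0.5)
  expect_equal(k$values[2, 1], -0.5)
})

test_that("integral kernel: forward difference along shear reproduces the psf interior", {
  for (ang in c(0, 45, 90, 135)) {
    for (kern in list(make_dirac_difference(shear_spec(ang)),
                      make_gaussian_derivative(0.8, shear_spec(ang), 3))) {
      k0 <- make_integral_kernel(kern)
      expect_identical(k0$half_width, kern$half_width + 2L)
      back <- kernel_from_integral(k0)
      expect_equal(back$values,
                   dicrecon:::embed_kernel(kern$values, k0$half_width),
                   tolerance = 1e-12)
      # first differences vanish along the entire boundary
      v <- k0$values; n <- nrow(v)
      boundary_diffs <- c(v[1, ] - v[2, ], v[n, ] - v[n - 1, ],
                          v[, 1] - v[, 2], v[, n] - v[, n - 1])
      expect_lt(max(abs(boundary_diffs)), 1e-12)
    }
  }
  expect_error(make_integral_kernel(matrix(1, 3, 3), shear_spec(0)),
               "derivative-type")
  z <- make_integral_kernel(matrix(0, 3, 3), shear_spec(0))
  expect_equal(max(abs(z$values)), 0)
})

test_that("kernel files round-trip", {
  k <- make_dirac_difference(shear_spec(0), offset = 1)
  txt <- withr::local_tempfile(fileext = ".txt")
  write_kernel(k, txt)
  expect_identical(load_kernel(txt)$values, k$values)  # text is exact
  kg <- make_gaussian_derivative(0.7, shear_spec(45))
  txt2 <- withr::local_tempfile(fileext = ".txt")
  write_kernel(kg, txt2)
  expect_equal(load_kernel(txt2)$values, kg$values, tolerance = 1e-15)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_kernel(kg, tif)
  # fixed-point TIFF storage: accurate to ~2^-32 of the dynamic range
  expect_lt(max(abs(load_kernel(tif)$values - kg$values)),
            1e-8 * diff(range(kg$values)))
  # even side length rejected
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3 4", "1 2 3 4", "1 2 3 4", "1 2 3 4"), bad)
  expect_error(load_kernel(bad), "odd")
})
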