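test_that("energy is zero at an exact fit and the TV term vanishes on constants", {
  k <- make_dirac_difference(shear_spec(45))
  ph <- square_phantom(24, 8, 17)
  g <- simulate_dic(ph, k)
  e <- energy(ph, g, k, lambda_tv = 0)
  expect_equal(unname(e["total"]), 0, tolerance = 1e-20)
  ec <- energy(matrix(2, 24, 24), g, k, lambda_tv = 0.5)
  expect_equal(unname(ec["tv"]), 0, tolerance = 1e-12)
  expect_error(energy(matrix(0, 5, 5), g, k), "mismatch")
})

test_that("data term of the energy matches the brute-force residual sum", {
  k <- make_gaussian_derivative(0.8, shear_spec(45), 3)
  i <- withr::with_seed(4, matrix(stats::rnorm(256), 16))
  g <- withr::with_seed(5, matrix(stats::rnorm(256), 16))
  e <- energy(i, g, k, lambda_tv = 0)
  expect_equal(unname(e["data"]),
               sum((oracle_correlate(i, k$values) - g)^2),
               tolerance = 1e-12)
})

test_that("all data-term schemes match finite differences of their energies", {
  k <- make_gaussian_derivative(0.8, shear_spec(45), 3)
  for (seed in 1:2) {
    i <- withr::with_seed(seed, matrix(stats::rnorm(256), 16))
    g <- withr::with_seed(seed + 10, matrix(stats::rnorm(256), 16))
    for (sc in c("kernel_form", "bilinear", "piecewise_constant")) {
      efn <- function(x) energy(x, g, k, lambda_tv = 0, scheme = sc)[["data"]]
      descent <- el_data_term(i, g, k, sc)
      fd <- oracle_fd_gradient(efn, i)
      expect_lt(max(abs(-descent - fd)) / max(abs(fd)), 1e-4)
    }
  }
})

test_that("TV descent term matches finite differences of the smoothed TV energy", {
  eps <- 1e-2
  for (seed in 1:2) {
    i <- withr::with_seed(seed, matrix(stats::rnorm(256), 16))
    efn <- function(x) {
      ix <- dicrecon:::correlate_mirror(x, dicrecon:::kern_dx())
      iy <- dicrecon:::correlate_mirror(x, dicrecon:::kern_dy())
      sum(sqrt(ix^2 + iy^2 + eps^2) - eps)
    }
    descent <- el_tv_term(i, eps)
    fd <- oracle_fd_gradient(efn, i)
    expect_lt(max(abs(-descent - fd)) / max(abs(fd)), 1e-4)
  }
  expect_equal(el_tv_term(matrix(5, 10, 10), 1e-3), matrix(0, 10, 10),
               tolerance = 1e-15)
})

test_that("data-term gradient vanishes at the exact solution", {
  # with the grid-exact impulse-pair kernel all three discretizations
  # realize the forward model exactly, so the true phantom is a stationary
  # point of each scheme's energy
  k <- make_dirac_difference(shear_spec(0), offset = 1)
  ph <- square_phantom(20, 6, 14, value = 2)
  g <- simulate_dic(ph, k)
  for (sc in c("kernel_form", "bilinear", "piecewise_constant"))
    expect_lt(max(abs(el_data_term(ph, g, k, sc))), 1e-8)
  # kernel_form is exact for the full sampled-Gaussian PSF as well
  kg <- make_gaussian_derivative(0.8, shear_spec(45), 3)
  g2 <- simulate_dic(ph, kg)
  expect_lt(max(abs(el_data_term(ph, g2, kg, "kernel_form"))), 1e-8)
})

test_that("the three schemes agree on a smooth low-frequency phantom", {
  n <- 32
  smooth <- outer(seq_len(n), seq_len(n), function(y, x)
    sin(2 * pi * x / n) + cos(2 * pi * y / n))
  k <- make_gaussian_derivative(1, shear_spec(45), 3)
  g <- simulate_dic(smooth, k)
  # a smooth, non-stationary evaluation point: all three discretizations
  # see the same low-frequency residual
  i0 <- 0.6 * smooth
  fields <- lapply(c("kernel_form", "bilinear", "piecewise_constant"),
                   function(sc) el_data_term(i0, g, k, sc))
  interior <- as.matrix(expand.grid(6:(n - 5), 6:(n - 5)))
  for (a in 1:2) for (b in (a + 1):3) {
    va <- fields[[a]][interior]; vb <- fields[[b]][interior]
    expect_gt(stats::cor(va, vb), 0.95)
  }
})

test_that("piecewise_constant rejects kernels without shear-axis symmetry", {
  k <- random_zero_sum_kernel(2, seed = 3)
  expect_error(el_data_term(matrix(0, 8, 8), matrix(0, 8, 8),
                            dicrecon:::new_kernel(k, shear_spec(0), "custom"),
                            "piecewise_constant"),
               "symmetry")
})

test_that("TV flow is edge-preserving where a Laplacian is not", {
  n <- 24
  edge <- matrix(0, n, n); edge[, 13:n] <- 100  # large-amplitude step
  eps <- 1e-2
  tv_resp <- el_tv_term(edge, eps)
  lap_resp <- dicrecon:::correlate_mirror(edge, dicrecon:::kern_laplace())
  edge_cols <- 12:13
  expect_gt(max(abs(lap_resp[, edge_cols])) /
              max(abs(tv_resp[, edge_cols])), 10)
})

test_that("proposed reconstruction recovers a noise-free phantom", {
  k <- make_dirac_difference(shear_spec(45))
  ph <- square_phantom(40, 12, 28)
  g <- simulate_dic(ph, k)
  rec <- reconstruct_proposed(g, k, variational_params(max_iter = 1200))
  np <- normalize_pair(rec, ph)
  expect_gt(pearson(np$recon, np$truth), 0.95)
  expect_true(all(rec$image >= 0))
  expect_true(all(diff(rec$trace$total) <= 1e-12))
})

test_that("zero contrast with TV gives a flat reconstruction", {
  k <- make_dirac_difference(shear_spec(45))
  rec <- reconstruct_proposed(matrix(0, 16, 16), k,
                              variational_params(lambda_tv = 0.5,
                                                 max_iter = 50))
  expect_equal(stats::sd(rec$image), 0, tolerance = 1e-12)
})

test_that("energy trace is monotone for both variational methods across fixtures", {
  k <- make_dirac_difference(shear_spec(45))
  fixtures <- list(
    simulate_dic(square_phantom(24, 8, 17), k),
    add_noise(simulate_dic(square_phantom(24, 8, 17), k), 20, seed = 1),
    simulate_dic(shape_mask_fixture(), k)
  )
  for (g in fixtures) {
    rp <- reconstruct_proposed(g, k, variational_params(max_iter = 150))
    expect_true(all(diff(rp$trace$total) <= 1e-12))
    rf <- reconstruct_feineigle(g, k, feineigle_params(max_iter = 150))
    expect_true(all(diff(rf$trace$total) <= 1e-12))
  }
})

test_that("background mask is binary, background-true on flat images, object-false near edges", {
  flat <- matrix(0.5, 20, 20)
  expect_equal(estimate_background_mask(flat), matrix(1, 20, 20))
  k <- make_dirac_difference(shear_spec(45))
  ph <- square_phantom(32, 12, 21)
  g <- simulate_dic(ph, k)
  b <- estimate_background_mask(g)
  expect_true(all(b %in% c(0, 1)))
  # the square's edges must be labelled object (mask 0)
  expect_lt(mean(b[11:22, 11:22]), 0.8)
  expect_gt(mean(b[c(1:5, 28:32), ]), 0.9)
})

test_that("feineigle: zero image is a fixed point and the perpendicular penalty flattens stripes", {
  k <- make_dirac_difference(shear_spec(0), offset = 1)
  p0 <- feineigle_params(mask = matrix(1, 16, 16), background_value = 0,
                         max_iter = 30)
  rec <- reconstruct_feineigle(matrix(0, 16, 16), k, p0)
  expect_equal(rec$image, matrix(0, 16, 16), tolerance = 1e-14)
  # noisy phantom: lambda1 penalizes variation perpendicular to the shear
  ph <- square_phantom(32, 12, 21)
  g <- add_noise(simulate_dic(ph, k), 10, seed = 9)
  with_pen <- reconstruct_feineigle(g, k, feineigle_params(lambda1 = 1,
                                                           max_iter = 400))
  without <- reconstruct_feineigle(g, k, feineigle_params(lambda1 = 0,
                                                          max_iter = 400))
  bg <- estimate_background_mask(g) == 1
  dn <- function(img) dicrecon:::correlate_mirror(img, dicrecon:::kern_dy())
  expect_lt(stats::var(dn(with_pen$image)[bg]),
            stats::var(dn(without$image)[bg]))
})
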