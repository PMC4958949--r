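test_that("normalize_pair clips negatives then scales both images to [0, 1]", {
  t_ <- matrix(runif(64), 8)
  np <- normalize_pair(t_, t_)
  expect_equal(np$recon, np$truth)
  r <- withr::with_seed(1, matrix(stats::rnorm(64), 8))
  np2 <- normalize_pair(r, t_)
  expect_equal(min(np2$recon), 0)
  expect_equal(max(np2$recon), 1)
  # positive affine transforms of the truth normalize identically
  np3 <- normalize_pair(r, 3.2 * t_ + 0.7)
  expect_equal(np3$truth, np2$truth, tolerance = 1e-12)
  expect_error(normalize_pair(matrix(-1, 4, 4), matrix(runif(16), 4)),
               "constant")
})

test_that("mse matches its definition and an explicit-loop oracle", {
  expect_equal(mse(matrix(1, 5, 5), matrix(1, 5, 5)), 0)
  expect_equal(mse(matrix(0, 3, 3), matrix(1, 3, 3)), 1)
  a <- withr::with_seed(2, matrix(stats::rnorm(30), 5, 6))
  b <- withr::with_seed(3, matrix(stats::rnorm(30), 5, 6))
  acc <- 0
  for (i in 1:5) for (j in 1:6) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(mse(a, b), acc / 30, tolerance = 1e-14)
  expect_error(mse(a, matrix(0, 2, 2)), "mismatch")
})

test_that("pearson matches the textbook formula and handles edge cases", {
  a <- withr::with_seed(4, matrix(stats::rnorm(50), 5, 10))
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, -a), -1)
  b <- withr::with_seed(5, matrix(stats::rnorm(50), 5, 10))
  av <- as.vector(a); bv <- as.vector(b)
  num <- sum((av - mean(av)) * (bv - mean(bv)))
  den <- sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(pearson(a, b), num / den, tolerance = 1e-14)
  expect_error(pearson(a, matrix(1, 5, 10)), "constant")
})

test_that("roc_auc hits the analytic extremes", {
  mask <- matrix(0, 8, 8); mask[3:6, 3:6] <- 1
  expect_equal(roc_auc(mask, mask)$auc, 1)
  expect_equal(roc_auc(1 - mask, mask)$auc, 0)
  expect_equal(roc_auc(matrix(0.5, 8, 8), mask)$auc, 0.5)
  expect_error(roc_auc(mask, matrix(1, 8, 8)), "single class")
  expect_error(roc_auc(mask, mask * 0.5), "binary")
})

test_that("roc_auc equals the Mann-Whitney formulation on brute-force instances", {
  for (s in 1:12) {
    vals <- withr::with_seed(s, {
      v <- stats::rnorm(64)
      if (s %% 2 == 0) v <- round(v * 2) / 2  # force ties
      matrix(v, 8)
    })
    mask <- withr::with_seed(s + 50, matrix(stats::rbinom(64, 1, 0.4), 8))
    if (sum(mask) == 0 || sum(mask) == 64) next
    r <- roc_auc(vals, mask)
    expect_equal(r$auc, oracle_auc_mann_whitney(as.vector(vals), as.vector(mask)),
                 tolerance = 1e-12)
    # curve endpoints and monotonicity of the sweep
    expect_equal(range(r$fpr), c(0, 1))
    expect_equal(range(r$tpr), c(0, 1))
    expect_true(all(diff(r$fpr) <= 0) || all(diff(r$fpr) >= 0))
  }
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  vals <- withr::with_seed(7, matrix(stats::rnorm(64), 8))
  mask <- withr::with_seed(8, matrix(stats::rbinom(64, 1, 0.5), 8))
  a0 <- roc_auc(vals, mask)$auc
  expect_equal(roc_auc(exp(2 * vals), mask)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(atan(vals) + 10, mask)$auc, a0, tolerance = 1e-12)
})

test_that("benchmark weights base shapes equally regardless of rotation count", {
  # hand-built set: shape A in 3 rotations (values favoring low error),
  # shape B once; the identity algorithm scores 0 everywhere
  k <- make_dirac_difference(shear_spec(0), offset = 1)
  gts <- list(square_phantom(16, 4, 9), square_phantom(16, 5, 10),
              square_phantom(16, 6, 11), square_phantom(16, 4, 12, value = 2))
  set <- structure(list(
    ground_truths = gts,
    dic_images = lapply(gts, simulate_dic, psf = k),
    labels = tibble::tibble(index = 1:4,
                            base_shape = c("A", "A", "A", "B"),
                            rotation_deg = c(0, 30, 60, 0),
                            mode = "binary"),
    psf = k, noise_db = Inf, seed = 1), class = "phantom_set")
  identity_alg <- list(ident = function(g) wiener_reconstruct(g, k, 1e-9))
  bm <- benchmark(set, identity_alg)
  # rotation-equal weighting: mean(mean(A1, A2, A3), B)
  per <- bm$per_image$value
  expect_equal(bm$summary$mean_value,
               mean(c(mean(per[1:3]), per[4])), tolerance = 1e-12)
  expect_error(benchmark(set, c("not_an_algorithm")), "unknown algorithm")
})

test_that("benchmark output ordering is deterministic and a perfect recon scores perfectly", {
  k <- make_dirac_difference(shear_spec(45))
  ps <- generate_shape_set(list(size = 24,
                                rotations_deg = c(0, 45),
                                shapes = c("ellipse", "rectangle")),
                           seed = 1)
  perfect <- list(oracle_identity = local({
    i <- 0
    function(g) { i <<- i + 1; ps$ground_truths[[i]] }
  }))
  bm <- benchmark(ps, perfect)
  expect_equal(bm$summary$mean_value, 0, tolerance = 1e-14)
  perfect2 <- list(oracle_identity = local({
    i <- 0
    function(g) { i <<- i + 1; ps$ground_truths[[i]] }
  }))
  bm_auc <- benchmark(ps, perfect2, metric = "auc")
  expect_equal(bm_auc$summary$mean_value, 1)
  expect_identical(bm$per_image$index, rep(seq_along(ps$ground_truths), 1))
})
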