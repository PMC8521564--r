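test_that("convolution matches hand values under both paddings", {
  ones <- matrix(1, 3, 3)
  Cz <- convolve_same(ones, padding = "zero")
  expect_equal(Cz[2, 2], 1)                # 5 - 4 interior
  expect_equal(Cz[1, 1], 3)                # 5 - 2 corner
  expect_equal(Cz[1, 2], 2)                # 5 - 3 edge middle
  # replicate padding leaves constants unchanged everywhere (kernel sum 1)
  expect_equal(convolve_same(ones), ones)
  expect_equal(convolve_same(matrix(2.5, 5, 5)), matrix(2.5, 5, 5))
  # impulse response reproduces the kernel
  imp <- matrix(0, 3, 3); imp[2, 2] <- 1
  expect_equal(convolve_same(imp, padding = "zero"), sharpen_kernel())
  expect_error(convolve_same(matrix(1, 2, 3)), "square")
})

test_that("convolution equals the brute-force double-sum oracle", {
  set.seed(5)
  w <- sharpen_kernel()
  for (rep in 1:8) {
    s <- sample(1:12, 1)
    A <- matrix(rnorm(s * s), s, s)
    for (pad in c("replicate", "zero"))
      expect_equal(convolve_same(A, w, padding = pad), oracle_conv(A, w, pad),
                   tolerance = 1e-12)
  }
})

test_that("ReLU rectifies, preserves shape and is idempotent", {
  expect_equal(relu(rbind(c(-1, 2), c(0, -3))), rbind(c(0, 2), c(0, 0)))
  set.seed(6)
  A <- matrix(rnorm(25), 5)
  expect_identical(relu(relu(A)), relu(A))
  B <- abs(A)
  expect_identical(relu(B), B)
})

test_that("max pooling matches hand values and the window-max oracle", {
  expect_equal(max_pool(rbind(c(1, 2), c(3, 4)), 2, 2), matrix(4, 1, 1))
  A3 <- matrix(1:9, 3, byrow = TRUE)
  expect_equal(max_pool(A3, 2, 2, mode = "ceil"), rbind(c(5, 6), c(8, 9)))
  set.seed(7)
  for (rep in 1:10) {
    s <- sample(2:9, 1)
    A <- matrix(rnorm(s * s), s, s)
    window <- sample(1:3, 1); stride <- sample(1:3, 1)
    expect_equal(max_pool(A, window, stride, mode = "ceil"),
                 oracle_pool(A, window, stride, "ceil"))
    if (window <= s)
      expect_equal(max_pool(A, window, stride, mode = "floor"),
                   oracle_pool(A, window, stride, "floor"))
  }
  expect_error(max_pool(A3, window = 0), "window")
  expect_error(max_pool(A3, stride = 0), "stride")
})

test_that("reduction follows the ceil-halving size trajectory of the case studies", {
  set.seed(8)
  R <- frp_from_partition(random_membership(897, 3))
  red <- reduce_to_cfrp(R, n = 2)
  expect_identical(red$size_trajectory,
                   c(897L, 449L, 225L, 113L, 57L, 29L, 15L, 8L, 4L, 2L))
  expect_equal(dim(red$matrix), c(2L, 2L))
  Rg <- frp_from_partition(random_membership(120, 3))
  expect_identical(reduce_to_cfrp(Rg, n = 2)$size_trajectory,
                   c(120L, 60L, 30L, 15L, 8L, 4L, 2L))
  # input already at the target size: zero iterations
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  red0 <- reduce_to_cfrp(A, n = 2)
  expect_identical(red0$matrix, A)
  expect_identical(red0$size_trajectory, 2L)
  expect_error(reduce_to_cfrp(A, n = 3), "smaller than target")
})

test_that("the size trajectory is strictly decreasing and terminates at n for every side", {
  # arithmetic of the ceil-halving map for every starting side up to 1000
  for (s in 2:1000) {
    traj <- s
    while (traj[length(traj)] > 2) traj <- c(traj, ceiling(traj[length(traj)] / 2))
    expect_true(all(diff(traj) < 0))
    expect_equal(traj[length(traj)], 2)
  }
  # and on real reductions for a spread of sides
  set.seed(9)
  for (s in c(2, 3, 5, 8, 13, 31, 64, 120)) {
    red <- reduce_to_cfrp(frp_from_partition(random_membership(s, 2)), n = 2)
    expect_true(all(diff(red$size_trajectory) < 0))
    expect_identical(red$size_trajectory[length(red$size_trajectory)], 2L)
  }
})

test_that("each reduction stage preserves symmetry and nonnegativity", {
  set.seed(10)
  A <- frp_from_partition(random_membership(33, 3))
  for (k in 1:4) {
    A <- convolve_same(A)
    expect_equal(max(abs(A - t(A))), 0)
    A <- relu(A)
    expect_true(all(A >= 0))
    A <- max_pool(A, 2, 2)
    expect_equal(max(abs(A - t(A))), 0)
  }
})

test_that("largest eigenvalue matches the 2x2 closed form and rejects asymmetry", {
  expect_equal(largest_eigenvalue(rbind(c(2, 1), c(1, 2)))$lambda_max, 3)
  expect_equal(largest_eigenvalue(diag(2))$lambda_max, 1)
  set.seed(11)
  for (rep in 1:20) {
    a <- rnorm(1); b <- rnorm(1); d <- rnorm(1)
    lam <- largest_eigenvalue(rbind(c(a, b), c(b, d)))$lambda_max
    expect_equal(lam, (a + d) / 2 + sqrt(((a - d) / 2)^2 + b^2),
                 tolerance = 1e-12)
  }
  expect_error(largest_eigenvalue(rbind(c(1, 2), c(0, 1))), "not symmetric")
})

test_that("lambda_max of a symmetric nonnegative matrix dominates its entry mean", {
  set.seed(12)
  for (rep in 1:15) {
    s <- sample(2:6, 1)
    A <- abs(random_symmetric(s))
    lam <- largest_eigenvalue(A)$lambda_max
    expect_gte(lam, 0)
    expect_gte(lam + 1e-12, mean(A) * s)   # Rayleigh quotient, all-ones vector
  }
})

test_that("the end-to-end recurrence eigenvalue is finite, nonnegative and seed-deterministic", {
  set.seed(13)
  s <- sin(2 * pi * 0.02 * (1:250)) + rnorm(250, sd = 0.1)
  r1 <- recurrence_eigenvalue(s, m = 4, tau = 1, c = 3, n = 2, seed = 21)
  r2 <- recurrence_eigenvalue(s, m = 4, tau = 1, c = 3, n = 2, seed = 21)
  expect_identical(r1$lambda_max, r2$lambda_max)     # bitwise
  expect_true(is.finite(r1$lambda_max) && r1$lambda_max >= 0)
  expect_identical(r1$size_trajectory[1], 247L)
})
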