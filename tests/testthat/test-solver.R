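test_that("objective value matches its definition and the stacked form", {
  g <- pfov_geometry(5, 3, 4)
  A <- make_forward(g)
  set.seed(2)
  b <- rnorm(A$n_rows)
  expect_equal(objective_value(numeric(A$n_cols), A, b, 0, 0, g), sum(b^2))
  expect_equal(objective_value(numeric(A$n_cols), A, numeric(A$n_rows), 0.3, 0.1, g), 0)
  rho <- rnorm(A$n_cols)
  sys <- stack_operators(A, 0.07, 0.02, b, g)
  o1 <- sum((map_apply(sys$T, rho) - sys$w)^2)
  o2 <- objective_value(rho, A, b, 0.07, 0.02, g)
  expect_lt(abs(o1 - o2) / o2, 1e-12)
  expect_error(objective_value(rnorm(3), A, b, 0, 0, g),
               class = "mpirecon_dimension_error")
})

test_that("non-negative projection is the closest non-negative point", {
  expect_equal(project_nonnegative(c(-1, 2, 0)), c(0, 2, 0))
  x <- c(3.5, 0, 2)
  expect_equal(project_nonnegative(project_nonnegative(x)), project_nonnegative(x))
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(10)
    px <- project_nonnegative(x)
    for (j in 1:10) {
      y <- pmax(rnorm(10), 0)
      expect_lte(sum((px - x)^2), sum((y - x)^2) + 1e-14)
    }
  }
})

test_that("power iteration recovers the largest squared singular value", {
  expect_lt(abs(lipschitz_estimate(identity_map(25)) - 1), 1e-6)
  two_diag <- linear_map(10, 10, function(x) 2 * x, function(y) 2 * y, "2I")
  expect_lt(abs(lipschitz_estimate(two_diag) - 4), 1e-6)

  g <- pfov_geometry(6, 3, 5)
  sys <- stack_operators(make_forward(g), 0.1, 0.04, numeric(make_forward(g)$n_rows), g)
  Lhat <- lipschitz_estimate(sys$T, power_iters = 1500, seed = 3)
  smax <- max(svd(materialize(sys$T, check_adjoint = FALSE))$d)
  expect_lt(abs(Lhat - smax^2) / smax^2, 1e-4)
  expect_error(lipschitz_estimate(identity_map(3), power_iters = 5),
               class = "mpirecon_config_error")
})

test_that("FISTA returns the zero image for zero data with Tikhonov weight", {
  g <- pfov_geometry(6, 3, 5)
  A <- make_forward(g)
  sys <- stack_operators(A, 0.2, 0.05, numeric(A$n_rows), g)
  fit <- fista_solve(sys, recon_config(alpha = 0.2, beta = 0.05, max_iters = 50))
  expect_equal(max(abs(fit$image)), 0)
  ref <- reference_solve(sys)
  expect_equal(max(abs(ref)), 0)
})

test_that("FISTA iterates are non-negative and do not increase the objective", {
  g <- pfov_geometry(8, 5, 6, transverse_shape = 4L)
  A <- make_forward(g)
  set.seed(14)
  b <- rnorm(A$n_rows)
  sys <- stack_operators(A, 0.05, 0.03, b, g)
  fit <- fista_solve(sys, recon_config(alpha = 0.05, beta = 0.03, max_iters = 200))
  expect_gte(min(fit$image), 0)
  expect_lte(fit$report$final_objective, fit$report$initial_objective)
  # monotone variant: objective non-increasing after the burn-in
  fitm <- fista_solve(sys, recon_config(alpha = 0.05, beta = 0.03, max_iters = 200,
                                        monotone = TRUE))
  tail_objs <- fitm$report$iterates[-(1:5)]
  expect_true(all(diff(tail_objs) <= 1e-10))
})

test_that("FISTA matches the projected-gradient reference on random instances", {
  set.seed(31)
  for (i in 1:5) {
    p <- sample(5:8, 1); s <- sample(2:(p - 1), 1); N <- sample(3:6, 1)
    g <- pfov_geometry(p, s, N)
    A <- make_forward(g)
    b <- rnorm(A$n_rows)
    alpha <- runif(1, 0.05, 0.2)
    sys <- stack_operators(A, alpha, runif(1, 0.01, 0.1), b, g)
    fit <- fista_solve(sys, recon_config(alpha = alpha, max_iters = 2000, seed = i))
    ref <- reference_solve(sys)
    of <- sum((map_apply(sys$T, as_image_vector(fit$image, g)) - sys$w)^2)
    or <- sum((map_apply(sys$T, as_image_vector(ref, g)) - sys$w)^2)
    expect_lt(abs(of - or) / or, 1e-6)
  }
})

test_that("unconstrained reference solve matches the normal equations", {
  g <- pfov_geometry(7, 4, 5)
  A <- make_forward(g)
  set.seed(6)
  b <- rnorm(A$n_rows)
  sys <- stack_operators(A, 0.1, 0.05, b, g)
  xu <- reference_solve(sys, nonneg = FALSE)
  Tm <- materialize(sys$T, check_adjoint = FALSE)
  xn <- solve(crossprod(Tm), as.numeric(crossprod(Tm, sys$w)))
  expect_lt(max(abs(xu - xn)), 1e-8)
  big <- pfov_geometry(30, 10, 10)   # n = 210 > guard
  sysb <- stack_operators(make_forward(big), 0.1, 0,
                          numeric(make_forward(big)$n_rows), big)
  expect_error(reference_solve(sysb), class = "mpirecon_size_error")
})

test_that("noiseless simulated data reconstructs the native image to under 1 percent", {
  g <- pfov_geometry(10, 5, 11, transverse_shape = 16L)
  nat <- edge_zero_native(g, seed = 3)
  stack <- simulate_partial_fovs(nat, g)
  sys <- stack_operators(make_forward(g), 1e-4, 1e-4, as.vector(stack), g)
  fit <- fista_solve(sys, recon_config(alpha = 1e-4, beta = 1e-4, max_iters = 3000))
  expect_lt(rel_rmse(fit$image, nat), 1e-2)
  expect_gte(min(fit$image), 0)
})

test_that("reconstruction error decreases with the noise level", {
  g <- pfov_geometry(10, 5, 9, transverse_shape = 10L)
  nat <- edge_zero_native(g, seed = 5)
  A <- make_forward(g)
  mean_rmse <- sapply(c(0.1, 0.03, 0.01), function(sg) {
    mean(sapply(1:10, function(s) {
      stack <- simulate_partial_fovs(nat, g, noise = noise_model(sg * max(nat), seed = 300 + s))
      sys <- stack_operators(A, 1e-3, 1e-3, as.vector(stack), g)
      fit <- fista_solve(sys, recon_config(alpha = 1e-3, beta = 1e-3, max_iters = 300))
      rel_rmse(fit$image, nat)
    }))
  })
  expect_true(all(diff(mean_rmse) < 0))
})

test_that("with no zero line pixels, recovery holds up to a constant and Tikhonov picks the smallest DC", {
  g <- pfov_geometry(10, 5, 9)
  x <- seq_len(g$image_shape[1])
  nat <- 0.5 + exp(-0.5 * ((x - 25) / 6)^2)     # strictly positive everywhere
  stack <- simulate_partial_fovs(nat, g)
  sys <- stack_operators(make_forward(g), 1e-5, 0, as.vector(stack), g)
  fit <- fista_solve(sys, recon_config(alpha = 1e-5, beta = 0, max_iters = 5000))
  offs <- mean(nat - fit$image)
  expect_lt(rel_rmse(fit$image + offs, nat), 1e-2)
  # the selected estimate has a smaller total DC than the truth
  expect_lt(sum(fit$image), sum(nat))
})
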