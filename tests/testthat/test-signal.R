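test_that("raw signal synthesis follows the position-velocity model", {
  g <- pfov_geometry(20, 15, 6)
  traj <- trajectory_for_geometry(g)
  # uniform tracer: the voltage is exactly the FFR velocity
  sig <- synthesize_signal_1d(rep(1, g$image_shape[1]), traj)
  expect_lt(max(abs(sig$samples - sig$velocities)), 1e-12)
  # empty image: pure feedthrough tone
  sig0 <- synthesize_signal_1d(numeric(g$image_shape[1]), traj, feedthrough_amp = 0.7)
  expect_lt(max(abs(sig0$samples -
                    0.7 * cos(2 * pi * traj$drive_frequency * sig0$times))), 1e-12)
  # trajectory exiting the image errors out
  expect_error(synthesize_signal_1d(rep(1, 30), traj), class = "mpirecon_config_error")
})

test_that("fundamental filtering rejects the tone and passes the harmonic band", {
  g <- pfov_geometry(20, 15, 6)
  traj <- trajectory_for_geometry(g)
  sig <- synthesize_signal_1d(numeric(g$image_shape[1]), traj, feedthrough_amp = 1)
  filt <- remove_fundamental(sig, 15)
  expect_lt(10 * log10(sum(filt$samples^2) / sum(sig$samples^2)), -60)

  f0 <- traj$drive_frequency
  harm <- cos(2 * pi * 2 * f0 * sig$times) + 0.4 * sin(2 * pi * 5 * f0 * sig$times)
  sig$samples <- harm
  passed <- remove_fundamental(sig, 15)
  expect_lt(max(abs(passed$samples - harm)), 1e-10)

  expect_error(remove_fundamental(sig, 1), class = "mpirecon_config_error")
  expect_error(remove_fundamental(sig, 1e6), class = "mpirecon_config_error")
})

test_that("velocity compensation normalizes by speed and masks turnarounds", {
  g <- pfov_geometry(20, 15, 6)
  traj <- trajectory_for_geometry(g)
  sig <- synthesize_signal_1d(rep(1, g$image_shape[1]), traj)
  comp <- velocity_compensate(sig, velocity_floor = 0.05)
  expect_lt(max(abs(comp$values[comp$valid] - 1)), 1e-12)
  slow <- abs(sig$velocities) < 0.05 * max(abs(sig$velocities))
  expect_true(any(slow))                       # stepped sweeps do turn around
  expect_true(all(!comp$valid[slow]))
  expect_error(velocity_compensate(sig, 0), class = "mpirecon_config_error")

  # compensated samples trace the native profile along the trajectory
  nat <- native_image(make_phantom("random_blobs", g$image_shape, seed = 2,
                                   edge_margin = 4),
                      psf_model("gaussian", 5, ndim = 1))
  sign <- synthesize_signal_1d(nat, traj)
  compn <- velocity_compensate(sign)
  ref <- approx(0:(g$image_shape[1] - 1), nat, xout = compn$positions[compn$valid],
                rule = 2)$y
  expect_lt(max(abs(compn$values[compn$valid] - ref)) / max(nat), 0.02)
})

test_that("gridding bin-averages, removes line means, and averages duplicates", {
  g1 <- pfov_geometry(20, 0, 1)
  ramp <- seq(0, 19)
  st <- grid_to_partial_fovs(rep(ramp, 3), rep(ramp, 3), g1)
  expect_lt(max(abs(st$values[, 1, 1] - (ramp - mean(ramp)))), 1e-12)

  # duplicates at one position are averaged, not summed
  vals <- c(seq(0, 19), 5)
  poss <- c(seq(0, 19), 3)
  st2 <- grid_to_partial_fovs(vals, poss, g1)
  raw <- seq(0, 19); raw[4] <- (3 + 5) / 2
  expect_lt(max(abs(st2$values[, 1, 1] - (raw - mean(raw)))), 1e-12)

  # output is never larger than the input sample count
  expect_lte(length(st$values), length(rep(ramp, 3)))

  expect_error(grid_to_partial_fovs(1:5, rep(100, 5), g1),
               class = "mpirecon_config_error")
})

test_that("bin averaging reduces white-noise levels as one over sqrt(k)", {
  gbig <- pfov_geometry(2000, 0, 1)
  sd_for_k <- function(k, seed) {
    set.seed(seed)
    n <- 2000L * k
    vals <- rnorm(n)
    poss <- rep(0:1999, k)
    sd(grid_to_partial_fovs(vals, poss, gbig)$values)
  }
  r <- sd_for_k(1, 5) / sd_for_k(16, 6)
  expect_lt(abs(r - 4) / 4, 0.10)
})

test_that("the full chain reproduces the operator simulation on smooth images", {
  g <- pfov_geometry(20, 15, 10)
  for (sd_ in c(7, 11)) {
    nat <- native_image(make_phantom("random_blobs", g$image_shape, n_blobs = 3,
                                     edge_margin = 5, seed = sd_),
                        psf_model("gaussian", fwhm = 6, ndim = 1))
    ref <- simulate_partial_fovs(nat, g)
    got <- process_signal_1d(nat, g, feedthrough_amp = 0.5)
    expect_lt(rel_rmse(got$values, ref$values), 0.03)
    expect_true(check_dc_free(got))
  }
})

test_that("a point source survives the chain with its peak in place", {
  g <- pfov_geometry(20, 15, 6)
  nat <- native_image(make_phantom("point", g$image_shape),
                      psf_model("gaussian", fwhm = 5, ndim = 1))
  got <- process_signal_1d(nat, g, feedthrough_amp = 0.2)
  rec <- stitch_1d_dc(got)
  expect_lte(abs(which.max(rec) - which.max(nat)), 1)
})
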