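test_that("radial_stats gives the population mean and SD", {
  # two points at distances 21 and 23: mean 22, population SD 1 (divisor N)
  pts <- rbind(c(21, 0, 0), c(-23, 0, 0))
  expect_equal(radial_stats(pts, c(0, 0, 0)), c(mean = 22, sd = 1))

  withr::local_seed(10)
  sphere <- rand_sphere_points(400, center = c(3, -2, 8), r = 22)
  expect_equal(radial_stats(sphere, c(3, -2, 8)),
               c(mean = 22, sd = 0), tolerance = 1e-12)

  noisy <- rand_sphere_points(10000, r = 22, sigma = 0.5)
  st <- radial_stats(noisy, c(0, 0, 0))
  expect_equal(unname(st["sd"]), 0.5, tolerance = 0.04)

  # agrees with an independent plain-R computation on irregular clouds
  blob <- matrix(rnorm(300, sd = 5), 100, 3)
  expect_equal(radial_stats(blob, c(1, 1, 1)), pop_stats(blob, c(1, 1, 1)),
               tolerance = 1e-12)
  expect_error(radial_stats(blob[1, , drop = FALSE], c(0, 0, 0)),
               class = "hipcongruity_validation_error")
})

test_that("noiseless sphere: center recovered to within grid quantization", {
  withr::local_seed(20)
  cen <- c(4, -7, 12)
  pts <- rand_sphere_points(600, center = cen, r = 22)
  fit <- fit_center_min_sd(pts, cen + c(3, 0, 0))
  expect_lt(sqrt(sum((fit$center - cen)^2)), 0.1 * sqrt(3))
  expect_lt(fit$sd, 0.05)
  expect_equal(fit$radius, 22, tolerance = 0.005)
  expect_true(fit$converged)
  expect_false(fit$aspherical)
})

test_that("descent matches the exhaustive brute-force oracle on small grids", {
  withr::local_seed(30)
  for (i in 1:8) {
    n <- sample(100:400, 1)
    cen <- rnorm(3, 0, 10)
    pts <- rand_sphere_points(n, center = cen, r = runif(1, 18, 28),
                              sigma = runif(1, 0, 0.4),
                              z_range = c(runif(1, -0.3, 0.2), 1))
    init <- cen + runif(3, -0.4, 0.4)
    step <- sample(c(0.25, 0.5), 1)
    fit <- fit_center_min_sd(pts, init, search_spec(range = 2, step = step),
                             schedule = "literal")
    oracle <- brute_force_min_sd(pts, init, range = 2, step = step)
    expect_equal(fit$center, oracle$center, tolerance = 1e-12)
    expect_equal(unname(fit$sd), oracle$sd, tolerance = 1e-9)
    expect_equal(unname(fit$radius), oracle$mean, tolerance = 1e-9)
  }
})

test_that("coarse-to-fine schedule lands on the literal descent fixed point", {
  withr::local_seed(31)
  for (i in 1:5) {
    cen <- rnorm(3, 0, 5)
    pts <- rand_sphere_points(400, center = cen, r = 23, sigma = 0.3,
                              z_range = c(-0.2, 1))
    init <- cen + runif(3, -2, 2)
    spec <- search_spec(range = 5, step = 0.25)
    lit <- fit_center_min_sd(pts, init, spec, schedule = "literal")
    ctf <- fit_center_min_sd(pts, init, spec, schedule = "coarse_to_fine")
    expect_equal(ctf$center, lit$center, tolerance = 1e-9)
    expect_equal(ctf$sd, lit$sd, tolerance = 1e-9)
  }
})

test_that("SD at the returned center never exceeds SD at the init", {
  withr::local_seed(32)
  for (i in 1:10) {
    pts <- rand_sphere_points(300, center = rnorm(3, 0, 10),
                              r = runif(1, 15, 30), sigma = runif(1, 0, 1),
                              z_range = c(runif(1, -1, 0.5), 1))
    init <- colMeans(pts) + runif(3, -3, 3)
    fit <- suppressWarnings(fit_center_min_sd(pts, init))
    expect_lte(fit$sd, pop_stats(pts, init)["sd"] + 1e-12)
  }
})

test_that("rigid-motion equivariance up to grid quantization", {
  withr::local_seed(33)
  cen <- c(2, 3, -4)
  pts <- rand_sphere_points(800, center = cen, r = 22, sigma = 0.2,
                            z_range = c(-0.17, 0.7))
  init <- cen + c(1.2, -0.8, 0.5)
  fit <- fit_center_min_sd(pts, init)
  R <- rand_rotation(); t0 <- c(30, -12, 55)
  fit2 <- fit_center_min_sd(sweep(pts %*% t(R), 2, t0, `+`),
                            as.numeric(R %*% init) + t0)
  expect_point_equal(fit2$center, as.numeric(R %*% fit$center) + t0,
                     tol = 0.1 * sqrt(3) + 1e-9)
  expect_equal(fit2$radius, fit$radius, tolerance = 0.01)
  expect_equal(fit2$sd, fit$sd, tolerance = 0.01)
})

test_that("large init offsets recover because the cube re-centers", {
  withr::local_seed(34)
  cen <- c(0, 0, 0)
  pts <- rand_sphere_points(500, center = cen, r = 25, z_range = c(0.1, 0.95))
  # 6 mm > one round's +/- 5 mm reach at default spec
  fit <- fit_center_min_sd(pts, cen + c(6, 0, 0))
  expect_lt(sqrt(sum((fit$center - cen)^2)), 0.1 * sqrt(3))
  # and a 4.8 mm offset with the default spec
  fit2 <- fit_center_min_sd(pts, cen + c(4.8, 0, 0))
  expect_lt(sqrt(sum((fit2$center - cen)^2)), 0.1 * sqrt(3))
})

test_that("classify_asphericity is strict at the threshold", {
  expect_true(classify_asphericity(list(sd = 1.2)))
  expect_false(classify_asphericity(list(sd = 0.0)))
  expect_false(classify_asphericity(list(sd = 1.0)))  # not "exceeded"
  expect_true(classify_asphericity(list(sd = 0.6), threshold = 0.5))
  expect_error(classify_asphericity(list(sd = 0.5), threshold = -1),
               class = "hipcongruity_validation_error")
})

test_that("fit_femoral_head: fovea outside ROI leaves the radius clean", {
  hip <- demo_hip(seed = 6)  # rf 22.7, fovea (15 deg, 2 mm), sigma 0
  fit <- fit_femoral_head(hip$femur)
  expect_equal(unname(fit$radius), 22.7, tolerance = 0.05 / 22.7)
  expect_false(fit$aspherical)
  # without the ROI the fovea contaminates the objective
  full <- fit_femoral_head(hip$femur, use_roi = FALSE)
  expect_gt(full$sd, fit$sd)
})

test_that("a cam bump below the caudal limit does not move the radius", {
  base <- demo_hip(seed = 8, cam = NULL)
  cam <- demo_hip(seed = 8, cam = c(-25, 40, 10, 2.5))  # below -10 deg...
  f0 <- fit_femoral_head(base$femur)
  f1 <- fit_femoral_head(cam$femur)
  # independent grid lattices: compare both to truth at the recovery bound
  expect_lt(abs(f0$radius - 22.7), 0.05)
  expect_lt(abs(f1$radius - 22.7), 0.05)
})

test_that("fit_acetabulum recovers an offset lunate sphere", {
  withr::local_seed(40)
  head_center <- c(0, 0, 0)
  acen <- head_center + c(2, 1, 1)
  pts <- rand_sphere_points(800, center = acen, r = 25.6,
                            z_range = c(sin(10 * pi / 180), 1))
  fit <- fit_acetabulum(pts, head_center)
  expect_lt(sqrt(sum((fit$center - acen)^2)), 0.1 * sqrt(3))
  expect_equal(unname(fit$radius), 25.6, tolerance = 0.05 / 25.6)
  expect_false(fit$aspherical)  # no asphericity rule for the acetabulum

  # removing a fossa-like polar cap only reduces N
  keep <- sweep(pts, 2, acen)[, 3] / 25.6 < sin(60 * pi / 180)
  fit2 <- fit_acetabulum(pts[keep, ], head_center)
  expect_equal(fit2$radius, fit$radius, tolerance = 0.005)
})

test_that("noisy parameter recovery is unbiased at the stated scale", {
  # 20 seeds, N = 2000, sigma = 0.3 mm
  rf_hat <- sd_hat <- numeric(20)
  for (s in 1:20) {
    hip <- generate_hip(synthetic_hip_spec(seed = s))
    fit <- fit_femoral_head(hip$femur)
    rf_hat[s] <- fit$radius; sd_hat[s] <- fit$sd
  }
  expect_lt(abs(mean(rf_hat) - 22.7), 0.1)
  expect_true(all(abs(sd_hat - 0.3) < 0.05))
})

test_that("a cam bump inside the ROI large enough to break sphericity flags the head", {
  # amplitude 4 mm over a 30 deg cap: SD at the true center ~1.4 mm
  hip <- generate_hip(synthetic_hip_spec(noise_sigma = 0,
                                         cam = c(17.5, 0, 30, 4), seed = 3))
  fit <- fit_femoral_head(hip$femur)
  expect_gt(fit$sd, 1.0)
  expect_true(fit$aspherical)
})

test_that("search_spec validates its fields", {
  expect_error(search_spec(step = 0), class = "hipcongruity_validation_error")
  expect_error(search_spec(range = 1, step = 2),
               class = "hipcongruity_validation_error")
  expect_error(search_spec(max_rounds = 0),
               class = "hipcongruity_validation_error")
  expect_warning(fit_center_min_sd(rand_sphere_points(10, r = 5), c(0, 0, 0)),
                 "fewer than 50")
})
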