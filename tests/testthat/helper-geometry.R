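# Shared fixtures and independent oracles. Everything here is built in code
# at test time; nothing touches the package's own estimators unless a test
# explicitly compares against them.

# Uniform random points on a sphere (optionally a latitude band) of radius r
# around center, with radial Gaussian noise. Independent of the package's
# Fibonacci-lattice generator.
rand_sphere_points <- function(n, center = c(0, 0, 0), r = 22,
                               sigma = 0, z_range = c(-1, 1)) {
  z <- runif(n, z_range[1], z_range[2])
  phi <- runif(n, 0, 2 * pi)
  rho <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(rho * cos(phi), rho * sin(phi), z)
  rr <- r + rnorm(n, 0, sigma)
  sweep(d * rr, 2, center, `+`)
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Independent brute-force oracle: exhaustively enumerate the step-spaced
# cube of half-width `range` around `init`, compute the population SD of
# point distances in plain R, and apply the stated tie-break (smallest SD,
# then smallest displacement from init, then lexicographic (x,y,z) offset
# order, which is the enumeration order here).
brute_force_min_sd <- function(points, init, range, step) {
  h <- round(range / step)
  best <- NULL
  for (i in -h:h) for (j in -h:h) for (k in -h:h) {
    cand <- init + c(i, j, k) * step
    d <- sqrt((points[, 1] - cand[1])^2 + (points[, 2] - cand[2])^2 +
              (points[, 3] - cand[3])^2)
    m <- mean(d)
    sdv <- sqrt(mean(d^2) - m^2)
    disp2 <- i^2 + j^2 + k^2
    if (is.null(best) || sdv < best$sd ||
        (sdv == best$sd && disp2 < best$disp2)) {
      best <- list(center = cand, sd = sdv, mean = m, disp2 = disp2)
    }
  }
  best
}

# Population SD in plain R (oracle for radial_stats).
pop_stats <- function(points, center) {
  d <- sqrt(rowSums(sweep(points, 2, center)^2))
  c(mean = mean(d), sd = sqrt(mean((d - mean(d))^2)))
}

# A small noiseless hip used by several files.
demo_hip <- function(seed = 5, sigma = 0, ...) {
  generate_hip(synthetic_hip_spec(noise_sigma = sigma, seed = seed, ...))
}

expect_point_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(sqrt(sum((actual - expected)^2)), tol)
}

# Two-decimal half-up rounding, written out independently of the package's
# internal helper.
round_half_up_test <- function(x) floor(x * 100 + 0.5) / 100
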