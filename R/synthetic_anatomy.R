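# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Quasi-uniform unit directions: golden-angle (Fibonacci) spiral lattice in
# (z, azimuth), plus seeded jitter of up to `jitter` of one lattice cell.
# With z restricted to [z_lo, z_hi] the sample is quasi-uniform on that
# spherical band (area element is uniform in z).
fib_band <- function(n, z_lo = -1, z_hi = 1, jitter = 0.5) {
  i <- seq_len(n)
  u <- (i - 0.5) / n + runif(n, -jitter, jitter) / n
  z <- z_lo + pmin(1, pmax(0, u)) * (z_hi - z_lo)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden + runif(n, -jitter, jitter) * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Orthonormal basis with third column w.
basis_from_axis <- function(w) {
  w <- w / sqrt(sum(w^2))
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * w) * w
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2] * e1[3] - w[3] * e1[2],
          w[3] * e1[1] - w[1] * e1[3],
          w[1] * e1[2] - w[2] * e1[1])
  cbind(e1, e2, w)
}

# von Mises-Fisher sample on the unit sphere around mean direction mu.
rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  u <- runif(n)
  w <- if (kappa < 1e-8) 2 * u - 1 else
    1 + log(u * (1 - exp(-2 * kappa)) + exp(-2 * kappa)) / kappa
  theta <- runif(n, 0, 2 * pi)
  rho <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(rho * cos(theta), rho * sin(theta), w)
  local %*% t(basis_from_axis(mu))
}

# Map anatomical (lateral, anterior, inferior) components to world
# coordinates for a given side and axis convention.
anat_to_world <- function(v_anat, side, frame = "RAI") {
  M <- axis_convention(frame)
  s <- if (side == "right") 1 else -1
  as.numeric(t(M) %*% c(v_anat[1] * s, v_anat[2], v_anat[3]))
}

#' Specification of one synthetic hip
#'
#' Parametric ground truth for a simulated hip: a spherical femoral head of
#' radius `rf` with a flat-bottomed fovea indentation at the cranial pole
#' and a neck frustum below -30 deg latitude; a lunate band of the
#' `ra`-sphere whose curvature center sits at `offset` (mm, anatomical
#' ML/PA/SI components) from the head center, with a fossa cap removed; and
#' optionally a cam bump at the head-neck junction. Gaussian radial noise of
#' SD `noise_sigma` perturbs every surface point.
#'
#' Defaults describe a borderline-dysplastic hip: head radius 22.7 mm,
#' acetabular radius 25.6 mm, center discrepancy 3.2 mm directed
#' lateral-anterior-inferior in proportions (0.69, 0.53, 0.23), fovea cap 15
#' deg / 2 mm deep, fossa cap 30 deg, lunate band 10-90 deg latitude on the
#' acetabular sphere (the bony cup is close to a hemisphere, its central
#' ~60 deg cone occupied by the non-articular fossa), 0.3 mm radial noise
#' (segmentation-scale jitter for 1 mm CT slices).
#'
#' @param rf femoral head radius of curvature, mm.
#' @param ra acetabular radius of curvature, mm.
#' @param offset length-3 vector, acetabular center minus head center, mm,
#'   in anatomical (ML = +lateral, PA = +anterior, SI = +inferior)
#'   components.
#' @param noise_sigma radial Gaussian noise SD, mm.
#' @param fovea `c(half_angle_deg, depth_mm)` or `NULL` for none.
#' @param cam `c(lat_deg, lon_deg, half_angle_deg, amplitude_mm)` or `NULL`:
#'   a flat-topped radial bump centered at the given head latitude/azimuth.
#' @param fossa cap half-angle in degrees removed from the lunate pole.
#' @param lunate_extent `c(lo, hi)` latitude range in degrees of the
#'   acetabular band (pole = cup axis).
#' @param n_head target number of head-sphere sample points (>= 100).
#' @param n_lunate target number of lunate band points before fossa removal
#'   (>= 100).
#' @param neck_axis length-3 direction of the head's cranial pole in
#'   anatomical components (default points medial-superior, a neutral neck
#'   orientation).
#' @param side `"left"` or `"right"`.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_hip_spec`.
#' @export
synthetic_hip_spec <- function(rf = 22.7, ra = 25.6,
                               offset = 3.2 * c(0.69, 0.53, 0.23) /
                                 sqrt(sum(c(0.69, 0.53, 0.23)^2)),
                               noise_sigma = 0.3,
                               fovea = c(15, 2), cam = NULL, fossa = 30,
                               lunate_extent = c(10, 90),
                               n_head = 2000L, n_lunate = 1500L,
                               neck_axis = c(-0.5, 0, -0.866),
                               side = "right", seed = 1L) {
  if (!is.finite(rf) || !is.finite(ra) || rf <= 0 || ra <= 0)
    abort_validation("rf and ra must be positive")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    abort_validation("noise_sigma must be non-negative")
  if (n_head < 100L || n_lunate < 100L)
    abort_validation("point counts must be at least 100")
  if (!is.null(fovea) && (length(fovea) != 2L || fovea[1] <= 0 || fovea[2] < 0))
    abort_validation("fovea must be c(half_angle_deg, depth_mm)")
  if (!is.null(cam) && length(cam) != 4L)
    abort_validation("cam must be c(lat, lon, half_angle, amplitude)")
  if (length(lunate_extent) != 2L || lunate_extent[1] >= lunate_extent[2] ||
      lunate_extent[1] < -90 || lunate_extent[2] > 90)
    abort_validation("lunate_extent must be an increasing range within [-90, 90]")
  structure(list(rf = rf, ra = ra, offset = as_point3(offset, "offset"),
                 noise_sigma = noise_sigma, fovea = fovea, cam = cam,
                 fossa = as.numeric(fossa), lunate_extent = lunate_extent,
                 n_head = as.integer(n_head), n_lunate = as.integer(n_lunate),
                 neck_axis = as_point3(neck_axis, "neck_axis") /
                   sqrt(sum(neck_axis^2)),
                 side = check_side(side), seed = as.integer(seed)),
            class = "synthetic_hip_spec")
}

#' Generate one synthetic hip
#'
#' Builds femoral and coxal surface models from a [synthetic_hip_spec()],
#' with region labels ("head" and "neck" on the femur, "lunate" on the coxal
#' bone) and a ground-truth record carrying every generating parameter plus
#' the true centers in world coordinates. Same seed, same clouds.
#'
#' The femoral head occupies latitudes above -30 deg of the `rf`-sphere; the
#' fovea is a flat indentation (points moved to `rf - depth`) inside its
#' polar cap; the cam, when present, a flat radial bump. The neck is a
#' tapered frustum continuing below -30 deg. The lunate is a latitude band
#' of the `ra`-sphere around the cup axis (taken parallel to the head's
#' polar axis) with the fossa cap removed.
#'
#' @param spec a [synthetic_hip_spec()].
#' @return list with `femur` and `coxal` ([surface_model()]s) and `truth`
#'   (list of ground-truth parameters).
#' @export
generate_hip <- function(spec) {
  stopifnot(inherits(spec, "synthetic_hip_spec"))
  with_seed(spec$seed, {
    w <- anat_to_world(spec$neck_axis, spec$side)     # cranial pole, world
    head_center <- c(0, 0, 0)
    acet_center <- head_center + anat_to_world(spec$offset, spec$side)
    B <- basis_from_axis(w)                            # cols e1, e2, w

    # --- femoral head: band lat >= -30 deg of the rf-sphere ---------------
    z_lo <- sin(-30 * pi / 180)
    dirs_local <- fib_band(spec$n_head, z_lo, 1)
    dirs <- dirs_local %*% t(B)
    lat <- asin(pmin(1, pmax(-1, dirs_local[, 3]))) * 180 / pi
    r <- rep(spec$rf, spec$n_head)
    if (!is.null(spec$fovea)) {
      polar_ang <- 90 - lat                            # degrees from pole
      r[polar_ang < spec$fovea[1]] <- spec$rf - spec$fovea[2]
    }
    if (!is.null(spec$cam)) {
      cl <- spec$cam[1] * pi / 180; co <- spec$cam[2] * pi / 180
      cam_dir_local <- c(cos(cl) * cos(co), cos(cl) * sin(co), sin(cl))
      ang <- acos(pmin(1, pmax(-1, dirs_local %*% cam_dir_local))) * 180 / pi
      r[ang < spec$cam[3]] <- r[ang < spec$cam[3]] + spec$cam[4]
    }
    if (spec$noise_sigma > 0) r <- r + rnorm(spec$n_head, 0, spec$noise_sigma)
    head_pts <- sweep(dirs * r, 2L, head_center, `+`)

    # --- neck frustum below the head, along -w ----------------------------
    n_neck <- max(100L, round(spec$n_head / 4))
    t_ax <- spec$rf * 0.5 + (seq_len(n_neck) - 0.5) / n_neck * 15
    rho <- spec$rf * (0.75 - 0.2 * (t_ax - spec$rf * 0.5) / 15)
    if (spec$noise_sigma > 0) rho <- rho + rnorm(n_neck, 0, spec$noise_sigma)
    phi <- seq_len(n_neck) * pi * (3 - sqrt(5)) + runif(n_neck, 0, 0.1)
    neck_pts <- sweep(cbind(rho * cos(phi), rho * sin(phi), -t_ax) %*% t(B),
                      2L, head_center, `+`)

    femur <- surface_model(rbind(head_pts, neck_pts), side = spec$side,
                           labels = list(head = seq_len(spec$n_head),
                                         neck = spec$n_head + seq_len(n_neck)))

    # --- lunate band of the ra-sphere, fossa cap removed ------------------
    zb <- sin(spec$lunate_extent * pi / 180)
    lun_local <- fib_band(spec$n_lunate, zb[1], zb[2])
    lun_lat <- asin(pmin(1, pmax(-1, lun_local[, 3]))) * 180 / pi
    keep <- (90 - lun_lat) >= spec$fossa
    lun_local <- lun_local[keep, , drop = FALSE]
    n_lun <- nrow(lun_local)
    rl <- rep(spec$ra, n_lun)
    if (spec$noise_sigma > 0) rl <- rl + rnorm(n_lun, 0, spec$noise_sigma)
    lun_pts <- sweep((lun_local %*% t(B)) * rl, 2L, acet_center, `+`)
    coxal <- surface_model(lun_pts, side = spec$side,
                           labels = list(lunate = seq_len(n_lun)))

    truth <- list(rf = spec$rf, ra = spec$ra,
                  ratio = spec$ra / spec$rf,
                  head_center = head_center, acet_center = acet_center,
                  offset_anat = spec$offset,
                  cd_distance = sqrt(sum(spec$offset^2)),
                  cd_unit = if (sqrt(sum(spec$offset^2)) > 0)
                    spec$offset / sqrt(sum(spec$offset^2)) else NULL,
                  polar_axis = w, noise_sigma = spec$noise_sigma,
                  side = spec$side, seed = spec$seed,
                  n_head = spec$n_head, n_lunate = n_lun)
    list(femur = femur, coxal = coxal, truth = truth)
  })
}

#' Cohort group profile
#'
#' Distributions from which [generate_cohort()] draws per-hip ground truth.
#' The acetabular radius is induced as `rf * ratio` — radii are strongly
#' coupled within a joint, and the mismatch ratio is the quantity whose
#' spread the groups are defined by. Defaults for the three named profiles
#' are the characteristic group values of the dysplasia continuum this
#' package targets (head radius ~22-23 mm in all groups; ratio 1.23 / 1.13 /
#' 1.07 and center discrepancy 4.8 / 3.2 / 1.6 mm for dysplasia / borderline
#' / control, with the published SDs), fully overridable.
#'
#' @param name `"dysplasia"`, `"borderline"` or `"control"`.
#' @param rf_mean,rf_sd femoral head radius distribution, mm.
#' @param ratio_mean,ratio_sd mismatch ratio distribution.
#' @param cd_mean,cd_sd center discrepancy distance distribution, mm.
#' @param dir_mean mean center-discrepancy direction (anatomical ML/PA/SI
#'   components; renormalized).
#' @param dir_kappa von Mises-Fisher concentration of the direction draw.
#' @param noise_sigma radial noise SD passed to every hip, mm.
#' @param n_head,n_lunate per-hip point counts.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name = c("borderline", "dysplasia", "control"),
                          rf_mean = NULL, rf_sd = NULL,
                          ratio_mean = NULL, ratio_sd = NULL,
                          cd_mean = NULL, cd_sd = NULL,
                          dir_mean = NULL, dir_kappa = 12,
                          noise_sigma = 0.3,
                          n_head = 2000L, n_lunate = 1500L) {
  name <- match.arg(name)
  defaults <- list(
    dysplasia  = list(rf = c(22.2, 1.4), ratio = c(1.23, 0.08),
                      cd = c(4.8, 2.3), dir = c(0.63, 0.61, 0.31)),
    borderline = list(rf = c(22.7, 1.8), ratio = c(1.13, 0.05),
                      cd = c(3.2, 1.4), dir = c(0.69, 0.53, 0.23)),
    control    = list(rf = c(22.9, 1.5), ratio = c(1.07, 0.02),
                      cd = c(1.6, 0.7), dir = c(0.59, 0.32, 0.05)))[[name]]
  dir <- dir_mean %||% defaults$dir
  dir <- dir / sqrt(sum(dir^2))
  structure(list(name = name,
                 rf_mean = rf_mean %||% defaults$rf[1],
                 rf_sd = rf_sd %||% defaults$rf[2],
                 ratio_mean = ratio_mean %||% defaults$ratio[1],
                 ratio_sd = ratio_sd %||% defaults$ratio[2],
                 cd_mean = cd_mean %||% defaults$cd[1],
                 cd_sd = cd_sd %||% defaults$cd[2],
                 dir_mean = dir, dir_kappa = dir_kappa,
                 noise_sigma = noise_sigma,
                 n_head = as.integer(n_head), n_lunate = as.integer(n_lunate)),
            class = "group_profile")
}

# Truncated-normal draw by rejection (falls back to clamping).
rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(hi, max(lo, mean))
}

#' Generate a cohort of synthetic hips
#'
#' Draws `n` hip specifications from a [group_profile()] (radius, ratio and
#' center-discrepancy distance from truncated normals; direction from a von
#' Mises-Fisher law around the profile mean direction; side alternating) and
#' generates each hip. Reproducible under `seed`.
#'
#' Truncation bounds keep the draws physical: rf in [15, 35] mm, ratio in
#' [1.0, 1.6], cd in [0.1, 12] mm.
#'
#' @param profile a [group_profile()].
#' @param n number of hips (>= 1).
#' @param seed integer RNG seed.
#' @return list of `n` elements as returned by [generate_hip()]; each
#'   `truth` additionally carries the group name.
#' @export
generate_cohort <- function(profile, n, seed = 1L) {
  stopifnot(inherits(profile, "group_profile"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort_validation("n must be a positive integer")
  with_seed(seed, {
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      rf <- rnorm_trunc(profile$rf_mean, profile$rf_sd, 15, 35)
      ratio <- rnorm_trunc(profile$ratio_mean, profile$ratio_sd, 1.0, 1.6)
      cd <- rnorm_trunc(profile$cd_mean, profile$cd_sd, 0.1, 12)
      dir <- as.numeric(rvmf(1, profile$dir_mean, profile$dir_kappa))
      specs[[i]] <- synthetic_hip_spec(
        rf = rf, ra = rf * ratio, offset = cd * dir,
        noise_sigma = profile$noise_sigma,
        n_head = profile$n_head, n_lunate = profile$n_lunate,
        side = if (i %% 2L == 0L) "left" else "right",
        seed = sample.int(.Machine$integer.max, 1L))
    }
    lapply(specs, function(s) {
      hip <- generate_hip(s)
      hip$truth$group <- profile$name
      hip
    })
  })
}
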