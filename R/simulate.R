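# Digital-phantom forward simulator: an ellipsoidal head phantom, a ring
# array of receive coils with smooth localized sensitivity profiles, rigid
# 6-DOF motion trajectories, and the forward navigator model
#   s_j(i) = sum_x density(T_i^-1 x) c_j(x) e^{i phi_j}
#            + drift_j(i) + fluctuation_j(i) + eps_j(i).
# The model deliberately reproduces only the mechanism the motion metrics
# exploit - a coil-sensitivity-weighted volume integral under rigid motion,
# plus slow drift and complex Gaussian noise - not MR physics (no spin
# history, B0 or flip-angle effects).

#' Phantom: scalar density on a regular 3D grid
#'
#' @slot density non-negative 3D array
#' @slot spacingMm isotropic grid spacing in mm (grid centred on 0)
#' @exportClass Phantom
setClass("Phantom",
  representation(density = "array", spacingMm = "numeric"))

setValidity("Phantom", function(object) {
  if (any(object@density < 0) || any(!is.finite(object@density)))
    return("density must be non-negative and finite")
  if (object@spacingMm <= 0) return("spacingMm must be positive")
  TRUE
})

#' CoilArray: receive sensitivity fields on the phantom grid
#'
#' Sensitivities are stored flattened (voxels x channels, complex: smooth
#' positive magnitude profile times a fixed per-coil phase).
#'
#' @slot sens complex matrix, voxels x channels
#' @slot dims grid dimensions
#' @slot spacingMm grid spacing in mm
#' @slot centers coil centre coordinates (channels x 3, mm)
#' @exportClass CoilArray
setClass("CoilArray",
  representation(sens = "matrix", dims = "integer", spacingMm = "numeric",
                 centers = "matrix"))

setValidity("CoilArray", function(object) {
  if (!is.complex(object@sens)) return("sens must be complex")
  if (nrow(object@sens) != prod(object@dims))
    return("sens rows must equal the number of grid voxels")
  if (any(colSums(Mod(object@sens)) <= 0))
    return("every coil must be sensitive somewhere")
  TRUE
})

#' MotionTrajectory: per-TR rigid pose
#'
#' Poses are 6-DOF: translations (mm) then rotations (deg), applied about
#' the grid centre. The pose at TR 1 is the identity.
#'
#' @slot poses numeric matrix, TRs x 6 (tx, ty, tz, rx, ry, rz)
#' @slot profile one of "still", "drift", "abrupt", "continuous"
#' @exportClass MotionTrajectory
setClass("MotionTrajectory",
  representation(poses = "matrix", profile = "character"))

.profiles <- c("still", "drift", "abrupt", "continuous")

setValidity("MotionTrajectory", function(object) {
  msgs <- character()
  if (ncol(object@poses) != 6L) msgs <- c(msgs, "poses must have 6 columns")
  if (!object@profile %in% .profiles)
    msgs <- c(msgs, sprintf("profile must be one of: %s",
                            paste(.profiles, collapse = ", ")))
  if (nrow(object@poses) >= 1L && any(object@poses[1, ] != 0))
    msgs <- c(msgs, "the pose at TR 1 must be the identity")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@density)
  cat(sprintf("Phantom: %dx%dx%d grid at %g mm, total density %.4g\n",
              d[1], d[2], d[3], object@spacingMm, sum(object@density)))
})

setMethod("show", "CoilArray", function(object) {
  cat(sprintf("CoilArray: %d channels on a %dx%dx%d grid\n",
              ncol(object@sens), object@dims[1], object@dims[2],
              object@dims[3]))
})

setMethod("show", "MotionTrajectory", function(object) {
  mx <- apply(abs(object@poses), 2, max)
  cat(sprintf(
    "MotionTrajectory <%s>: %d TRs, max |t| %.2f mm, max |r| %.2f deg\n",
    object@profile, nrow(object@poses), max(mx[1:3]), max(mx[4:6])))
})

# grid coordinate axes, centred on 0
.grid_axes <- function(dims, spacing) {
  lapply(seq_len(3), function(k)
    (seq_len(dims[k]) - (dims[k] + 1) / 2) * spacing)
}

# voxel coordinates as an nvox x 3 matrix (column-major order, matching
# as.vector() of a 3D array)
.grid_points <- function(dims, spacing) {
  ax <- .grid_axes(dims, spacing)
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

#' Ellipsoidal head phantom
#'
#' Indicator density of an ellipsoid with the given semi-axes, with a soft
#' (linear) edge one voxel wide to reduce discretization artifacts.
#'
#' @param grid_shape integer grid dimensions (default 24^3)
#' @param semi_axes_mm ellipsoid semi-axes in mm; default approximates a
#'   head within a 220 mm field of view
#' @param spacing_mm isotropic voxel spacing in mm
#' @param edge_voxels width of the soft edge in voxels (0 = hard indicator)
#' @return a [Phantom-class]
#' @export
makePhantom <- function(grid_shape = c(24L, 24L, 24L),
                        semi_axes_mm = c(75, 90, 80),
                        spacing_mm = 9, edge_voxels = 1) {
  grid_shape <- as.integer(grid_shape)
  half_extent <- (grid_shape - 1) / 2 * spacing_mm
  if (any(semi_axes_mm > half_extent))
    stop("ellipsoid semi-axes exceed the grid extent")
  if (any(semi_axes_mm == 0)) {
    return(new("Phantom", density = array(0, grid_shape),
               spacingMm = spacing_mm))
  }
  pts <- .grid_points(grid_shape, spacing_mm)
  u <- sqrt((pts[, 1] / semi_axes_mm[1])^2 +
            (pts[, 2] / semi_axes_mm[2])^2 +
            (pts[, 3] / semi_axes_mm[3])^2)
  if (edge_voxels > 0) {
    # soft edge of width edge_voxels, symmetric about the surface u = 1
    w <- edge_voxels * spacing_mm / min(semi_axes_mm)
    dens <- pmin(1, pmax(0, (1 + w / 2 - u) / w))
  } else {
    dens <- as.numeric(u <= 1)
  }
  new("Phantom", density = array(dens, grid_shape), spacingMm = spacing_mm)
}

#' Ring array of receive coils
#'
#' Coil centres are distributed on rings of a cylinder surrounding the
#' head; each coil has a spherical Gaussian sensitivity profile, a small
#' seeded gain variation and a fixed seeded complex phase. Deterministic
#' for a given seed.
#'
#' @param phantom a [Phantom-class] supplying the grid
#' @param n_channels number of coils (default 32, arranged in rings of 8)
#' @param ring_radius_mm cylinder radius
#' @param sigma_mm Gaussian profile width
#' @param seed RNG seed
#' @param centers optional explicit coil centres (channels x 3, mm),
#'   overriding the ring geometry
#' @return a [CoilArray-class]
#' @export
makeCoilArray <- function(phantom, n_channels = 32L, ring_radius_mm = 120,
                          sigma_mm = 60, seed = 1L, centers = NULL) {
  stopifnot(is(phantom, "Phantom"), n_channels >= 1L)
  dims <- dim(phantom@density)
  spacing <- phantom@spacingMm
  set.seed(as.integer(seed))
  if (is.null(centers)) {
    per_ring <- min(8L, n_channels)
    n_rings <- ceiling(n_channels / per_ring)
    zmax <- (dims[3] - 1) / 2 * spacing * 0.6
    zs <- if (n_rings == 1L) 0 else seq(-zmax, zmax, length.out = n_rings)
    centers <- matrix(0, n_channels, 3)
    for (j in seq_len(n_channels)) {
      ring <- (j - 1L) %/% per_ring
      slot <- (j - 1L) %% per_ring
      ang <- 2 * pi * slot / per_ring + ring * pi / per_ring +
        runif(1, -0.05, 0.05)
      centers[j, ] <- c(ring_radius_mm * cos(ang),
                        ring_radius_mm * sin(ang), zs[ring + 1L])
    }
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != n_channels) stop("centers must be channels x 3")
  }
  pts <- .grid_points(dims, spacing)
  gains <- runif(n_channels, 0.9, 1.1)
  phases <- runif(n_channels, 0, 2 * pi)
  sens <- vapply(seq_len(n_channels), function(j) {
    d2 <- rowSums(sweep(pts, 2, centers[j, ])^2)
    gains[j] * exp(-d2 / (2 * sigma_mm^2))
  }, numeric(nrow(pts)))
  sens <- sens * rep(exp(1i * phases), each = nrow(pts))
  new("CoilArray", sens = sens, dims = as.integer(dims),
      spacingMm = spacing, centers = centers)
}

# rotation matrix from Euler angles in degrees (Rz %*% Ry %*% Rx)
.rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# seeded unit direction in 6-DOF "displacement-equivalent" units: rotation
# components are expressed as mm of displacement at the reference radius
.random_direction6 <- function(rot_radius_mm = 60) {
  d <- rnorm(6)
  d <- d / sqrt(sum(d^2))
  # convert rotational mm-equivalents to degrees
  d[4:6] <- d[4:6] / (rot_radius_mm * pi / 180)
  d
}

#' Rigid motion trajectory
#'
#' Generates a per-TR 6-DOF pose sequence of one of four pediatric motion
#' archetypes: `"still"` (identity throughout), `"drift"` (linear ramp to
#' the target magnitude along a seeded direction), `"abrupt"` (step
#' change(s) at `event_times`, constant in between), `"continuous"`
#' (seeded 6-DOF random walk with per-TR step scaled to `magnitude`).
#' Magnitudes are in mm of displacement-equivalent at a 60 mm reference
#' radius, so rotations contribute commensurately.
#'
#' @param profile motion archetype
#' @param magnitude target magnitude in mm (drift/abrupt: final offset;
#'   continuous: per-TR RMS step)
#' @param n_tr number of TRs
#' @param event_times TR indices of abrupt events (in 2..n_tr); default a
#'   single event halfway through
#' @param seed RNG seed
#' @param rot_radius_mm reference radius converting degrees to mm
#' @return a [MotionTrajectory-class]
#' @export
sampleTrajectory <- function(profile = .profiles, magnitude = 1,
                             n_tr = 160L, event_times = NULL, seed = 1L,
                             rot_radius_mm = 60) {
  profile <- match.arg(profile)
  n_tr <- as.integer(n_tr)
  set.seed(as.integer(seed))
  poses <- matrix(0, n_tr, 6)
  if (profile == "drift") {
    d <- .random_direction6(rot_radius_mm)
    ramp <- seq(0, 1, length.out = n_tr)
    poses <- outer(ramp * magnitude, d)
  } else if (profile == "abrupt") {
    if (is.null(event_times)) event_times <- as.integer(round(n_tr / 2))
    if (any(event_times < 2L | event_times > n_tr))
      stop("event times must lie in [2, n_tr]")
    for (t in sort(event_times)) {
      d <- .random_direction6(rot_radius_mm)
      poses[t:n_tr, ] <- poses[t:n_tr, , drop = FALSE] +
        matrix(magnitude * d, n_tr - t + 1L, 6, byrow = TRUE)
    }
  } else if (profile == "continuous") {
    # continuous restlessness: a mean-reverting walk (foam padding keeps
    # the head wandering within a bounded range), with per-TR innovation
    # norm equal to `magnitude`
    rho <- 0.9
    innov <- matrix(rnorm(n_tr * 6), n_tr, 6)
    innov <- innov / sqrt(rowSums(innov^2)) * magnitude
    x <- matrix(0, n_tr, 6)
    for (t in 2:n_tr) x[t, ] <- rho * x[t - 1L, ] + innov[t, ]
    x[, 4:6] <- x[, 4:6] / (rot_radius_mm * pi / 180)
    poses <- x
  }
  colnames(poses) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  new("MotionTrajectory", poses = poses, profile = profile)
}

# trilinear interpolation of a 3D array at arbitrary mm coordinates;
# points outside the grid evaluate to 0
.trilinear <- function(arr, q, spacing) {
  dims <- dim(arr)
  v <- as.vector(arr)
  n <- nrow(q)
  out <- numeric(n)
  fx <- q[, 1] / spacing + (dims[1] + 1) / 2
  fy <- q[, 2] / spacing + (dims[2] + 1) / 2
  fz <- q[, 3] / spacing + (dims[3] + 1) / 2
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  inside <- i0 >= 1 & i0 + 1 <= dims[1] &
            j0 >= 1 & j0 + 1 <= dims[2] &
            k0 >= 1 & k0 + 1 <= dims[3]
  if (!any(inside)) return(out)
  i0 <- i0[inside]; j0 <- j0[inside]; k0 <- k0[inside]
  dx <- fx[inside] - i0; dy <- fy[inside] - j0; dz <- fz[inside] - k0
  base <- function(i, j, k) i + (j - 1) * dims[1] + (k - 1) * dims[1] * dims[2]
  acc <- v[base(i0, j0, k0)] * (1 - dx) * (1 - dy) * (1 - dz) +
         v[base(i0 + 1, j0, k0)] * dx * (1 - dy) * (1 - dz) +
         v[base(i0, j0 + 1, k0)] * (1 - dx) * dy * (1 - dz) +
         v[base(i0 + 1, j0 + 1, k0)] * dx * dy * (1 - dz) +
         v[base(i0, j0, k0 + 1)] * (1 - dx) * (1 - dy) * dz +
         v[base(i0 + 1, j0, k0 + 1)] * dx * (1 - dy) * dz +
         v[base(i0, j0 + 1, k0 + 1)] * (1 - dx) * dy * dz +
         v[base(i0 + 1, j0 + 1, k0 + 1)] * dx * dy * dz
  out[inside] <- acc
  out
}

# density resampled under one rigid pose: density(T^-1 x) with
# T x = R x + t, evaluated at every grid voxel
.resample_density <- function(phantom, pose) {
  dims <- dim(phantom@density)
  pts <- .grid_points(dims, phantom@spacingMm)
  R <- .rotation_matrix(pose[4:6])
  q <- t(t(pts) - pose[1:3]) %*% R   # (x - t) R == t(R^-1 (x - t)^T)
  .trilinear(phantom@density, q, phantom@spacingMm)
}

#' Noise model for the forward simulator
#'
#' All amplitudes are relative to the per-channel baseline navigator
#' magnitude. The FID is an unencoded whole-volume signal with very high
#' SNR, so the defaults are small: 0.1% complex Gaussian noise, 0.01%/TR
#' linear drift, 0.05% physiological (quasi-respiratory) sinusoidal
#' fluctuation with a 4 s period.
#'
#' @param sd_rel complex Gaussian SD (per real/imag part)
#' @param drift_rate linear drift per TR
#' @param fluct_amp physiological fluctuation amplitude
#' @param fluct_period_s fluctuation period in seconds
#' @return list of noise parameters
#' @export
noiseModel <- function(sd_rel = 0.001, drift_rate = 1e-4,
                       fluct_amp = 5e-4, fluct_period_s = 4) {
  stopifnot(sd_rel >= 0, fluct_amp >= 0, fluct_period_s > 0)
  list(sd_rel = sd_rel, drift_rate = drift_rate, fluct_amp = fluct_amp,
       fluct_period_s = fluct_period_s)
}

#' Forward navigator simulation
#'
#' Evaluates the coil-sensitivity-weighted volume integral of the rigidly
#' transformed phantom at every TR, then adds per-channel linear drift,
#' sinusoidal physiological fluctuation and complex Gaussian noise.
#' Repeated poses (still periods, abrupt profiles) are resampled once and
#' cached.
#'
#' @param phantom a [Phantom-class]
#' @param coils a [CoilArray-class] on the same grid
#' @param trajectory a [MotionTrajectory-class]
#' @param tr_seconds repetition time in seconds (default 1.54)
#' @param noise a [noiseModel()] list; `NULL` disables all noise terms
#' @param seed RNG seed for the noise terms
#' @param subject_id carried into the resulting series
#' @return a [FidnavSeries-class], channels x TRs
#' @export
forwardFidnav <- function(phantom, coils, trajectory, tr_seconds = 1.54,
                          noise = noiseModel(), seed = 1L,
                          subject_id = NA_character_) {
  stopifnot(is(phantom, "Phantom"), is(coils, "CoilArray"),
            is(trajectory, "MotionTrajectory"))
  if (!identical(dim(phantom@density), as.integer(coils@dims)))
    stop("phantom and coil array grids do not match")
  poses <- trajectory@poses
  n_tr <- nrow(poses)
  keys <- apply(round(poses, 9), 1, paste, collapse = ",")
  uniq <- !duplicated(keys)
  dens <- matrix(0, sum(uniq), nrow(coils@sens))
  for (r in seq_len(sum(uniq)))
    dens[r, ] <- .resample_density(phantom, poses[which(uniq)[r], ])
  row_of <- match(keys, keys[uniq])
  D <- dens[row_of, , drop = FALSE]
  clean <- (D %*% Re(coils@sens)) + 1i * (D %*% Im(coils@sens))  # nTR x Nc
  sig <- t(clean)
  if (!is.null(noise)) {
    set.seed(as.integer(seed))
    nc <- nrow(sig)
    b <- Mod(sig[, 1])
    b[b == 0] <- mean(b)
    if (all(b == 0)) b <- rep(1, nc)
    i_idx <- matrix(rep(seq_len(n_tr) - 1, each = nc), nc, n_tr)
    drift_dir <- runif(nc, -1, 1)
    drift <- noise$drift_rate * drift_dir * b * i_idx
    ph <- runif(nc, 0, 2 * pi)
    fluct <- noise$fluct_amp * b *
      sin(2 * pi * i_idx * tr_seconds / noise$fluct_period_s + ph)
    eps <- matrix(complex(real = rnorm(nc * n_tr),
                          imaginary = rnorm(nc * n_tr)), nc, n_tr) *
      (noise$sd_rel * b)
    sig <- sig + drift + fluct + eps
  }
  FidnavSeries(sig, tr_seconds = tr_seconds, subject_id = subject_id)
}

#' k-space-weighted mean displacement of a trajectory
#'
#' Mean displacement of six reference points on a shell of radius
#' `rot_radius_mm` (so rotations about any axis contribute), weighted per
#' TR by the k-space partition weighting — motion during the acquisition
#' of high-energy central k-space degrades the image most.
#'
#' @param trajectory a [MotionTrajectory-class]
#' @param weighting a [KspaceWeighting-class] or numeric weights (length =
#'   number of TRs); `NULL` for uniform weighting
#' @param rot_radius_mm reference shell radius
#' @return weighted mean displacement in mm
#' @export
weightedMeanDisplacement <- function(trajectory, weighting = NULL,
                                     rot_radius_mm = 60) {
  stopifnot(is(trajectory, "MotionTrajectory"))
  poses <- trajectory@poses
  n <- nrow(poses)
  refs <- rbind(diag(3) * rot_radius_mm, -diag(3) * rot_radius_mm)
  d <- vapply(seq_len(n), function(i) {
    R <- .rotation_matrix(poses[i, 4:6])
    moved <- refs %*% t(R)
    moved <- sweep(moved, 2, poses[i, 1:3], `+`)
    mean(sqrt(rowSums((moved - refs)^2)))
  }, numeric(1))
  w <- if (is.null(weighting)) rep(1, n)
       else if (is(weighting, "KspaceWeighting")) stepWeights(weighting)
       else as.numeric(weighting)
  if (length(w) != n) stop("weighting length must equal the number of TRs")
  sum(w * d) / sum(w)
}

#' Ground-truth grade from a motion trajectory
#'
#' Bins the k-space-weighted mean displacement into the five-point scale:
#' below the first threshold is grade 5 (no appreciable motion), above the
#' last is grade 1 (severe). Default thresholds 0.3/0.8/2/5 mm.
#'
#' @inheritParams weightedMeanDisplacement
#' @param thresholds strictly increasing displacement cut-points (mm),
#'   length 4
#' @return integer grade in 1..5
#' @export
gradeFromTrajectory <- function(trajectory, weighting = NULL,
                                thresholds = c(0.3, 0.8, 2, 5),
                                rot_radius_mm = 60) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing values")
  d <- weightedMeanDisplacement(trajectory, weighting, rot_radius_mm)
  5L - as.integer(findInterval(d, thresholds))
}

# target weighted-mean displacement (mm) per grade; mid-bin values chosen
# once against the 0.3/0.8/2/5 mm grade cut-points
.grade_targets <- c(6.0, 4.0, 1.3, 0.5, 0.12)
# motion archetypes per grade: motion-prone subjects (grades 1-2) move
# continuously; intermediate grades show events or slow drift
.grade_profiles <- list(
  `1` = "continuous",
  `2` = "continuous",
  `3` = c("abrupt", "drift"),
  `4` = c("drift", "abrupt"),
  `5` = c("continuous", "continuous", "still")
)

# largest-remainder apportionment of n into round(n * p) with sum n
.apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# scale a trajectory's poses so its weighted mean displacement hits the
# target (two fixed-point iterations; rotations are mildly nonlinear)
.scale_to_displacement <- function(traj, target, weighting, rot_radius_mm) {
  for (it in 1:2) {
    d <- weightedMeanDisplacement(traj, weighting, rot_radius_mm)
    if (d == 0) return(traj)
    traj@poses <- traj@poses * (target / d)
  }
  traj
}

#' Generate a synthetic navigator cohort with known ground truth
#'
#' Builds one shared phantom and coil array, then per subject draws a
#' motion trajectory of the archetype and magnitude appropriate to its
#' target grade, scales it so its k-space-weighted mean displacement lands
#' mid-bin, simulates the navigator series, and labels it with the grade
#' recomputed from the trajectory. Defaults emulate the acquisition the
#' metrics were designed for: 32 channels, TR 1.54 s, 160 TRs (a 4.1-min
#' scan) and a grade mix of 3/9/12/29/49 per 102 subjects.
#'
#' @param n_subjects cohort size
#' @param grade_mix target proportions for grades 1..5 (sum 1)
#' @param n_tr TRs (= outer phase-encoding steps) per scan
#' @param tr_seconds repetition time in seconds
#' @param n_channels receive channels
#' @param grid_shape,spacing_mm phantom grid
#' @param noise a [noiseModel()] list
#' @param thresholds grade displacement cut-points (mm)
#' @param seed master RNG seed; all per-subject streams derive from it
#' @param out_dir if non-NULL, navigator CSVs and a manifest are written
#'   there
#' @return list with `manifest` (data.frame: subject_id, grade, profile,
#'   target_mm, seed, file), `series` (list of [FidnavSeries-class]),
#'   `trajectories`, `phantom`, `coils`, `weighting`
#' @export
generateCohort <- function(n_subjects = 102L,
                           grade_mix = c(3, 9, 12, 29, 49) / 102,
                           n_tr = 160L, tr_seconds = 1.54,
                           n_channels = 32L,
                           grid_shape = c(24L, 24L, 24L), spacing_mm = 9,
                           noise = noiseModel(),
                           thresholds = c(0.3, 0.8, 2, 5),
                           seed = 1L, out_dir = NULL) {
  if (abs(sum(grade_mix) - 1) > 1e-8)
    stop("grade_mix proportions must sum to 1")
  if (length(grade_mix) != 5L) stop("grade_mix must have 5 entries")
  counts <- .apportion(n_subjects, grade_mix)
  if (n_subjects < sum(grade_mix > 0))
    stop("fewer subjects than nonzero grade bins")
  phantom <- makePhantom(grid_shape = grid_shape, spacing_mm = spacing_mm)
  coils <- makeCoilArray(phantom, n_channels = n_channels, seed = seed)
  weighting <- defaultKspaceWeights(n_tr)
  w <- stepWeights(weighting)
  grades_wanted <- rep(5:1, times = rev(counts))
  manifest <- NULL
  series <- list()
  trajectories <- list()
  for (k in seq_len(n_subjects)) {
    g <- grades_wanted[k]
    opts <- .grade_profiles[[as.character(g)]]
    profile <- opts[(k - 1L) %% length(opts) + 1L]
    subj_seed <- .replicate_seed(seed, k)
    target <- .grade_targets[g]
    if (profile == "still") {
      traj <- sampleTrajectory("still", n_tr = n_tr, seed = subj_seed)
    } else {
      mag0 <- if (profile == "continuous") target / sqrt(n_tr) else target
      traj <- sampleTrajectory(profile, magnitude = mag0, n_tr = n_tr,
                               seed = subj_seed)
      traj <- .scale_to_displacement(traj, target, w, 60)
    }
    true_grade <- gradeFromTrajectory(traj, w, thresholds)
    sid <- sprintf("S%03d", k)
    ser <- forwardFidnav(phantom, coils, traj, tr_seconds = tr_seconds,
                         noise = noise, seed = subj_seed,
                         subject_id = sid)
    file <- NA_character_
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      file <- file.path(out_dir, paste0(sid, ".csv"))
      writeNavigatorCsv(ser, file)
    }
    series[[sid]] <- ser
    trajectories[[sid]] <- traj
    manifest <- rbind(manifest, data.frame(
      subject_id = sid, grade = true_grade, profile = profile,
      target_mm = if (profile == "still") 0 else target,
      seed = subj_seed, file = file, stringsAsFactors = FALSE))
  }
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  list(manifest = manifest, series = series, trajectories = trajectories,
       phantom = phantom, coils = coils, weighting = weighting)
}
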