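# dose-engine tests run on small custom phantoms so beamlet banks are cheap

dose_phantom <- function(shape = c(12L, 12L, 12L)) {
  P <- vmatrl:::voxel_coords(shape, rep(5, 3))
  make_phantom(shape, list(PTV = which(rowSums(P^2) <= 12^2),
                           bladder = 1L, rectum = 2L,
                           femoral_head_L = 3L, femoral_head_R = 4L))
}

test_that("beamlet depth dose follows closed-form exponential attenuation", {
  mach <- toy_machine()
  ph <- dose_phantom()
  arc <- list(cp_angles = 0, spacing_deg = 360, gap = NULL,
              gap_mode = "open", n_cp = 1L)
  class(arc) <- "vmat_arc"
  kern <- beam_kernel()
  bank <- precompute_beamlets(ph, arc, mach, kern)
  # beam at gantry 0 travels along +y; pick the beamlet column over x = 2.5 mm
  # and compare two voxels at different depths on the same ray
  b <- which(bank$beamlets$u_lo < 0.25 & bank$beamlets$u_hi > 0.25 &
               bank$beamlets$pair == 13)[1]
  shape <- ph$grid_shape
  vox_at <- function(ix, iy, iz) ix + shape[1] * (iy - 1) + shape[1] * shape[2] * (iz - 1)
  P <- vmatrl:::voxel_coords(shape, rep(5, 3))
  ix <- which(abs(P[1:shape[1], 1] - 2.5) < 1e-9)
  col <- bank$tensors[[1]][, b]
  iz <- 7  # z = 2.5 mm, inside pair 13 (0 - 7.1 mm)
  d1 <- col[vox_at(ix, 4, iz)]
  d2 <- col[vox_at(ix, 9, iz)]
  # deeper voxel is 5 rows = 25 mm further along the beam
  expect_equal(d2 / d1, exp(-kern$mu_mm * 25), tolerance = 1e-10)
  # dose decreases monotonically with depth along the ray
  ray <- col[vox_at(ix, 1:shape[2], iz)]
  expect_true(all(diff(ray) < 0))
  # far outside the penumbra the dose is negligible
  far <- col[vox_at(1, 6, 12)]
  axis_dose <- max(col)
  expect_lt(far, 1e-6 * axis_dose)
  expect_error(beam_kernel(mu_mm = -1), "positive")
})

test_that("opposing angles give mirrored dose tensors on a symmetric phantom", {
  mach <- toy_machine()
  ph <- dose_phantom()
  expect_equal(as.numeric(ph$isocenter), c(0, 0, 0), tolerance = 1e-12)
  arc <- list(cp_angles = c(0, 180), spacing_deg = 180, gap = NULL,
              gap_mode = "open", n_cp = 2L)
  class(arc) <- "vmat_arc"
  bank <- precompute_beamlets(ph, arc, mach)
  shape <- ph$grid_shape
  # at 180 deg the beam direction flips (y mirrored) and the lateral axis
  # reverses: beamlet [u_lo, u_hi] maps to [-u_hi, -u_lo]
  nb <- nrow(bank$beamlets)
  mirror_b <- vapply(seq_len(nb), function(b) {
    which(abs(bank$beamlets$u_lo + bank$beamlets$u_hi[b]) < 1e-9 &
            abs(bank$beamlets$u_hi + bank$beamlets$u_lo[b]) < 1e-9 &
            bank$beamlets$pair == bank$beamlets$pair[b])[1]
  }, integer(1))
  idx <- array(seq_len(prod(shape)), dim = shape)
  flipped <- idx[, shape[2]:1, ]
  t0 <- bank$tensors[[1]]
  t180 <- bank$tensors[[2]]
  err <- max(abs(t180[as.vector(flipped), mirror_b] - t0))
  expect_lt(err, 1e-12)
})

test_that("control-point dose is linear in MU and honors partial beamlet credit", {
  mach <- toy_machine()
  ph <- dose_phantom()
  arc <- list(cp_angles = 0, spacing_deg = 360, gap = NULL,
              gap_mode = "open", n_cp = 1L)
  class(arc) <- "vmat_arc"
  bank <- precompute_beamlets(ph, arc, mach)
  closed <- rep(0, 52)
  expect_true(all(cp_dose(list(angle = 0, leaves = closed, mu = 2), bank)$values == 0))
  open <- c(rep(-3, 26), rep(3, 26))
  d1 <- cp_dose(list(angle = 0, leaves = open, mu = 1), bank)
  d2 <- cp_dose(list(angle = 0, leaves = open, mu = 2), bank)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-15)
  # leaf bisecting a single beamlet: dose is half the open-beamlet dose
  b <- which(bank$beamlets$pair == 13 & bank$beamlets$u_lo == 0)[1]
  lo <- bank$beamlets$u_lo[b]; hi <- bank$beamlets$u_hi[b]
  pair <- bank$beamlets$pair[b]
  ap_full <- rep(0, 52); ap_full[pair] <- lo; ap_full[26 + pair] <- hi
  ap_half <- rep(0, 52); ap_half[pair] <- lo; ap_half[26 + pair] <- (lo + hi) / 2
  # restrict to this pair's beamlets only: adjacent pairs are closed
  df <- cp_dose(list(angle = 0, leaves = ap_full, mu = 1), bank)
  dh <- cp_dose(list(angle = 0, leaves = ap_half, mu = 1), bank)
  expect_equal(dh$values, 0.5 * df$values, tolerance = 1e-12)
})

test_that("plan dose superposes CP doses and supports angular blending", {
  mach <- toy_machine()
  ph <- dose_phantom()
  arc <- toy_arc()
  env_bank <- precompute_beamlets(ph, arc, mach)
  set.seed(5)
  leaves <- t(replicate(arc$n_cp, project_action_to_bounds(runif(52, -3, 3), mach)))
  plan <- new_plan(arc, leaves, runif(arc$n_cp, 0, 3), mach)
  total <- plan_dose(plan, env_bank)
  manual <- Reduce(`+`, lapply(seq_len(arc$n_cp), function(t) {
    cp_dose(list(angle = arc$cp_angles[t], leaves = leaves[t, ],
                 mu = plan$mu[t]), env_bank)$values
  }))
  expect_equal(total$values, manual, tolerance = 1e-14)
  # all-zero MU yields a zero grid
  plan0 <- new_plan(arc, leaves, rep(0, arc$n_cp), mach)
  expect_true(all(plan_dose(plan0, env_bank)$values == 0))

  # two-CP plan against an explicit two-term weighted-sum oracle:
  # bank at 0 and 30 deg, CP at 10 deg -> weights 2/3 and 1/3
  barc <- list(cp_angles = c(0, 30), spacing_deg = 30, gap = NULL,
               gap_mode = "open", n_cp = 2L)
  class(barc) <- "vmat_arc"
  bank2 <- precompute_beamlets(ph, barc, mach)
  parc <- list(cp_angles = c(10, 30), spacing_deg = 20, gap = NULL,
               gap_mode = "open", n_cp = 2L)
  class(parc) <- "vmat_arc"
  ap <- c(rep(-2, 26), rep(2, 26))
  plan2 <- new_plan(parc, rbind(ap, ap), c(1.5, 0), mach)
  blended <- plan_dose(plan2, bank2, blend = TRUE)
  w <- vmatrl:::aperture_weights(ap, bank2)
  oracle <- 1.5 * (2 / 3 * as.vector(bank2$tensors[[1]] %*% w) +
                   1 / 3 * as.vector(bank2$tensors[[2]] %*% w))
  expect_equal(as.vector(blended$values), oracle, tolerance = 1e-12)
})

test_that("wider apertures never decrease dose anywhere", {
  mach <- toy_machine()
  ph <- dose_phantom()
  arc <- list(cp_angles = 45, spacing_deg = 360, gap = NULL,
              gap_mode = "open", n_cp = 1L)
  class(arc) <- "vmat_arc"
  bank <- precompute_beamlets(ph, arc, mach)
  set.seed(9)
  for (i in 1:10) {
    ap <- project_action_to_bounds(runif(52, -2, 2), mach)
    wider <- ap
    j <- sample(26, 1)
    wider[j] <- ap[j] - runif(1, 0, 1)
    wider[26 + j] <- ap[26 + j] + runif(1, 0, 1)
    d0 <- cp_dose(list(angle = 45, leaves = ap, mu = 1), bank)$values
    d1 <- cp_dose(list(angle = 45, leaves = wider, mu = 1), bank)$values
    expect_true(all(d1 - d0 >= -1e-15))
  }
})

test_that("D95 anchoring matches the sorted-array convention and is scale-invariant", {
  ph <- make_phantom(c(4L, 4L, 4L), list(PTV = 1:20, bladder = 21L, rectum = 22L,
                                         femoral_head_L = 23L, femoral_head_R = 24L))
  set.seed(3)
  v <- numeric(64)
  v[1:20] <- runif(20, 0.5, 2)
  d <- make_dose(v, ph)
  dn <- normalize_d95(d, ph$masks$PTV)
  # oracle: the ceiling(0.95 * 20) = 19th hottest PTV voxel scales to 1
  oracle_d95 <- sort(v[1:20], decreasing = TRUE)[19]
  expect_equal(dn$d95_scale, 1 / oracle_d95)
  expect_equal(dvh_metric(dn, ph$masks$PTV, "Dpct", value = 95), 1.0)
  # rescaling the raw input leaves the anchored grid unchanged
  dk <- normalize_d95(make_dose(7.3 * v, ph), ph$masks$PTV)
  expect_equal(dk$values, dn$values, tolerance = 1e-12)
  expect_error(normalize_d95(make_dose(numeric(64), ph), ph$masks$PTV), "zero")
})

test_that("gamma pass rate agrees with a brute-force oracle", {
  ph <- dose_phantom(c(8L, 8L, 8L))
  set.seed(17)
  base <- array(runif(512, 0.2, 1), dim = c(8, 8, 8))
  ref <- make_dose(base, ph)
  expect_equal(gamma_pass_rate(ref, ref), 100)
  # uniform +2.9% passes a 3% dose criterion everywhere
  up29 <- make_dose(base * 1.029, ph)
  expect_equal(gamma_pass_rate(up29, ref), 100)
  # uniform +6% on a spatially flat grid: no spatial offset can rescue it
  flat <- make_dose(array(1, dim = c(8, 8, 8)), ph)
  flat6 <- make_dose(array(1.06, dim = c(8, 8, 8)), ph)
  expect_equal(gamma_pass_rate(flat6, flat), 0)

  # randomized comparison against an explicit voxel-loop gamma
  ev <- make_dose(base * (1 + array(rnorm(512, 0, 0.03), dim = c(8, 8, 8))), ph)
  got <- gamma_pass_rate(ev, ref)
  dmax <- max(ref$values)
  dtol <- 0.03 * dmax
  sp <- 5
  pass <- 0; n_eval <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    if (ref$values[i, j, k] < 0.1 * dmax) next
    n_eval <- n_eval + 1
    best <- Inf
    for (oi in -1:1) for (oj in -1:1) for (ok in -1:1) {
      ii <- i + oi; jj <- j + oj; kk <- k + ok
      if (ii < 1 || ii > 8 || jj < 1 || jj > 8 || kk < 1 || kk > 8) next
      dist <- sp * sqrt(oi^2 + oj^2 + ok^2)
      if (dist > 6) next
      g2 <- ((ev$values[ii, jj, kk] - ref$values[i, j, k]) / dtol)^2 + (dist / 2)^2
      best <- min(best, g2)
    }
    if (best <= 1 + 1e-9) pass <- pass + 1
  }
  expect_equal(got, 100 * pass / n_eval, tolerance = 1e-12)
  expect_error(gamma_pass_rate(ref, make_dose(numeric(27),
    make_phantom(c(3L, 3L, 3L), list(PTV = 1L, bladder = 2L, rectum = 3L,
                                     femoral_head_L = 4L, femoral_head_R = 5L)))),
    "geometry")
})
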