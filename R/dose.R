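#' Analytic beamlet kernel parameters
#'
#' The dose engine models each beamlet as a divergence-free (parallel) ray
#' with exponential depth attenuation `exp(-mu * depth)` inside the phantom
#' and error-function box-Gaussian lateral profiles (a rectangular beamlet
#' cross-section convolved with a Gaussian penumbra). A single global
#' calibration scalar sets the absolute output so that an open field delivers
#' `calib_dose_per_100mu` Gy per 100 MU at `calib_depth_mm` depth on the
#' central axis.
#'
#' @param mu_mm Linear attenuation coefficient, 1/mm (default 0.005).
#' @param sigma_mm Gaussian penumbra sigma, mm (default 3).
#' @param bin_width_cm Beamlet width along leaf travel in the isocenter
#'   plane, cm (default 0.5).
#' @param calib_dose_per_100mu Calibration dose, Gy per 100 MU (default 2).
#' @param calib_depth_mm Calibration depth, mm (default 100).
#' @return A `vmat_kernel` parameter list.
#' @export
beam_kernel <- function(mu_mm = 0.005, sigma_mm = 3, bin_width_cm = 0.5,
                        calib_dose_per_100mu = 2, calib_depth_mm = 100) {
  vals <- c(mu_mm, sigma_mm, bin_width_cm, calib_dose_per_100mu, calib_depth_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("kernel parameters must be strictly positive")
  }
  k <- list(mu_mm = mu_mm, sigma_mm = sigma_mm, bin_width_cm = bin_width_cm,
            calib_dose_per_100mu = calib_dose_per_100mu,
            calib_depth_mm = calib_depth_mm,
            calib = (calib_dose_per_100mu / 100) / exp(-mu_mm * calib_depth_mm))
  class(k) <- "vmat_kernel"
  k
}

# radiological depth (mm) of every voxel for a parallel beam at gantry angle
# theta (degrees): distance from the grid boundary to the voxel along the
# beam direction d = (sin t, cos t, 0)
beam_depths <- function(P, grid_shape, spacing, angle_deg) {
  th <- angle_deg * pi / 180
  dx <- sin(th); dy <- cos(th)
  hx <- grid_shape[1] * spacing[1] / 2
  hy <- grid_shape[2] * spacing[2] / 2
  tx <- if (abs(dx) > 1e-12) {
    if (dx > 0) (P[, 1] + hx) / dx else (P[, 1] - hx) / dx
  } else rep(Inf, nrow(P))
  ty <- if (abs(dy) > 1e-12) {
    if (dy > 0) (P[, 2] + hy) / dy else (P[, 2] - hy) / dy
  } else rep(Inf, nrow(P))
  pmin(tx, ty)
}

# integral of a unit box of half-width w convolved with a Gaussian(0, sigma),
# evaluated at offsets t (all mm or all cm, consistently)
box_gauss <- function(t, w, sigma) {
  stats::pnorm((t + w) / sigma) - stats::pnorm((t - w) / sigma)
}

#' Precompute per-angle beamlet dose tensors on a phantom
#'
#' For every control-point angle of the arc, computes the dose per MU of each
#' beamlet (leaf pair x along-travel bin) at every voxel of the phantom grid.
#' Beamlets whose dose is everywhere negligible (outside the grid footprint)
#' are dropped. The result is the patient-specific input from which all plan
#' doses are composed by superposition.
#'
#' @param phantom A `vmat_phantom`.
#' @param arc A `vmat_arc`.
#' @param machine A `vmat_machine`.
#' @param kernel A `vmat_kernel` (see [beam_kernel()]).
#' @return A `vmat_beamlet_bank`: `angles`, per-angle dose matrices
#'   (`n_voxel x n_beamlet`, Gy/MU), shared beamlet geometry
#'   (`pair`, `u_lo`, `u_hi` in cm), and the grid geometry.
#' @export
precompute_beamlets <- function(phantom, arc, machine = machine_model(),
                                kernel = beam_kernel()) {
  P0 <- voxel_coords(phantom$grid_shape, phantom$spacing)  # grid-center frame
  P <- sweep(P0, 2, phantom$isocenter)  # beam frame centered on the isocenter
  sig <- kernel$sigma_mm
  edges <- leaf_pair_edges(machine) * 10  # mm
  hw_mm <- machine$field_half_width * 10
  bw_mm <- kernel$bin_width_cm * 10
  # lateral bins spanning the travel range
  n_bin <- ceiling(2 * hw_mm / bw_mm)
  u_lo <- -hw_mm + (seq_len(n_bin) - 1) * bw_mm
  u_hi <- pmin(u_lo + bw_mm, hw_mm)
  u_c <- (u_lo + u_hi) / 2
  # keep only beamlets that can reach the grid (plus penumbra)
  # grid footprint in the beam frame is bounded by the corner radius
  rad <- sqrt(sum((phantom$grid_shape[1:2] * phantom$spacing[1:2] / 2)^2)) +
    max(abs(phantom$isocenter[1:2])) + 3 * sig
  keep_bin <- which(u_c >= -rad & u_c <= rad)
  z_top <- phantom$grid_shape[3] * phantom$spacing[3] / 2 - phantom$isocenter[3] + 3 * sig
  z_bot <- -phantom$grid_shape[3] * phantom$spacing[3] / 2 - phantom$isocenter[3] - 3 * sig
  keep_pair <- which(edges[, "z_hi"] >= z_bot & edges[, "z_lo"] <= z_top)
  geom <- expand.grid(bin = keep_bin, pair = keep_pair, KEEP.OUT.ATTRS = FALSE)
  # z profiles are angle-independent
  Pz <- vapply(keep_pair, function(j) {
    box_gauss(P[, 3] - (edges[j, "z_lo"] + edges[j, "z_hi"]) / 2,
              (edges[j, "z_hi"] - edges[j, "z_lo"]) / 2, sig)
  }, numeric(nrow(P)))
  tensors <- lapply(arc$cp_angles, function(a) {
    th <- a * pi / 180
    u_v <- P[, 1] * cos(th) - P[, 2] * sin(th)
    att <- kernel$calib * exp(-kernel$mu_mm *
                                beam_depths(P0, phantom$grid_shape, phantom$spacing, a))
    Pu <- vapply(keep_bin, function(k) {
      box_gauss(u_v - u_c[k], (u_hi[k] - u_lo[k]) / 2, sig)
    }, numeric(nrow(P)))
    m <- (att * Pz[, match(geom$pair, keep_pair), drop = FALSE]) *
      Pu[, match(geom$bin, keep_bin), drop = FALSE]
    m[m < 1e-12] <- 0
    m
  })
  bank <- list(angles = arc$cp_angles, tensors = tensors,
               beamlets = data.frame(pair = geom$pair,
                                     u_lo = u_lo[geom$bin] / 10,
                                     u_hi = u_hi[geom$bin] / 10),
               grid_shape = phantom$grid_shape, spacing = phantom$spacing,
               kernel = kernel, machine = machine)
  class(bank) <- "vmat_beamlet_bank"
  bank
}

#' @export
print.vmat_beamlet_bank <- function(x, ...) {
  cat(sprintf("Beamlet bank: %d angles x %d beamlets on a %s grid\n",
              length(x$angles), nrow(x$beamlets),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

# open fraction of each beamlet under an aperture (52 leaf positions, cm)
aperture_weights <- function(leaves, bank) {
  np <- bank$machine$leaf_pairs
  x1 <- leaves[bank$beamlets$pair]
  x2 <- leaves[np + bank$beamlets$pair]
  ov <- pmin(x2, bank$beamlets$u_hi) - pmax(x1, bank$beamlets$u_lo)
  pmax(ov, 0) / (bank$beamlets$u_hi - bank$beamlets$u_lo)
}

# raw dose vector of one control point (Gy); leaves cm, mu MU
cp_dose_vector <- function(angle, leaves, mu, bank) {
  ai <- which(abs(bank$angles - angle) < 1e-9)
  if (!length(ai)) stop(sprintf("angle %g not present in the beamlet bank", angle))
  w <- aperture_weights(leaves, bank)
  as.vector(bank$tensors[[ai]] %*% w) * mu
}

# wrap a raw dose vector as a vmat_dose object
as_dose <- function(values, bank_or_phantom, normalization = "raw") {
  d <- list(values = array(values, dim = bank_or_phantom$grid_shape),
            grid_shape = bank_or_phantom$grid_shape,
            spacing = bank_or_phantom$spacing,
            normalization = normalization)
  class(d) <- "vmat_dose"
  d
}

#' Dose of a single control point
#'
#' `dose = mu * sum_b a_b * beamlet_dose_b`, where `a_b` in `[0, 1]` is the
#' fraction of beamlet b left open by the aperture, with linear partial
#' credit where a leaf bisects a beamlet. A fully closed aperture yields a
#' zero grid.
#'
#' @param cp List with `angle` (deg), `leaves` (52 values, cm), `mu`.
#' @param bank A `vmat_beamlet_bank` containing the CP angle.
#' @return A raw `vmat_dose`.
#' @export
cp_dose <- function(cp, bank) {
  as_dose(cp_dose_vector(cp$angle, cp$leaves, cp$mu, bank), bank, "raw")
}

#' Total raw dose of a plan
#'
#' Sums the control-point doses over the arc. With `blend = TRUE`, each CP's
#' fluence is spread as a distance-weighted combination of the two nearest
#' precomputed angular tensors (weights linear in angular distance, summing
#' to one) — the VMAT adaptation of a fixed-angle open-field engine. With
#' blending disabled (the default) and the bank computed at the CP angles
#' themselves, the result is the plain per-angle superposition.
#'
#' @param plan A `vmat_plan`.
#' @param bank A `vmat_beamlet_bank`.
#' @param blend Spread each CP over its angular sector (default `FALSE`).
#' @return A raw `vmat_dose`.
#' @export
plan_dose <- function(plan, bank, blend = FALSE) {
  total <- numeric(prod(bank$grid_shape))
  for (t in seq_len(plan$arc$n_cp)) {
    a <- plan$arc$cp_angles[t]
    w <- aperture_weights(plan$leaves[t, ], bank)
    if (!blend) {
      ai <- which(abs(bank$angles - a) < 1e-9)
      if (!length(ai)) stop(sprintf("angle %g not present in the beamlet bank", a))
      total <- total + as.vector(bank$tensors[[ai]] %*% w) * plan$mu[t]
    } else {
      dist <- abs((bank$angles - a + 180) %% 360 - 180)
      ord <- order(dist)[1:2]
      if (dist[ord[1]] < 1e-9) {
        total <- total + as.vector(bank$tensors[[ord[1]]] %*% w) * plan$mu[t]
      } else {
        wts <- rev(dist[ord]) / sum(dist[ord])
        total <- total + (as.vector(bank$tensors[[ord[1]]] %*% w) * wts[1] +
                          as.vector(bank$tensors[[ord[2]]] %*% w) * wts[2]) * plan$mu[t]
      }
    }
  }
  as_dose(total, bank, "raw")
}

#' Anchor a dose grid to 95% target coverage
#'
#' Rescales the whole grid by a single factor `s` so that the PTV D95 — the
#' dose received by the `ceiling(0.95 * n)`-th hottest PTV voxel, computed by
#' sorting without interpolation — equals 1.0, i.e. the prescription scaled
#' to 1.0 covers 95% of the target. All DVH scoring operates on anchored
#' grids, making the objective invariant to global MU scale.
#'
#' @param dose A raw `vmat_dose`.
#' @param ptv_mask Logical array marking the PTV.
#' @return A `vmat_dose` with `normalization = "d95_anchored"` and the applied
#'   scale factor in `$d95_scale`.
#' @export
normalize_d95 <- function(dose, ptv_mask) {
  d <- dose$values[ptv_mask]
  if (!length(d)) stop("PTV mask is empty")
  d95 <- sort(d, decreasing = TRUE)[ceiling(0.95 * length(d))]
  if (!is.finite(d95) || d95 <= 0) {
    stop("cannot anchor D95: PTV dose is (near) zero")
  }
  dose$values <- dose$values / d95
  dose$normalization <- "d95_anchored"
  dose$d95_scale <- 1 / d95
  dose
}

#' Global gamma-index pass rate between two dose grids
#'
#' Global gamma: the dose criterion is a percentage of the reference maximum;
#' voxels with reference dose below `threshold`% of the reference maximum are
#' excluded from scoring. For each evaluated voxel the minimum generalized
#' distance `gamma = min_o sqrt((dD/dose_tol)^2 + (|o|/dist_crit)^2)` is
#' searched exhaustively over all voxel offsets `o` within
#' `search_factor * dist_crit` mm. Returns the percent of evaluated voxels
#' with `gamma <= 1`.
#'
#' @param eval_dose,ref_dose `vmat_dose` objects on identical geometry.
#' @param dose_crit Dose criterion, percent of the reference maximum (default 3).
#' @param dist_crit Distance-to-agreement criterion, mm (default 2).
#' @param threshold Low-dose exclusion threshold, percent of the reference
#'   maximum (default 10).
#' @param search_factor Search radius in units of `dist_crit` (default 3).
#' @return Pass rate in percent.
#' @export
gamma_pass_rate <- function(eval_dose, ref_dose, dose_crit = 3, dist_crit = 2,
                            threshold = 10, search_factor = 3) {
  if (!identical(dim(eval_dose$values), dim(ref_dose$values)) ||
      !isTRUE(all.equal(eval_dose$spacing, ref_dose$spacing))) {
    stop("dose grids do not share geometry")
  }
  ref <- ref_dose$values
  ev <- eval_dose$values
  rmax <- max(ref)
  if (rmax <= 0) stop("reference dose is identically zero")
  dtol <- dose_crit / 100 * rmax
  evalv <- ref >= threshold / 100 * rmax
  if (!any(evalv)) stop("no voxel above the low-dose threshold")
  sp <- ref_dose$spacing
  radius <- search_factor * dist_crit
  ro <- lapply(seq_along(sp), function(i) seq(-floor(radius / sp[i]), floor(radius / sp[i])))
  offs <- as.matrix(expand.grid(ro[[1]], ro[[2]], ro[[3]]))
  dist <- sqrt((offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 + (offs[, 3] * sp[3])^2)
  offs <- offs[dist <= radius + 1e-9, , drop = FALSE]
  dist <- dist[dist <= radius + 1e-9]
  dims <- dim(ref)
  g2 <- array(Inf, dim = dims)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    # target index ranges such that source (target + o) stays in the grid
    t1 <- max(1, 1 - o[1]):min(dims[1], dims[1] - o[1])
    t2 <- max(1, 1 - o[2]):min(dims[2], dims[2] - o[2])
    t3 <- max(1, 1 - o[3]):min(dims[3], dims[3] - o[3])
    dd <- ev[t1 + o[1], t2 + o[2], t3 + o[3], drop = FALSE] -
      ref[t1, t2, t3, drop = FALSE]
    cand <- (dd / dtol)^2 + (dist[k] / dist_crit)^2
    g2[t1, t2, t3] <- pmin(g2[t1, t2, t3, drop = FALSE], cand)
  }
  100 * mean(g2[evalv] <= 1 + 1e-9)
}

#' Write / read a dose grid as JSON text
#'
#' Full-precision text serialization of a `vmat_dose` with its geometry and
#' normalization state.
#' @param dose A `vmat_dose`.
#' @param path File path.
#' @export
write_dose <- function(dose, path) {
  obj <- list(format = "vmatrl-dose-v1", grid_shape = dose$grid_shape,
              spacing_mm = dose$spacing, normalization = dose$normalization,
              d95_scale = dose$d95_scale %||% NA_real_,
              values = as.vector(dose$values))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_dose
#' @return `read_dose` returns the `vmat_dose`.
#' @export
read_dose <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "vmatrl-dose-v1") stop("not a vmatrl dose file")
  d <- list(values = array(obj$values, dim = obj$grid_shape),
            grid_shape = as.integer(obj$grid_shape), spacing = obj$spacing_mm,
            normalization = obj$normalization)
  if (is.finite(obj$d95_scale)) d$d95_scale <- obj$d95_scale
  class(d) <- "vmat_dose"
  d
}

#' @export
print.vmat_dose <- function(x, ...) {
  cat(sprintf("Dose grid %s (%s): max %.4g, mean %.4g\n",
              paste(x$grid_shape, collapse = "x"), x$normalization,
              max(x$values), mean(x$values)))
  invisible(x)
}
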