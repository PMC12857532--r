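#' Machine model for an MR-linac-style VMAT delivery
#'
#' Describes the delivery hardware the planner must respect: the central MLC
#' leaf bank used for field modulation, the physical travel range of the
#' leaves, the maximum leaf speed and dose rate, and the nominal time spent
#' delivering one control point (CP). Leaf-travel and MU limits per CP are
#' derived from `max_leaf_speed * cp_delivery_time` and
#' `max_dose_rate * cp_delivery_time / 60` respectively.
#'
#' @param leaf_pairs Number of opposed leaf pairs modelled (default 26, the
#'   central pairs needed for a centrally located pelvic target).
#' @param leaf_width_iso Leaf width projected to the isocenter plane, cm.
#' @param field_half_width Maximum |leaf position| along the travel axis, cm.
#' @param max_leaf_speed Maximum leaf speed, cm/s.
#' @param max_dose_rate Maximum dose rate, MU/min.
#' @param cp_delivery_time Nominal delivery time per CP, s.
#' @return An object of class `vmat_machine`.
#' @export
machine_model <- function(leaf_pairs = 26L, leaf_width_iso = 0.71,
                          field_half_width = 10, max_leaf_speed = 6,
                          max_dose_rate = 425, cp_delivery_time = 0.5) {
  vals <- c(leaf_pairs = leaf_pairs, leaf_width_iso = leaf_width_iso,
            field_half_width = field_half_width, max_leaf_speed = max_leaf_speed,
            max_dose_rate = max_dose_rate, cp_delivery_time = cp_delivery_time)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all machine parameters must be strictly positive and finite")
  }
  m <- list(leaf_pairs = as.integer(leaf_pairs), leaf_width_iso = leaf_width_iso,
            field_half_width = field_half_width, max_leaf_speed = max_leaf_speed,
            max_dose_rate = max_dose_rate, cp_delivery_time = cp_delivery_time)
  class(m) <- "vmat_machine"
  m
}

#' Maximum leaf travel allowed between adjacent control points (cm)
#' @param machine A `vmat_machine`.
#' @return Travel limit in cm.
#' @export
max_leaf_travel <- function(machine) machine$max_leaf_speed * machine$cp_delivery_time

#' Maximum MU deliverable at one control point
#' @param machine A `vmat_machine`.
#' @return MU limit per CP.
#' @export
max_cp_mu <- function(machine) machine$max_dose_rate * machine$cp_delivery_time / 60

#' Superior edges / centers of the leaf pairs on the isocenter plane (cm)
#'
#' Pair index increases superior to inferior; the bank is centered on the
#' isocenter. Returns a matrix with columns `z_lo`, `z_hi`, `z_c` (cm).
#' @param machine A `vmat_machine`.
#' @return Numeric matrix, one row per leaf pair.
#' @export
leaf_pair_edges <- function(machine) {
  n <- machine$leaf_pairs
  w <- machine$leaf_width_iso
  # integer multiples of the leaf width so the bank edges are exact
  k_hi <- n / 2 - (seq_len(n) - 1)
  z_hi <- k_hi * w
  z_lo <- (k_hi - 1) * w
  cbind(z_lo = z_lo, z_hi = z_hi, z_c = (z_lo + z_hi) / 2)
}

#' Build the control-point angle template of a single VMAT arc
#'
#' CPs are evenly spaced gantry angles over a full rotation; an excluded
#' angular interval (for the MR-linac cryostat pipe) removes CPs. Two gap
#' conventions are supported: `"conservative"` removes only CPs whose whole
#' +/- one-spacing sector lies inside the gap (delivery retained at the gap
#' edges), `"open"` removes every CP strictly inside the gap. The default
#' 2-degree spacing with a 4-23 degree conservative gap yields 172 CPs.
#'
#' @param spacing_deg Angular spacing between CPs in degrees; must divide 360.
#' @param gap Numeric length-2 excluded interval in degrees, or `NULL` for a
#'   full arc with no gap.
#' @param gap_mode `"conservative"` or `"open"` (see Details).
#' @return An object of class `vmat_arc` with fields `cp_angles`,
#'   `spacing_deg`, `gap`, `gap_mode`, `n_cp`.
#' @examples
#' arc <- build_arc_template()
#' arc$n_cp  # 172
#' @export
build_arc_template <- function(spacing_deg = 2, gap = c(4, 23),
                               gap_mode = c("conservative", "open")) {
  gap_mode <- match.arg(gap_mode)
  if (spacing_deg <= 0 || (360 %% spacing_deg) != 0) {
    stop("spacing_deg must be a positive divisor of 360")
  }
  angles <- seq(0, 360 - spacing_deg, by = spacing_deg)
  if (!is.null(gap)) {
    if (length(gap) != 2 || gap[2] <= gap[1]) stop("gap must be an increasing length-2 interval")
    if (gap[2] - gap[1] >= 360) stop("gap cannot cover the full circle")
    keep <- if (gap_mode == "conservative") {
      !(angles - spacing_deg >= gap[1] & angles + spacing_deg <= gap[2])
    } else {
      !(angles > gap[1] & angles < gap[2])
    }
    angles <- angles[keep]
    if (length(angles) == 0) stop("gap excludes every control point")
  }
  arc <- list(cp_angles = angles, spacing_deg = spacing_deg, gap = gap,
              gap_mode = gap_mode, n_cp = length(angles))
  class(arc) <- "vmat_arc"
  arc
}

#' Construct a VMAT plan
#'
#' A plan is an ordered sequence of control points matching an arc template,
#' each holding a gantry angle, 52 leaf positions (the 26 X1/"top" leaves
#' followed by the 26 X2/"bottom" leaves; an open gap at pair j requires
#' `X2_j >= X1_j`, positions in cm on the isocenter plane), and an MU value.
#'
#' @param arc A `vmat_arc`.
#' @param leaves Numeric matrix `n_cp x (2 * leaf_pairs)` of leaf positions, cm.
#' @param mu Numeric vector of per-CP monitor units (>= 0).
#' @param machine A `vmat_machine` (defines geometry for validation).
#' @param patient_id Identifier string.
#' @param validate Check per-CP validity (bounds, crossing, MU sign).
#' @return An object of class `vmat_plan`.
#' @export
new_plan <- function(arc, leaves, mu, machine = machine_model(),
                     patient_id = "anon", validate = TRUE) {
  leaves <- as.matrix(leaves)
  if (nrow(leaves) != arc$n_cp) {
    stop(sprintf("plan has %d control points but the arc template requires %d",
                 nrow(leaves), arc$n_cp))
  }
  if (ncol(leaves) != 2L * machine$leaf_pairs) {
    stop(sprintf("expected %d leaf positions per CP, got %d",
                 2L * machine$leaf_pairs, ncol(leaves)))
  }
  if (length(mu) != arc$n_cp) stop("mu must have one value per control point")
  plan <- list(arc = arc, leaves = unname(leaves), mu = as.numeric(mu),
               patient_id = patient_id)
  class(plan) <- "vmat_plan"
  if (validate) {
    bad <- plan_cp_invalid(plan, machine)
    if (length(bad)) {
      stop(sprintf("invalid control point(s) %s: leaf bound/crossing or negative MU",
                   paste(bad, collapse = ", ")))
    }
  }
  plan
}

# indices of CPs violating static validity (bounds, crossing, negative MU)
plan_cp_invalid <- function(plan, machine) {
  np <- machine$leaf_pairs
  hw <- machine$field_half_width
  x1 <- plan$leaves[, seq_len(np), drop = FALSE]
  x2 <- plan$leaves[, np + seq_len(np), drop = FALSE]
  bad <- abs(plan$leaves) > hw + 1e-9
  cross <- x2 - x1 < -1e-9
  which(rowSums(bad) > 0 | rowSums(cross) > 0 | plan$mu < 0)
}

#' Check a plan against machine deliverability constraints
#'
#' Report-only: returns a data frame with one row per violation and zero rows
#' iff the plan is deliverable. Checked per CP: leaf positions within
#' `+/- field_half_width`; opposing leaves non-crossing (`X2 >= X1`);
#' inter-CP leaf travel within `max_leaf_speed * cp_delivery_time`; per-CP MU
#' within `max_dose_rate * cp_delivery_time / 60` and non-negative. All
#' comparisons are inclusive: values exactly at a limit are deliverable.
#'
#' @param plan A `vmat_plan`.
#' @param machine A `vmat_machine`.
#' @return data.frame with columns `cp`, `type`, `index`, `value`, `limit`.
#' @export
check_deliverability <- function(plan, machine = machine_model()) {
  np <- machine$leaf_pairs
  hw <- machine$field_half_width
  travel_max <- max_leaf_travel(machine)
  mu_max <- max_cp_mu(machine)
  out <- list()
  add <- function(cp, type, index, value, limit) {
    out[[length(out) + 1L]] <<- data.frame(cp = cp, type = type, index = index,
                                           value = value, limit = limit)
  }
  L <- plan$leaves
  tol <- 1e-9
  over <- which(abs(L) > hw + tol, arr.ind = TRUE)
  if (nrow(over)) add(over[, 1], "leaf_bound", over[, 2], L[over], hw)
  x1 <- L[, seq_len(np), drop = FALSE]
  x2 <- L[, np + seq_len(np), drop = FALSE]
  crossed <- which(x2 - x1 < -tol, arr.ind = TRUE)
  if (nrow(crossed)) {
    add(crossed[, 1], "leaf_cross", crossed[, 2],
        (x2 - x1)[crossed], 0)
  }
  if (nrow(L) > 1) {
    travel <- abs(L[-1, , drop = FALSE] - L[-nrow(L), , drop = FALSE])
    tv <- which(travel > travel_max + tol, arr.ind = TRUE)
    if (nrow(tv)) add(tv[, 1] + 1L, "leaf_travel", tv[, 2], travel[tv], travel_max)
  }
  mu_bad <- which(plan$mu > mu_max + tol)
  if (length(mu_bad)) add(mu_bad, "mu_rate", NA_integer_, plan$mu[mu_bad], mu_max)
  mu_neg <- which(plan$mu < 0)
  if (length(mu_neg)) add(mu_neg, "mu_negative", NA_integer_, plan$mu[mu_neg], 0)
  if (!length(out)) {
    return(data.frame(cp = integer(), type = character(), index = integer(),
                      value = numeric(), limit = numeric()))
  }
  do.call(rbind, out)
}

#' Project raw leaf positions onto the statically valid set
#'
#' Sampled policy actions can land outside the physical leaf range or cross
#' their opposing leaf. Positions are clipped to `+/- field_half_width`; any
#' crossed pair is replaced by its midpoint (a closed aperture at that pair).
#' The map is idempotent and never increases any |position|.
#'
#' @param raw_leaves Numeric vector of length `2 * leaf_pairs` (X1 then X2), cm.
#' @param machine A `vmat_machine`.
#' @return Valid leaf-position vector of the same length.
#' @export
project_action_to_bounds <- function(raw_leaves, machine = machine_model()) {
  np <- machine$leaf_pairs
  if (length(raw_leaves) != 2L * np) stop("raw_leaves must have 2 * leaf_pairs values")
  hw <- machine$field_half_width
  v <- pmin(pmax(raw_leaves, -hw), hw)
  x1 <- v[seq_len(np)]
  x2 <- v[np + seq_len(np)]
  crossed <- x1 > x2
  if (any(crossed)) {
    mid <- (x1[crossed] + x2[crossed]) / 2
    x1[crossed] <- mid
    x2[crossed] <- mid
  }
  c(x1, x2)
}

#' Repair a plan to satisfy dynamic deliverability
#'
#' Sequentially clamps each CP's leaves into the travel window of the previous
#' CP (`+/- max_leaf_speed * cp_delivery_time`), projects to bounds, closes
#' crossed pairs at the nearest feasible point, and caps MU to
#' `[0, max_cp_mu]`. The result always yields an empty
#' [check_deliverability()] report. Used to finalize policy output at
#' inference.
#'
#' @param plan A `vmat_plan`.
#' @param machine A `vmat_machine`.
#' @return A deliverable `vmat_plan`.
#' @export
enforce_deliverability <- function(plan, machine = machine_model()) {
  np <- machine$leaf_pairs
  hw <- machine$field_half_width
  tmax <- max_leaf_travel(machine)
  L <- plan$leaves
  L[1, ] <- project_action_to_bounds(L[1, ], machine)
  if (nrow(L) > 1) {
    for (t in 2:nrow(L)) {
      prev <- L[t - 1, ]
      v <- pmin(pmax(L[t, ], prev - tmax), prev + tmax)
      v <- pmin(pmax(v, -hw), hw)
      x1 <- v[seq_len(np)]
      x2 <- v[np + seq_len(np)]
      crossed <- which(x1 > x2)
      for (j in crossed) {
        m <- (x1[j] + x2[j]) / 2
        # meeting point feasible for both leaves: prev CP is itself valid,
        # so the travel windows overlap whenever the previous gap <= 2*tmax
        lo1 <- prev[j] - tmax; hi1 <- prev[j] + tmax
        lo2 <- prev[np + j] - tmax; hi2 <- prev[np + j] + tmax
        lo <- max(lo1, lo2, -hw); hi <- min(hi1, hi2, hw)
        if (lo <= hi) {
          m <- min(max(m, lo), hi)
          x1[j] <- m; x2[j] <- m
        } else {
          x1[j] <- min(max(x1[j], lo1), hi1, hw)
          x2[j] <- max(min(x2[j], hi2), lo2, -hw)
        }
      }
      L[t, ] <- c(x1, x2)
    }
  }
  plan$leaves <- L
  plan$mu <- pmin(pmax(plan$mu, 0), max_cp_mu(machine))
  plan
}

#' Write a plan to a JSON file
#'
#' The schema stores the arc metadata (spacing, gap, gap convention, CP
#' angles) and, per control point, the gantry angle, the 52 leaf positions and
#' the MU value. Doubles are written at full precision so a write/read
#' round-trip is bit-exact.
#'
#' @param plan A `vmat_plan`.
#' @param path Output file path.
#' @export
write_plan <- function(plan, path) {
  obj <- list(
    format = "vmatrl-plan-v1",
    patient_id = plan$patient_id,
    arc = list(spacing_deg = plan$arc$spacing_deg, gap = plan$arc$gap,
               gap_mode = plan$arc$gap_mode, cp_angles = plan$arc$cp_angles),
    control_points = lapply(seq_len(nrow(plan$leaves)), function(t) {
      list(angle = plan$arc$cp_angles[t], leaves = plan$leaves[t, ],
           mu = plan$mu[t])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a plan from a JSON file
#'
#' @param path File written by [write_plan()].
#' @param machine A `vmat_machine` used to validate leaf counts and bounds.
#' @return A `vmat_plan`.
#' @export
read_plan <- function(path, machine = machine_model()) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "vmatrl-plan-v1") {
    stop("not a vmatrl plan file")
  }
  gap <- as.numeric(unlist(obj$arc$gap))
  if (!length(gap)) gap <- NULL
  arc <- build_arc_template(spacing_deg = obj$arc$spacing_deg, gap = gap,
                            gap_mode = obj$arc$gap_mode)
  cps <- obj$control_points
  if (length(cps) != arc$n_cp) {
    stop(sprintf("file holds %d control points but the arc template requires %d",
                 length(cps), arc$n_cp))
  }
  nleaf <- 2L * machine$leaf_pairs
  leaves <- matrix(NA_real_, length(cps), nleaf)
  mu <- numeric(length(cps))
  for (t in seq_along(cps)) {
    lv <- as.numeric(unlist(cps[[t]]$leaves))
    if (length(lv) != nleaf) {
      stop(sprintf("control point %d: expected %d leaf values, got %d",
                   t, nleaf, length(lv)))
    }
    m <- cps[[t]]$mu
    if (is.null(m) || !is.finite(as.numeric(m)) || as.numeric(m) < 0) {
      stop(sprintf("control point %d: MU missing, non-finite or negative", t))
    }
    leaves[t, ] <- lv
    mu[t] <- as.numeric(m)
  }
  new_plan(arc, leaves, mu, machine = machine,
           patient_id = if (is.null(obj$patient_id)) "anon" else obj$patient_id)
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("VMAT plan '%s': %d control points, total MU %.1f\n",
              x$patient_id, x$arc$n_cp, sum(x$mu)))
  invisible(x)
}

#' @export
print.vmat_arc <- function(x, ...) {
  cat(sprintf("VMAT arc: %d CPs every %g deg", x$n_cp, x$spacing_deg))
  if (!is.null(x$gap)) cat(sprintf(", gap %g-%g deg (%s)", x$gap[1], x$gap[2], x$gap_mode))
  cat("\n")
  invisible(x)
}
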