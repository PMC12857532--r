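#' Constraint-scaled dose objective specification
#'
#' Defines, per structure, the weight `w_i`, the ideal dose `o_i`
#' (1.0 for the PTV, 0.0 for OARs, prescription-relative), the dose-volume
#' constraints, and the scaling factor `f_i < 1` applied once per satisfied
#' constraint. The defaults are the clinical endpoints used to drive the
#' reward: PTV (w 50, D2.0cm3 < 135%, f 0.75), bladder (w 20, V50% < 40%,
#' f 0.5), rectum (w 20, V50% < 50% and V80% < 20%, f 0.7). Femoral heads are
#' evaluation-only and carry no objective term.
#'
#' @param structures Optional list overriding the defaults; each element is
#'   `list(name, weight, ideal, factor, constraints)` with constraints a list
#'   of `list(metric = "Vpct"|"Dcc", arg, limit)` — `Vpct` compares the
#'   percent of structure volume receiving at least `arg`% of prescription
#'   against `limit` (percent volume); `Dcc` compares the minimum dose of the
#'   hottest `arg` cm^3 against `limit` (prescription-relative). All
#'   comparisons are strict (`<`); ties count as unmet.
#' @return A `vmat_objective_spec`.
#' @export
objective_spec <- function(structures = NULL) {
  if (is.null(structures)) {
    structures <- list(
      list(name = "PTV", weight = 50, ideal = 1.0, factor = 0.75,
           constraints = list(list(metric = "Dcc", arg = 2.0, limit = 1.35))),
      list(name = "bladder", weight = 20, ideal = 0.0, factor = 0.5,
           constraints = list(list(metric = "Vpct", arg = 50, limit = 40))),
      list(name = "rectum", weight = 20, ideal = 0.0, factor = 0.7,
           constraints = list(list(metric = "Vpct", arg = 50, limit = 50),
                              list(metric = "Vpct", arg = 80, limit = 20))))
  }
  for (s in structures) {
    stopifnot(is.character(s$name), s$weight > 0,
              s$factor > 0, s$factor < 1)
  }
  spec <- list(structures = structures)
  class(spec) <- "vmat_objective_spec"
  spec
}

#' Load an objective specification from YAML
#' @param path YAML file with a `structures` list (see [objective_spec()]).
#' @return A `vmat_objective_spec`.
#' @export
read_objective_spec <- function(path) {
  y <- yaml::read_yaml(path)
  objective_spec(y$structures)
}

#' Write an objective specification to YAML
#' @param spec A `vmat_objective_spec`.
#' @param path Output path.
#' @export
write_objective_spec <- function(spec, path) {
  yaml::write_yaml(list(structures = spec$structures), path)
  invisible(path)
}

#' Dose-volume histogram metric of a structure
#'
#' Metrics operate on the voxel doses of the masked structure:
#' `Dmean`/`Dmax`/`Dmin`; `Dpct` (`value` = x) is the minimum dose of the
#' hottest x% of voxels (the `ceiling(x/100 * n)`-th hottest voxel, no
#' interpolation); `Dcc` (`value` = cm^3) the minimum dose of the hottest
#' given absolute volume (capped at the structure volume); `Vpct`
#' (`value` = X) the percent of structure volume receiving at least X% of the
#' prescription (inclusive), meaningful on a D95-anchored grid where the
#' prescription is 1.0.
#'
#' @param dose A `vmat_dose` (anchored for prescription-relative metrics).
#' @param mask Logical array, nonempty.
#' @param metric One of `"Dmean"`, `"Dmax"`, `"Dmin"`, `"Dpct"`, `"Vpct"`, `"Dcc"`.
#' @param value Metric argument (x%, X% or cm^3) where applicable.
#' @return Scalar metric value (dose in grid units; `Vpct` in percent).
#' @export
dvh_metric <- function(dose, mask, metric = c("Dmean", "Dmax", "Dmin", "Dpct",
                                              "Vpct", "Dcc"), value = NULL) {
  metric <- match.arg(metric)
  d <- dose$values[mask]
  if (!length(d)) stop("structure mask is empty")
  switch(metric,
    Dmean = mean(d),
    Dmax = max(d),
    Dmin = min(d),
    Dpct = {
      if (is.null(value)) stop("Dpct needs `value` (percent of volume)")
      sort(d, decreasing = TRUE)[ceiling(value / 100 * length(d))]
    },
    Vpct = {
      if (is.null(value)) stop("Vpct needs `value` (percent of prescription)")
      100 * mean(d >= value / 100)
    },
    Dcc = {
      if (is.null(value)) stop("Dcc needs `value` (cm^3)")
      vox_cc <- prod(dose$spacing) / 1000
      m <- min(length(d), ceiling(value / vox_cc))
      sort(d, decreasing = TRUE)[m]
    })
}

#' Conformity index
#'
#' Ratio of the number of voxels anywhere in the grid receiving at least 95%
#' of the prescription to the number of PTV voxels.
#'
#' @param dose A D95-anchored `vmat_dose`.
#' @param ptv_mask Logical PTV mask, nonempty.
#' @return CI (dimensionless).
#' @export
conformity_index <- function(dose, ptv_mask) {
  n_ptv <- sum(ptv_mask)
  if (n_ptv == 0) stop("PTV mask is empty")
  sum(dose$values >= 0.95) / n_ptv
}

# evaluate one constraint on a masked dose; returns TRUE iff strictly met
constraint_met <- function(dose, mask, con) {
  val <- switch(con$metric,
    Vpct = dvh_metric(dose, mask, "Vpct", value = con$arg),
    Dcc = dvh_metric(dose, mask, "Dcc", value = con$arg),
    stop(sprintf("unknown constraint metric '%s'", con$metric)))
  val < con$limit
}

#' Constraint-scaled dose objective value
#'
#' For each structure i: `MSE_i` is the mean over structure voxels of
#' `(d - o_i)^2` on the D95-anchored grid; `n_i` counts the structure's
#' dose-volume constraints that are strictly satisfied; the structure term is
#' `w_i * MSE_i * f_i^{n_i}` and the total is their sum. Lower is better;
#' each newly satisfied constraint multiplies the structure's term by its
#' factor, producing the reward jumps that prioritize meeting constraints.
#'
#' @param dose A `vmat_dose`; must be D95-anchored (scoring order is
#'   normalize, then score).
#' @param phantom A `vmat_phantom` supplying the structure masks.
#' @param spec A `vmat_objective_spec`.
#' @return A `vmat_objective`: `total`, per-structure `terms`, `mse`, `n_sat`.
#' @export
objective_value <- function(dose, phantom, spec = objective_spec()) {
  if (!identical(dose$normalization, "d95_anchored")) {
    stop("objective_value requires a D95-anchored dose (run normalize_d95 first)")
  }
  terms <- mse <- numeric(0)
  n_sat <- integer(0)
  for (s in spec$structures) {
    mask <- phantom$masks[[s$name]]
    if (is.null(mask) || !any(mask)) {
      stop(sprintf("objective structure '%s' missing or empty in phantom", s$name))
    }
    d <- dose$values[mask]
    m <- mean((d - s$ideal)^2)
    n <- sum(vapply(s$constraints, function(con) constraint_met(dose, mask, con),
                    logical(1)))
    terms[s$name] <- s$weight * m * s$factor^n
    mse[s$name] <- m
    n_sat[s$name] <- n
  }
  v <- list(total = sum(terms), terms = terms, mse = mse, n_sat = n_sat)
  class(v) <- "vmat_objective"
  v
}

#' @export
print.vmat_objective <- function(x, ...) {
  cat(sprintf("Dose objective v = %.6g\n", x$total))
  for (nm in names(x$terms)) {
    cat(sprintf("  %-10s term %.6g (MSE %.6g, %d constraint(s) met)\n",
                nm, x$terms[nm], x$mse[nm], x$n_sat[nm]))
  }
  invisible(x)
}

#' Step reward from two objective values
#'
#' `r = v_old - v_new`: a step that lowers the dose objective earns a
#' positive reward, and larger improvements earn more. Rewards over an
#' episode telescope to `v_initial - v_final`.
#'
#' @param v_old,v_new `vmat_objective` values computed under the same spec.
#' @return Scalar reward.
#' @export
step_reward <- function(v_old, v_new) {
  v_old$total - v_new$total
}
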