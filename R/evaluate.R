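#' Evaluate a plan against the clinical endpoints
#'
#' Computes the plan dose, anchors 95% PTV coverage at the prescription, and
#' reports the clinically relevant metrics per structure in Gy (via the
#' phantom prescription; the anchored grid has prescription = 1.0) or
#' percent volume, together with the objective constraint pass/fail flags
#' and a deliverability summary. An all-zero-MU plan raises an error (the
#' dose cannot be anchored) rather than returning zero metrics.
#'
#' @param plan A `vmat_plan`.
#' @param env A `vmat_env` (phantom, bank, machine, objective spec).
#' @param blend Passed to [plan_dose()].
#' @return A `vmat_plan_report`: `metrics` (data.frame structure, metric,
#'   value, unit), `constraints` (data.frame with `met` flags), `deliverable`,
#'   `n_violations`, `d95_scale`.
#' @export
evaluate_plan <- function(plan, env, blend = FALSE) {
  dose <- plan_dose(plan, env$bank, blend = blend)
  dose <- normalize_d95(dose, env$phantom$masks$PTV)
  rx <- env$phantom$prescription_dose
  ph <- env$phantom
  rows <- list()
  add <- function(structure, metric, value, unit) {
    rows[[length(rows) + 1L]] <<- data.frame(structure = structure,
                                             metric = metric, value = value,
                                             unit = unit)
  }
  ptv <- ph$masks$PTV
  add("PTV", "Dmean", dvh_metric(dose, ptv, "Dmean") * rx, "Gy")
  add("PTV", "D2%", dvh_metric(dose, ptv, "Dpct", value = 2) * rx, "Gy")
  add("PTV", "D95%", dvh_metric(dose, ptv, "Dpct", value = 95) * rx, "Gy")
  add("PTV", "D98%", dvh_metric(dose, ptv, "Dpct", value = 98) * rx, "Gy")
  add("PTV", "Dmax", dvh_metric(dose, ptv, "Dmax") * rx, "Gy")
  add("PTV", "D2.0cm3", dvh_metric(dose, ptv, "Dcc", value = 2) * rx, "Gy")
  add("PTV", "CI", conformity_index(dose, ptv), "")
  for (nm in c("bladder", "rectum")) {
    add(nm, "Dmean", dvh_metric(dose, ph$masks[[nm]], "Dmean") * rx, "Gy")
    add(nm, "Dmax", dvh_metric(dose, ph$masks[[nm]], "Dmax") * rx, "Gy")
    add(nm, "V50%", dvh_metric(dose, ph$masks[[nm]], "Vpct", value = 50), "%")
  }
  add("rectum", "V80%", dvh_metric(dose, ph$masks$rectum, "Vpct", value = 80), "%")
  for (nm in c("femoral_head_L", "femoral_head_R")) {
    add(nm, "Dmean", dvh_metric(dose, ph$masks[[nm]], "Dmean") * rx, "Gy")
    add(nm, "V40%", dvh_metric(dose, ph$masks[[nm]], "Vpct", value = 40), "%")
  }
  metrics <- do.call(rbind, rows)
  cons <- list()
  for (s in env$spec$structures) {
    for (con in s$constraints) {
      val <- switch(con$metric,
                    Vpct = dvh_metric(dose, ph$masks[[s$name]], "Vpct", value = con$arg),
                    Dcc = dvh_metric(dose, ph$masks[[s$name]], "Dcc", value = con$arg))
      cons[[length(cons) + 1L]] <- data.frame(
        structure = s$name,
        constraint = if (con$metric == "Vpct") {
          sprintf("V%g%% < %g%%", con$arg, con$limit)
        } else sprintf("D%.1fcm3 < %g%%", con$arg, con$limit * 100),
        value = val, limit = con$limit, met = val < con$limit)
    }
  }
  viol <- check_deliverability(plan, env$machine)
  rep <- list(metrics = metrics, constraints = do.call(rbind, cons),
              deliverable = nrow(viol) == 0, n_violations = nrow(viol),
              d95_scale = dose$d95_scale, patient_id = plan$patient_id)
  class(rep) <- "vmat_plan_report"
  rep
}

#' @export
print.vmat_plan_report <- function(x, ...) {
  cat(sprintf("Plan report (%s), deliverable: %s\n", x$patient_id,
              if (x$deliverable) "yes" else sprintf("no (%d violations)", x$n_violations)))
  print(x$metrics, row.names = FALSE)
  cat("Constraints:\n")
  print(x$constraints, row.names = FALSE)
  invisible(x)
}

#' Write a plan report to CSV
#' @param report A `vmat_plan_report`.
#' @param path Output CSV path.
#' @export
write_plan_report <- function(report, path) {
  utils::write.csv(report$metrics, path, row.names = FALSE)
  invisible(path)
}

# two-sided Wilcoxon rank-sum p-value with midranks: exact by full
# enumeration for combined n <= exact_max, normal approximation with tie
# correction otherwise
ranksum_p <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    combs <- utils::combn(n, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    tol <- 1e-9
    p <- min(1, 2 * min(mean(Ws <= W + tol), mean(Ws >= W - tol)))
    return(p)
  }
  E <- n1 * (n + 1) / 2
  ties <- table(r)
  V <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (V <= 0) return(1)
  2 * stats::pnorm(-abs(W - E) / sqrt(V))
}

#' Compare two cohorts of plan reports
#'
#' For every metric present in both cohorts, reports cohort means and
#' standard deviations and a two-sided Wilcoxon rank-sum p-value (exact by
#' full enumeration with midranks for combined n <= 10, normal approximation
#' with tie correction otherwise).
#'
#' @param reports_a,reports_b Lists of `vmat_plan_report` (or of plain metric
#'   data.frames with columns structure, metric, value); >= 2 plans each.
#' @return data.frame: structure, metric, mean_a, sd_a, mean_b, sd_b, p_value.
#' @export
compare_cohorts <- function(reports_a, reports_b) {
  stopifnot(length(reports_a) >= 2, length(reports_b) >= 2)
  pull <- function(reports) {
    do.call(rbind, lapply(seq_along(reports), function(i) {
      m <- if (is.data.frame(reports[[i]])) reports[[i]] else reports[[i]]$metrics
      m <- m[, c("structure", "metric", "value")]
      m$plan <- i
      m
    }))
  }
  ma <- pull(reports_a); mb <- pull(reports_b)
  key_a <- unique(ma[, c("structure", "metric")])
  key_b <- unique(mb[, c("structure", "metric")])
  if (!identical(key_a[order(key_a$structure, key_a$metric), ],
                 key_b[order(key_b$structure, key_b$metric), ])) {
    keys_match <- nrow(merge(key_a, key_b)) == nrow(key_a) &&
      nrow(key_a) == nrow(key_b)
    if (!keys_match) stop("cohorts report different metric sets")
  }
  out <- lapply(seq_len(nrow(key_a)), function(k) {
    s <- key_a$structure[k]; m <- key_a$metric[k]
    va <- ma$value[ma$structure == s & ma$metric == m]
    vb <- mb$value[mb$structure == s & mb$metric == m]
    data.frame(structure = s, metric = m,
               mean_a = mean(va), sd_a = stats::sd(va),
               mean_b = mean(vb), sd_b = stats::sd(vb),
               p_value = ranksum_p(va, vb))
  })
  do.call(rbind, out)
}

#' Cumulative DVH curves of a dose grid
#'
#' @param dose A `vmat_dose` (anchored doses are reported prescription-
#'   relative unless `rx` is given to convert to Gy).
#' @param phantom A `vmat_phantom`.
#' @param rx Optional prescription (Gy) to scale the dose axis.
#' @param n_bins Number of dose bins.
#' @return data.frame: structure, dose, volume_pct.
#' @export
dvh_curve <- function(dose, phantom, rx = NULL, n_bins = 100) {
  dmax <- max(dose$values)
  bins <- seq(0, dmax, length.out = n_bins)
  out <- lapply(names(phantom$masks), function(nm) {
    d <- dose$values[phantom$masks[[nm]]]
    data.frame(structure = nm, dose = if (is.null(rx)) bins else bins * rx,
               volume_pct = vapply(bins, function(b) 100 * mean(d >= b),
                                   numeric(1)))
  })
  do.call(rbind, out)
}

#' Plot DVH curves
#'
#' Requires ggplot2.
#' @inheritParams dvh_curve
#' @return A ggplot object.
#' @export
plot_dvh <- function(dose, phantom, rx = NULL, n_bins = 100) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_dvh requires the ggplot2 package")
  }
  df <- dvh_curve(dose, phantom, rx = rx, n_bins = n_bins)
  ggplot2::ggplot(df, ggplot2::aes(x = dose, y = volume_pct, colour = structure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (is.null(rx)) "Dose (prescription-relative)" else "Dose (Gy)",
                  y = "Volume (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the training log
#'
#' Mean total plan reward and mean baseline objective per RL iteration.
#' Requires ggplot2.
#' @param training A `vmat_training`.
#' @return A ggplot object.
#' @export
plot_training_log <- function(training) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_training_log requires the ggplot2 package")
  }
  df <- training$log
  ggplot2::ggplot(df, ggplot2::aes(x = iteration, y = mean_reward)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = training$best$iteration, linetype = 2) +
    ggplot2::labs(x = "RL iteration", y = "Mean total plan reward") +
    ggplot2::theme_minimal()
}
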