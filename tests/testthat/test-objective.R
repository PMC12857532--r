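test_that("DVH metrics match hand-computable cases", {
  ph <- make_phantom(c(4L, 4L, 4L), list(PTV = 1:10, bladder = 11:26, rectum = 27L,
                                         femoral_head_L = 28L, femoral_head_R = 29L))
  # uniform dose: every point metric equals it
  v <- numeric(64); v[1:10] <- 0.8
  d <- make_dose(v, ph, "d95_anchored")
  m <- ph$masks$PTV
  expect_equal(dvh_metric(d, m, "Dmean"), 0.8)
  expect_equal(dvh_metric(d, m, "Dmax"), 0.8)
  expect_equal(dvh_metric(d, m, "Dpct", value = 2), 0.8)
  expect_equal(dvh_metric(d, m, "Dpct", value = 98), 0.8)
  # 10 voxels with doses 0.1..1.0: V50% counts the 6 voxels at >= 0.5
  v2 <- numeric(64); v2[1:10] <- (1:10) / 10
  d2 <- make_dose(v2, ph, "d95_anchored")
  expect_equal(dvh_metric(d2, m, "Vpct", value = 50), 60)
  # D2.0cm3 on a structure of exactly 2.0 cm3 (16 voxels at 125 mm3) is Dmin
  v3 <- numeric(64); v3[11:26] <- seq(0.2, 1.7, length.out = 16)
  d3 <- make_dose(v3, ph, "d95_anchored")
  expect_equal(dvh_metric(d3, ph$masks$bladder, "Dcc", value = 2),
               min(v3[11:26]))
  expect_error(dvh_metric(d3, array(FALSE, dim = ph$grid_shape), "Dmean"), "empty")
})

test_that("conformity index counts 95% prescription coverage", {
  ph <- make_phantom(c(4L, 4L, 4L), list(PTV = 1:10, bladder = 11L, rectum = 12L,
                                         femoral_head_L = 13L, femoral_head_R = 14L))
  v <- numeric(64); v[1:10] <- 0.95
  expect_equal(conformity_index(make_dose(v, ph, "d95_anchored"), ph$masks$PTV), 1.0)
  expect_equal(conformity_index(make_dose(numeric(64), ph, "d95_anchored"),
                                ph$masks$PTV), 0)
  # hand-built: 10 PTV voxels at 1.0, 5 outside voxels at 0.96, 3 at 0.5
  v2 <- numeric(64); v2[1:10] <- 1; v2[20:24] <- 0.96; v2[30:32] <- 0.5
  expect_equal(conformity_index(make_dose(v2, ph, "d95_anchored"), ph$masks$PTV),
               15 / 10)
})

test_that("objective value follows the constraint-scaled weighted MSE", {
  ph <- factor_phantom()
  # perfectly conformal case: PTV exactly 1, OARs 0 -> total 0
  d <- factor_dose(rep(1, 400), numeric(10), numeric(10))
  ov <- objective_value(d, ph)
  expect_equal(ov$total, 0)
  expect_equal(unname(ov$n_sat["PTV"]), 1)   # D2cc = 1 < 1.35
  # un-anchored dose is rejected (normalize-then-score order)
  expect_error(objective_value(make_dose(rep(1, 512), ph), ph), "anchored")
  # naive voxel-loop oracle on a random dose
  set.seed(21)
  raw <- runif(512, 0, 1.2)
  dn <- normalize_d95(make_dose(raw, ph), ph$masks$PTV)
  got <- objective_value(dn, ph)
  spec <- objective_spec()
  total <- 0
  for (s in spec$structures) {
    idx <- which(as.vector(ph$masks[[s$name]]))
    dd <- as.vector(dn$values)[idx]
    mse <- 0
    for (x in dd) mse <- mse + (x - s$ideal)^2
    mse <- mse / length(dd)
    n <- 0
    for (con in s$constraints) {
      val <- if (con$metric == "Vpct") {
        100 * sum(dd >= con$arg / 100) / length(dd)
      } else {
        mth <- min(length(dd), ceiling(con$arg * 1000 / prod(ph$spacing)))
        sort(dd, decreasing = TRUE)[mth]
      }
      if (val < con$limit) n <- n + 1
    }
    expect_equal(unname(got$mse[s$name]), mse, tolerance = 1e-12)
    total <- total + s$weight * mse * s$factor^n
  }
  expect_equal(got$total, total, tolerance = 1e-12)
  # invariance to global MU scale via D95 anchoring
  dn2 <- normalize_d95(make_dose(3.7 * raw, ph), ph$masks$PTV)
  expect_equal(objective_value(dn2, ph)$total, got$total, tolerance = 1e-12)
})

test_that("crossing one constraint threshold scales exactly one term by its factor", {
  ph <- factor_phantom()
  base_b <- bladder_unmet(); met_b <- bladder_met()
  expect_equal(mean(base_b^2), mean(met_b^2), tolerance = 1e-12)
  v_unmet <- objective_value(factor_dose(ptv_unmet(), base_b, rectum_none()), ph)
  v_met <- objective_value(factor_dose(ptv_unmet(), met_b, rectum_none()), ph)
  expect_equal(unname(v_met$terms["bladder"] / v_unmet$terms["bladder"]), 0.5)
  expect_equal(unname(v_met$terms["PTV"]), unname(v_unmet$terms["PTV"]))
  expect_equal(unname(v_met$terms["rectum"]), unname(v_unmet$terms["rectum"]))
})

test_that("step reward is the objective decrease", {
  ph <- factor_phantom()
  v1 <- objective_value(factor_dose(ptv_unmet(), bladder_unmet(), rectum_none()), ph)
  v2 <- objective_value(factor_dose(ptv_unmet(), bladder_met(), rectum_none()), ph)
  expect_equal(step_reward(v1, v1), 0)
  r <- step_reward(v1, v2)
  # newly satisfying the bladder constraint at equal MSE jumps the reward by
  # w * MSE * (1 - f) = 20 * MSE * 0.5
  expect_equal(r, 20 * mean(bladder_unmet()^2) * (1 - 0.5), tolerance = 1e-12)
  # halving the objective gives reward v/2
  half <- v1; half$total <- v1$total / 2
  expect_equal(step_reward(v1, half), v1$total / 2)
})

test_that("objective spec round-trips through YAML and validates factors", {
  spec <- objective_spec()
  path <- tempfile(fileext = ".yaml")
  write_objective_spec(spec, path)
  back <- read_objective_spec(path)
  expect_equal(back$structures, spec$structures)
  shipped <- read_objective_spec(system.file("extdata", "default_objective.yaml",
                                             package = "vmatrl"))
  expect_equal(shipped$structures, spec$structures)
  bad <- spec$structures
  bad[[1]]$factor <- 1.2
  expect_error(objective_spec(bad))
})
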