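# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

toy_machine <- function() machine_model(field_half_width = 4)

toy_arc <- function() build_arc_template(15, NULL)  # 24 CPs, no gap

toy_phantom <- function(seed = 1) generate_phantom(seed, "toy")

# cached toy environment (phantom + beamlet bank are the expensive parts)
toy_env <- function(seed = 1) {
  key <- paste0("env", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- plan_env(toy_phantom(seed), toy_arc(), toy_machine())
  }
  .fixtures[[key]]
}

# hand-built phantom with explicit masks on a small grid; masks is a named
# list of integer voxel index vectors
make_phantom <- function(grid_shape, masks_idx, spacing = rep(5, 3),
                         prescription = 36.25) {
  masks <- lapply(masks_idx, function(idx) {
    m <- array(FALSE, dim = grid_shape)
    m[idx] <- TRUE
    m
  })
  P <- vmatrl:::voxel_coords(grid_shape, spacing)
  ph <- list(grid_shape = as.integer(grid_shape), spacing = spacing,
             masks = masks, prescription_dose = prescription,
             isocenter = colMeans(P[as.vector(masks$PTV), , drop = FALSE]),
             size_class = "custom", seed = 0L)
  class(ph) <- "vmat_phantom"
  ph
}

# wrap a numeric vector/array as a vmat_dose on a phantom grid
make_dose <- function(values, phantom, normalization = "raw") {
  d <- list(values = array(values, dim = phantom$grid_shape),
            grid_shape = phantom$grid_shape, spacing = phantom$spacing,
            normalization = normalization)
  class(d) <- "vmat_dose"
  d
}

# 8^3 phantom with disjoint PTV (400 vox), bladder (10), rectum (10) used by
# the constraint-factor constructions: voxel doses are assigned directly
factor_phantom <- function() {
  if (is.null(.fixtures$factor_ph)) {
    .fixtures$factor_ph <- make_phantom(
      c(8L, 8L, 8L),
      list(PTV = 1:400, bladder = 401:410, rectum = 421:430))
  }
  .fixtures$factor_ph
}

# anchored dose over the factor_phantom with per-structure voxel doses;
# PTV doses must already anchor D95 at exactly 1 (verified here)
factor_dose <- function(ptv, bladder, rectum) {
  ph <- factor_phantom()
  v <- numeric(prod(ph$grid_shape))
  v[1:400] <- ptv
  v[401:410] <- bladder
  v[421:430] <- rectum
  d <- normalize_d95(make_dose(v, ph), ph$masks$PTV)
  stopifnot(abs(d$d95_scale - 1) < 1e-12)
  d
}

# PTV dose vectors (400 voxels): D2.0cm3 (= 16 hottest voxels at 5 mm
# isotropic) just over vs just under 135% of prescription, identical MSE,
# D95 anchored at exactly 1.0
ptv_unmet <- function() c(rep(1.4, 16), rep(1.0, 364), rep(1.0, 20))
ptv_met <- function() c(rep(1.3, 16), rep(1.0, 364),
                        rep(1 - sqrt(16 * (0.4^2 - 0.3^2) / 20), 20))

# bladder 10-voxel doses: V50% = 40% (unmet, ties strict) vs 30% (met),
# identical MSE against ideal 0
bladder_unmet <- function() c(rep(0.5, 4), rep(0.1, 6))
bladder_met <- function() c(rep(0.5, 3), rep(sqrt((4 * 0.25 + 6 * 0.01 - 3 * 0.25) / 7), 7))

# rectum 10-voxel doses: none met (V50 = 50%, V80 = 20%), one met
# (V50 = 40%), both met (V50 = 40%, V80 = 10%); identical MSE
rectum_none <- function() c(rep(0.9, 2), rep(0.5, 3), rep(0.1, 5))
rectum_one <- function() c(rep(0.9, 2), rep(0.5, 2),
                           rep(sqrt((2.42 - 2 * 0.81 - 2 * 0.25) / 6), 6))
rectum_both <- function() c(0.9, rep(0.5, 3), rep(sqrt((2.42 - 0.81 - 3 * 0.25) / 6), 6))

# constant policy stub for episode tests: always returns fixed means
net_forward.const_policy <- function(net, state, cache = FALSE) {
  list(mean = net$mean, log_std = rep(net$log_std, length(net$mean)),
       value = 0)
}
registerS3method("net_forward", "const_policy", net_forward.const_policy,
                 envir = asNamespace("vmatrl"))

const_policy <- function(mean, log_std = -20) {
  structure(list(mean = mean, log_std = log_std,
                 cfg = list(out_dim = length(mean))),
            class = c("const_policy", "vmat_network_stub"))
}
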