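#' Generate a seeded synthetic pelvic phantom
#'
#' Builds a labeled voxel phantom emulating the anatomy of a localized
#' prostate treatment: a central ellipsoidal PTV (prostate plus margin),
#' bladder anterior-superior, rectum posterior, and two lateral femoral
#' heads, on a regular isotropic grid. Organ half-axes are varied by a
#' relative jitter and centroids by a positional jitter so every seed yields
#' a distinct but anatomically ordered case. Overlaps with the PTV are
#' removed from all OAR masks so each structure has a single ideal dose.
#'
#' Axis convention: +x patient-left, +y posterior, +z superior. The gantry
#' rotates about z.
#'
#' @param seed Non-negative integer; regeneration with the same seed and
#'   configuration is bit-identical.
#' @param size_class `"toy"` (16^3 grid, 5 mm) or `"standard"` (32^3, 5 mm).
#' @param size_jitter Relative half-axis variation (default 0.2, i.e. +/-20%).
#' @param center_jitter_mm Centroid jitter, mm (default 10 for standard,
#'   4 for toy).
#' @param prescription_dose Prescription in Gy (default 36.25, five-fraction
#'   prostate SBRT).
#' @return A `vmat_phantom`: `grid_shape`, `spacing` (mm), `masks` (named
#'   logical arrays: PTV, bladder, rectum, femoral_head_L, femoral_head_R),
#'   `prescription_dose`, `isocenter` (PTV centroid, mm, grid-center frame).
#' @export
generate_phantom <- function(seed, size_class = c("toy", "standard"),
                             size_jitter = 0.2, center_jitter_mm = NULL,
                             prescription_dose = 36.25) {
  if (!is.numeric(seed) || seed < 0) stop("seed must be a non-negative integer")
  size_class <- match.arg(size_class)
  geo <- switch(size_class,
    toy = list(shape = c(16L, 16L, 16L), spacing = rep(5, 3), scale = 0.5,
               jitter = 4),
    standard = list(shape = c(32L, 32L, 32L), spacing = rep(5, 3), scale = 1,
                    jitter = 10))
  if (is.null(center_jitter_mm)) center_jitter_mm <- geo$jitter
  s <- geo$scale
  # nominal organ geometry, mm (standard scale): center, half-axes
  organs <- list(
    PTV            = list(c(0, 0, 0),        c(22, 20, 20) * s),
    bladder        = list(c(0, -45, 38) * s, c(24, 20, 18) * s),
    rectum         = list(c(0, 42, 0) * s,   c(12, 14, 36) * s),
    femoral_head_L = list(c(58, 5, 0) * s,   c(16, 16, 16) * s),
    femoral_head_R = list(c(-58, 5, 0) * s,  c(16, 16, 16) * s))
  P <- voxel_coords(geo$shape, geo$spacing)
  extent <- geo$shape * geo$spacing / 2
  masks <- with_seed(as.integer(seed) + 20693L, {
    lapply(organs, function(o) {
      ax <- o[[2]] * stats::runif(3, 1 - size_jitter, 1 + size_jitter)
      ctr <- o[[1]] + stats::runif(3, -center_jitter_mm, center_jitter_mm)
      # keep the ellipsoid inside the grid
      ctr <- pmin(pmax(ctr, -extent + ax + 1), extent - ax - 1)
      r2 <- ((P[, 1] - ctr[1]) / ax[1])^2 + ((P[, 2] - ctr[2]) / ax[2])^2 +
        ((P[, 3] - ctr[3]) / ax[3])^2
      array(r2 <= 1, dim = geo$shape)
    })
  })
  # OARs made disjoint from the PTV so ideal doses (1 vs 0) are consistent
  for (nm in setdiff(names(masks), "PTV")) {
    masks[[nm]] <- masks[[nm]] & !masks$PTV
  }
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) {
      stop(sprintf("structure %s is empty; widen the grid or reduce jitter", nm))
    }
  }
  iso <- unname(colMeans(P[as.vector(masks$PTV), , drop = FALSE]))
  ph <- list(grid_shape = geo$shape, spacing = geo$spacing, masks = masks,
             prescription_dose = prescription_dose, isocenter = iso,
             size_class = size_class, seed = as.integer(seed))
  class(ph) <- "vmat_phantom"
  ph
}

#' @export
print.vmat_phantom <- function(x, ...) {
  cat(sprintf("Synthetic pelvic phantom (seed %d, %s): %s grid @ %g mm, Rx %.2f Gy\n",
              x$seed, x$size_class, paste(x$grid_shape, collapse = "x"),
              x$spacing[1], x$prescription_dose))
  for (nm in names(x$masks)) cat(sprintf("  %-15s %d voxels\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

#' Union of the organ-at-risk masks of a phantom
#' @param phantom A `vmat_phantom`.
#' @param structures Which masks to union (default all non-PTV).
#' @return Logical array.
#' @export
oar_union_mask <- function(phantom, structures = setdiff(names(phantom$masks), "PTV")) {
  out <- array(FALSE, dim = phantom$grid_shape)
  for (nm in structures) out <- out | phantom$masks[[nm]]
  out
}

#' Mask centroid in mm (grid-center frame)
#' @param phantom A `vmat_phantom`.
#' @param structure Mask name.
#' @return Length-3 numeric (x, y, z) mm.
#' @export
mask_centroid <- function(phantom, structure) {
  P <- voxel_coords(phantom$grid_shape, phantom$spacing)
  colMeans(P[as.vector(phantom$masks[[structure]]), , drop = FALSE])
}

# 6-connectivity check used by tests and validation
mask_connected <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1) return(length(idx) == 1)
  dims <- dim(mask)
  coord <- arrayInd(idx, dims)
  key <- function(m) m[, 1] + dims[1] * (m[, 2] - 1) + dims[1] * dims[2] * (m[, 3] - 1)
  inside <- rep(FALSE, prod(dims))
  inside[idx] <- TRUE
  seen <- rep(FALSE, prod(dims))
  queue <- idx[1]
  seen[idx[1]] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    cc <- arrayInd(cur, dims)
    for (k in seq_len(6)) {
      nb <- cc + offs[k, , drop = FALSE]
      if (all(nb >= 1) && all(nb <= dims)) {
        ni <- key(nb)
        if (inside[ni] && !seen[ni]) {
          seen[ni] <- TRUE
          queue <- c(queue, ni)
        }
      }
    }
  }
  all(seen[idx])
}

#' Beam's-eye-view conformal expert apertures
#'
#' Constructs the expert demonstration used for behavioral-cloning
#' initialization: at every control point each leaf pair opens exactly to the
#' PTV silhouette projected (parallel rays along the beam axis) into the
#' isocenter plane at that gantry angle, expanded by a margin; pairs onto
#' which the PTV does not project stay closed. The pair covering a voxel is
#' determined by the voxel-center z coordinate; the lateral opening uses the
#' full projected voxel footprint.
#'
#' @param phantom A `vmat_phantom` with a nonempty PTV.
#' @param arc A `vmat_arc`.
#' @param machine A `vmat_machine` on the same machine model.
#' @param margin_cm Lateral margin added to the silhouette, cm (default 0.3).
#' @return A `vmat_expert_demo`: `patient_id`, `apertures`
#'   (`n_cp x 2*leaf_pairs` matrix, cm, X1 block then X2 block).
#' @export
generate_expert_demos <- function(phantom, arc, machine = machine_model(),
                                  margin_cm = 0.3) {
  if (!any(phantom$masks$PTV)) stop("phantom PTV mask is empty")
  P <- voxel_coords(phantom$grid_shape, phantom$spacing)
  ptv <- P[as.vector(phantom$masks$PTV), , drop = FALSE]
  ptv <- sweep(ptv, 2, phantom$isocenter)  # beam frame centered on isocenter
  np <- machine$leaf_pairs
  edges <- leaf_pair_edges(machine)  # cm
  hw <- machine$field_half_width
  sp <- phantom$spacing
  zc <- ptv[, 3] / 10  # cm
  pair_of <- rep(NA_integer_, nrow(ptv))
  for (j in seq_len(np)) {
    pair_of[zc >= edges[j, "z_lo"] & zc < edges[j, "z_hi"]] <- j
  }
  apertures <- matrix(0, arc$n_cp, 2L * np)
  for (t in seq_len(arc$n_cp)) {
    th <- arc$cp_angles[t] * pi / 180
    u <- (ptv[, 1] * cos(th) - ptv[, 2] * sin(th)) / 10  # cm
    half_u <- (abs(cos(th)) * sp[1] + abs(sin(th)) * sp[2]) / 2 / 10
    for (j in seq_len(np)) {
      sel <- which(pair_of == j)
      if (length(sel)) {
        x1 <- min(u[sel] - half_u) - margin_cm
        x2 <- max(u[sel] + half_u) + margin_cm
        apertures[t, j] <- max(x1, -hw)
        apertures[t, np + j] <- min(x2, hw)
      }
    }
  }
  demo <- list(patient_id = sprintf("phantom-%d", phantom$seed %||% 0L),
               apertures = apertures)
  class(demo) <- "vmat_expert_demo"
  demo
}

#' Build a plan from an expert demonstration
#'
#' Combines conformal apertures with a uniform MU per control point chosen so
#' the uncalibrated mean PTV dose is of the order of the prescription (the
#' absolute scale is irrelevant after D95 anchoring) while respecting the
#' per-CP MU limit.
#'
#' @param demo A `vmat_expert_demo`.
#' @param arc A `vmat_arc`.
#' @param machine A `vmat_machine`.
#' @param mu_per_cp Uniform MU per CP; default half the per-CP MU limit.
#' @return A `vmat_plan`.
#' @export
expert_plan <- function(demo, arc, machine = machine_model(), mu_per_cp = NULL) {
  if (is.null(mu_per_cp)) mu_per_cp <- max_cp_mu(machine) / 2
  new_plan(arc, demo$apertures, rep(mu_per_cp, arc$n_cp), machine = machine,
           patient_id = demo$patient_id)
}

#' Serialize a phantom to a directory
#'
#' Writes `phantom.yaml` (geometry, prescription, isocenter, provenance) and
#' one run-length-encoded plain-text mask file per structure under `masks/`.
#' The round-trip through [read_phantom()] is bit-identical.
#'
#' @param phantom A `vmat_phantom`.
#' @param dir Output directory (created if missing).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "vmatrl-phantom-v1",
               grid_shape = as.integer(phantom$grid_shape),
               spacing_mm = as.numeric(phantom$spacing),
               prescription_dose_gy = phantom$prescription_dose,
               isocenter_mm = as.numeric(phantom$isocenter),
               size_class = phantom$size_class, seed = phantom$seed,
               masks = names(phantom$masks))
  yaml::write_yaml(meta, file.path(dir, "phantom.yaml"), precision = 17)
  for (nm in names(phantom$masks)) {
    writeLines(rle_encode(as.vector(phantom$masks[[nm]])),
               file.path(dir, "masks", paste0(nm, ".rle.txt")))
  }
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#' @param dir Directory holding `phantom.yaml` and `masks/`.
#' @return A `vmat_phantom`.
#' @export
read_phantom <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "phantom.yaml"))
  if (is.null(meta$format) || meta$format != "vmatrl-phantom-v1") {
    stop("not a vmatrl phantom directory")
  }
  shape <- as.integer(meta$grid_shape)
  masks <- lapply(meta$masks, function(nm) {
    s <- readLines(file.path(dir, "masks", paste0(nm, ".rle.txt")))
    array(rle_decode(paste(s, collapse = " "), prod(shape)), dim = shape)
  })
  names(masks) <- meta$masks
  ph <- list(grid_shape = shape, spacing = as.numeric(meta$spacing_mm),
             masks = masks, prescription_dose = meta$prescription_dose_gy,
             isocenter = as.numeric(meta$isocenter_mm),
             size_class = meta$size_class, seed = meta$seed)
  class(ph) <- "vmat_phantom"
  ph
}
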