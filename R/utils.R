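# internal helpers shared across modules

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# voxel-center coordinates (mm) relative to the grid center, one row per voxel
# in column-major (array) order
voxel_coords <- function(grid_shape, spacing) {
  ax <- lapply(seq_along(grid_shape), function(i) {
    (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * spacing[i]
  })
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]], KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

# nearest-neighbour index map rotating a volume by `angle_deg` about the
# z axis through `center_mm` (grid-center-relative); voxels sampling outside
# the grid map to the zero pad index n_vox + 1
rotation_index <- function(grid_shape, spacing, angle_deg, center_mm = c(0, 0, 0)) {
  P <- voxel_coords(grid_shape, spacing)
  th <- angle_deg * pi / 180
  xr <- P[, 1] - center_mm[1]
  yr <- P[, 2] - center_mm[2]
  # source coordinates: rotate the target grid backwards
  xs <- cos(th) * xr + sin(th) * yr + center_mm[1]
  ys <- -sin(th) * xr + cos(th) * yr + center_mm[2]
  ix <- round(xs / spacing[1] + (grid_shape[1] + 1) / 2)
  iy <- round(ys / spacing[2] + (grid_shape[2] + 1) / 2)
  iz <- round(P[, 3] / spacing[3] + (grid_shape[3] + 1) / 2)
  ok <- ix >= 1 & ix <= grid_shape[1] & iy >= 1 & iy <= grid_shape[2] &
    iz >= 1 & iz <= grid_shape[3]
  idx <- ifelse(ok, ix + grid_shape[1] * (iy - 1) +
                  grid_shape[1] * grid_shape[2] * (iz - 1),
                prod(grid_shape) + 1L)
  as.integer(idx)
}

# run-length encode / decode a logical vector as an integer run-length string
rle_encode <- function(x) {
  r <- rle(as.integer(x))
  paste(paste(r$values, r$lengths, sep = ":"), collapse = " ")
}

rle_decode <- function(s, n) {
  parts <- strsplit(strsplit(trimws(s), " +")[[1]], ":", fixed = TRUE)
  vals <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  lens <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  out <- inverse.rle(structure(list(lengths = lens, values = vals), class = "rle"))
  if (length(out) != n) stop("run-length payload does not match grid size")
  as.logical(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
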