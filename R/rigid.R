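## Rigid-body resampling shared by the phantom generator (which applies
## motion) and the realignment stage (which undoes it).
##
## Parameter convention: theta = (rot_x, rot_y, rot_z [deg],
## trans_x, trans_y, trans_z [mm]).  The forward map acts on mm coordinates
## about the volume centre: T(x) = R_z R_y R_x (x - c) + c + t.  A moving
## volume is modelled as moved(x) = clean(T(x)); realignment resamples the
## moved volume at T^{-1}(x).

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

## trilinear interpolation at continuous 1-based voxel coordinates
## (n x 3 matrix); coordinates are clamped to the volume (edge replication)
trilinear_interp <- function(vol, pts) {
  d <- dim(vol)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), d[2] - 1L); y1 <- y0 + 1
  z0 <- pmin(floor(z), d[3] - 1L); z1 <- z0 + 1
  if (d[1] == 1L) { x0 <- x1 <- rep(1, length(x)) }
  if (d[2] == 1L) { y0 <- y1 <- rep(1, length(y)) }
  if (d[3] == 1L) { z0 <- z1 <- rep(1, length(z)) }
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  v000 <- vol[idx(x0, y0, z0)]; v100 <- vol[idx(x1, y0, z0)]
  v010 <- vol[idx(x0, y1, z0)]; v110 <- vol[idx(x1, y1, z0)]
  v001 <- vol[idx(x0, y0, z1)]; v101 <- vol[idx(x1, y0, z1)]
  v011 <- vol[idx(x0, y1, z1)]; v111 <- vol[idx(x1, y1, z1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

## sampling coordinates (voxel units) for a rigid transform of a grid;
## `grid_offset_vox` shifts the target grid by a sub-voxel amount (used by
## the registration cost so that no candidate transform samples exactly on
## grid nodes, which would be spuriously blur-free)
rigid_sample_points <- function(d, theta, voxel_size_mm, inverse,
                                grid_offset_vox = c(0, 0, 0)) {
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  g <- sweep(g, 2, grid_offset_vox, `+`)
  mm <- sweep(g - 1, 2, voxel_size_mm, `*`)
  centre <- (d - 1) / 2 * voxel_size_mm
  R <- rotation_matrix(theta[1:3])
  t_mm <- theta[4:6]
  if (inverse) {
    out <- sweep((sweep(mm, 2, centre + t_mm, `-`)) %*% R, 2, centre, `+`)
  } else {
    out <- sweep(sweep(mm, 2, centre, `-`) %*% t(R), 2, centre + t_mm, `+`)
  }
  sweep(out, 2, voxel_size_mm, `/`) + 1
}

## Lanczos-3 windowed-sinc interpolation at continuous 1-based voxel
## coordinates; separable, edge-clamped.  Near-exact for band-limited
## volumes, which trilinear interpolation visibly blurs.
lanczos3_interp <- function(vol, pts) {
  d <- dim(vol)
  a <- 3
  lanc <- function(x) {
    out <- rep(0, length(x))
    nz <- abs(x) < a
    xi <- x[nz]
    out[nz] <- ifelse(abs(xi) < 1e-12, 1,
                      a * sin(pi * xi) * sin(pi * xi / a) / (pi^2 * xi^2))
    out
  }
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  offs <- (-a + 1):a
  wx <- vapply(offs, function(o) lanc(x - (x0 + o)), numeric(length(x)))
  wy <- vapply(offs, function(o) lanc(y - (y0 + o)), numeric(length(y)))
  wz <- vapply(offs, function(o) lanc(z - (z0 + o)), numeric(length(z)))
  wx <- wx / rowSums(wx); wy <- wy / rowSums(wy); wz <- wz / rowSums(wz)
  acc <- numeric(length(x))
  for (i in seq_along(offs)) {
    xi <- cl(x0 + offs[i], d[1])
    for (j in seq_along(offs)) {
      yj <- cl(y0 + offs[j], d[2])
      wij <- wx[, i] * wy[, j]
      for (k in seq_along(offs)) {
        zk <- cl(z0 + offs[k], d[3])
        acc <- acc + wij * wz[, k] *
          vol[xi + (yj - 1) * d[1] + (zk - 1) * d[1] * d[2]]
      }
    }
  }
  acc
}

## resample one 3D volume under a rigid transform
rigid_resample <- function(vol, theta, voxel_size_mm, inverse = FALSE,
                           method = c("linear", "lanczos")) {
  method <- match.arg(method)
  if (all(theta == 0)) return(vol)
  d <- dim(vol)
  pts <- rigid_sample_points(d, theta, voxel_size_mm, inverse)
  vals <- if (method == "lanczos") lanczos3_interp(vol, pts)
  else trilinear_interp(vol, pts)
  array(vals, dim = d)
}

## phase volumes are resampled on the unit circle: interpolate cos/sin and
## recombine through the angle, avoiding wrap artefacts
rigid_resample_phase <- function(vol, theta, voxel_size_mm, inverse = FALSE,
                                 method = c("linear", "lanczos")) {
  method <- match.arg(method)
  if (all(theta == 0)) return(vol)
  d <- dim(vol)
  pts <- rigid_sample_points(d, theta, voxel_size_mm, inverse)
  fn <- if (method == "lanczos") lanczos3_interp else trilinear_interp
  c_i <- fn(cos(vol), pts)
  s_i <- fn(sin(vol), pts)
  array(atan2(s_i, c_i), dim = d)
}
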