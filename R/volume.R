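#' Scalar volume
#'
#' A 3D intensity grid with voxel spacing and a voxel-to-world affine, the
#' container used throughout the filtering and segmentation stages.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Voxel size per axis in mm (length 3, strictly positive).
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal scaling
#'   by `spacing`.
#' @return An object of class `scalar_volume` with fields `data`, `spacing`
#'   and `affine`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  nbad <- sum(!is.finite(data))
  if (nbad > 0)
    stop(sprintf("volume contains %d non-finite voxel(s)", nbad))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, range [", signif(min(x$data), 6), ", ", signif(max(x$data), 6),
      "]\n", sep = "")
  invisible(x)
}

as_volume <- function(v) {
  if (inherits(v, "scalar_volume")) return(v)
  scalar_volume(v)
}

#' Binary mask
#'
#' @param data 3D logical (or 0/1) array.
#' @param spacing,affine As in [scalar_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "binary_mask")
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving spacing and affine.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1, drop = TRUE]
  dim(arr) <- dim(arr)[1:3]
  scalar_volume(arr,
                spacing = RNifti::pixdim(img)[1:3],
                affine = unclass(RNifti::xform(img)))
}

#' @rdname read_volume
#' @param vol A [scalar_volume()] or [binary_mask()].
#' @export
write_volume <- function(vol, path) {
  arr <- vol$data
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 1D normalized Gaussian kernel, radius 4 sigma
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# dense smoothing matrix along one axis with mirrored boundary; rows sum to 1
smooth_matrix <- function(n, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    j <- seq_len(n) + off
    # mirror about the boundary voxels
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + k[off + r + 1L]
  }
  K
}

smooth_axis <- function(arr, axis, sigma) {
  d <- dim(arr)
  K <- smooth_matrix(d[axis], sigma)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  a <- array(K %*% m, dim = d[perm])
  aperm(a, order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with mirrored boundaries; the kernel is
#' normalized so constants are preserved exactly. `sigma` is expressed in
#' voxels.
#'
#' @param v A [scalar_volume()] or 3D array.
#' @param sigma Non-negative standard deviation in voxels; `sigma = 0` returns
#'   the input unchanged.
#' @return A volume of the same shape and class as the input.
#' @export
gaussian_smooth <- function(v, sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number")
  isvol <- inherits(v, "scalar_volume")
  arr <- if (isvol) v$data else v
  nbad <- sum(!is.finite(arr))
  if (nbad > 0)
    stop(sprintf("input contains %d non-finite voxel(s)", nbad))
  if (sigma == 0) return(v)
  for (axis in 1:3) arr <- smooth_axis(arr, axis, sigma)
  if (isvol) scalar_volume(arr, v$spacing, v$affine) else arr
}

# central-difference gradient with replicated boundary values; physical units
grad_cd <- function(arr, spacing = c(1, 1, 1)) {
  d <- dim(arr)
  sh <- function(axis, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    i <- idx[[axis]] + by
    i[i < 1L] <- 1L
    i[i > d[axis]] <- d[axis]
    idx[[axis]] <- i
    arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  list(
    (sh(1, 1L) - sh(1, -1L)) / (2 * spacing[1]),
    (sh(2, 1L) - sh(2, -1L)) / (2 * spacing[2]),
    (sh(3, 1L) - sh(3, -1L)) / (2 * spacing[3])
  )
}

# divergence with zero-flux boundaries: ghost fluxes are anti-reflected so the
# grid total is conserved exactly (discrete divergence theorem)
div_zeroflux <- function(fx, fy, fz, spacing = c(1, 1, 1)) {
  d <- dim(fx)
  axis_div <- function(f, axis) {
    n <- d[axis]
    ix <- function(i) {
      a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      a[[axis]] <- i
      f[a[[1]], a[[2]], a[[3]], drop = FALSE]
    }
    plus <- ix(pmin(seq_len(n) + 1L, n))
    minus <- ix(pmax(seq_len(n) - 1L, 1L))
    # overwrite the boundary slices with anti-reflected ghosts
    asn <- function(target, i, value) {
      a <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      a[[axis]] <- i
      target[a[[1]], a[[2]], a[[3]]] <- value
      target
    }
    plus <- asn(plus, n, -ix(n))
    minus <- asn(minus, 1L, -ix(1L))
    (plus - minus) / (2 * spacing[axis])
  }
  axis_div(fx, 1) + axis_div(fy, 2) + axis_div(fz, 3)
}

#' Trilinear resampling to a new isotropic voxel size
#'
#' Optional pre-step before filtering; used to bring volumes to finer
#' resolution (e.g. 0.5 mm isotropic).
#'
#' @param v A [scalar_volume()].
#' @param new_spacing Target isotropic voxel size (mm).
#' @return A resampled [scalar_volume()].
#' @export
resample_volume <- function(v, new_spacing) {
  stopifnot(inherits(v, "scalar_volume"), new_spacing > 0)
  d <- dim(v$data)
  newd <- pmax(2L, as.integer(round((d - 1) * v$spacing / new_spacing)) + 1L)
  gx <- seq(1, d[1], length.out = newd[1])
  gy <- seq(1, d[2], length.out = newd[2])
  gz <- seq(1, d[3], length.out = newd[3])
  x0 <- pmin(floor(gx), d[1] - 1); y0 <- pmin(floor(gy), d[2] - 1)
  z0 <- pmin(floor(gz), d[3] - 1)
  tx <- gx - x0; ty <- gy - y0; tz <- gz - z0
  out <- array(0, newd)
  A <- v$data
  for (dz in 0:1) {
    wz <- if (dz == 0) (1 - tz) else tz
    for (dy in 0:1) {
      wy <- if (dy == 0) (1 - ty) else ty
      for (dx in 0:1) {
        wx <- if (dx == 0) (1 - tx) else tx
        block <- A[x0 + dx, y0 + dy, z0 + dz, drop = FALSE]
        w <- outer(outer(wx, wy), wz)
        out <- out + block * array(w, newd)
      }
    }
  }
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] %*% diag((d - 1) / (newd - 1))
  scalar_volume(out, spacing = rep(new_spacing, 3), affine = aff)
}
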