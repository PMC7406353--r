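#' Joint intensity / gradient-magnitude histogram
#'
#' Bins every (in-mask) voxel by its intensity and central-difference gradient
#' magnitude. Bin edges are linear between robust percentiles (0.5th-99.5th by
#' default); values outside the edges are clamped into the boundary bins so
#' counts always conserve the voxel total.
#'
#' @param v A [scalar_volume()] or 3D array.
#' @param n_bins_intensity,n_bins_gradmag Number of bins per axis (>= 2).
#' @param mask Optional [binary_mask()] restricting the voxels considered.
#' @param probs Robust percentile pair used for the bin range.
#' @return A `joint_histogram` with `counts`, `int_edges`, `grad_edges`.
#' @export
joint_histogram <- function(v, n_bins_intensity = 100, n_bins_gradmag = 100,
                            mask = NULL, probs = c(0.005, 0.995)) {
  if (n_bins_intensity < 2 || n_bins_gradmag < 2)
    stop("need at least 2 bins per axis")
  vol <- as_volume(v)
  g <- grad_cd(vol$data, vol$spacing)
  gm <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  keep <- if (is.null(mask)) rep(TRUE, length(vol$data)) else as.vector(mask$data)
  iv <- as.vector(vol$data)[keep]
  gv <- as.vector(gm)[keep]
  edges <- function(x, n) {
    r <- unname(quantile(x, probs))
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = n + 1L)
  }
  ie <- edges(iv, n_bins_intensity)
  ge <- edges(gv, n_bins_gradmag)
  bin <- function(x, e) pmin(pmax(findInterval(x, e, all.inside = TRUE), 1L),
                             length(e) - 1L)
  bi <- bin(iv, ie)
  bg <- bin(gv, ge)
  counts <- matrix(0L, n_bins_intensity, n_bins_gradmag)
  tab <- table(factor(bi, levels = seq_len(n_bins_intensity)),
               factor(bg, levels = seq_len(n_bins_gradmag)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, int_edges = ie, grad_edges = ge,
                 n = length(iv)),
            class = "joint_histogram")
}

#' Write a joint histogram as CSV (edges then counts)
#' @param h A `joint_histogram`.
#' @param path Output file.
#' @export
write_histogram_csv <- function(h, path) {
  df <- as.data.frame(as.table(h$counts))
  names(df) <- c("intensity_bin", "gradmag_bin", "count")
  df$intensity_bin <- as.integer(df$intensity_bin)
  df$gradmag_bin <- as.integer(df$gradmag_bin)
  df$intensity_lo <- h$int_edges[df$intensity_bin]
  df$intensity_hi <- h$int_edges[df$intensity_bin + 1L]
  df$gradmag_lo <- h$grad_edges[df$gradmag_bin]
  df$gradmag_hi <- h$grad_edges[df$gradmag_bin + 1L]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Selection region in (intensity, gradient-magnitude) space
#'
#' Either an axis-aligned box (`intensity` and `gradmag` ranges) or a polygon
#' (matrix with columns intensity, gradmag). Regions are explicit and
#' serializable (JSON) so selections are reproducible without a GUI.
#'
#' @param intensity,gradmag Length-2 numeric ranges (box form).
#' @param polygon Optional k x 2 matrix of polygon vertices; overrides the box.
#' @return A `histogram_region`.
#' @export
histogram_region <- function(intensity = NULL, gradmag = NULL, polygon = NULL) {
  if (is.null(polygon)) {
    stopifnot(length(intensity) == 2L, length(gradmag) == 2L)
    if (diff(intensity) <= 0 || diff(gradmag) <= 0)
      stop("region has degenerate area")
    structure(list(type = "box", intensity = sort(intensity),
                   gradmag = sort(gradmag)), class = "histogram_region")
  } else {
    polygon <- as.matrix(polygon)
    if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
    structure(list(type = "polygon", polygon = polygon),
              class = "histogram_region")
  }
}

#' @rdname histogram_region
#' @param region A `histogram_region`.
#' @param path JSON file path.
#' @export
write_region_json <- function(region, path) {
  jsonlite::write_json(unclass(region), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname histogram_region
#' @export
read_region_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$type, "box"))
    histogram_region(intensity = x$intensity, gradmag = x$gradmag)
  else histogram_region(polygon = x$polygon)
}

# even-odd rule point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Binary mask from a histogram-space region
#'
#' A voxel is included iff its (intensity, gradient-magnitude) pair falls
#' inside the region (and inside `mask`, when given). Deterministic; an empty
#' selection yields a valid all-zero mask with a warning.
#'
#' @param v A [scalar_volume()] or 3D array.
#' @param region A [histogram_region()].
#' @param mask Optional [binary_mask()] restriction.
#' @return A [binary_mask()].
#' @export
mask_from_region <- function(v, region, mask = NULL) {
  stopifnot(inherits(region, "histogram_region"))
  vol <- as_volume(v)
  g <- grad_cd(vol$data, vol$spacing)
  gm <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  iv <- as.vector(vol$data)
  gv <- as.vector(gm)
  sel <- if (region$type == "box") {
    iv >= region$intensity[1] & iv <= region$intensity[2] &
      gv >= region$gradmag[1] & gv <= region$gradmag[2]
  } else {
    point_in_polygon(iv, gv, region$polygon)
  }
  if (!is.null(mask)) sel <- sel & as.vector(mask$data)
  if (!any(sel)) warning("region selects no voxels; returning an empty mask")
  out <- array(sel, dim(vol$data))
  binary_mask(out, vol$spacing, vol$affine)
}

#' Split a mask at a sagittal plane
#'
#' Utility for separating hemispheres: voxels with first-axis index up to
#' `plane` go left, the rest right.
#'
#' @param mask A [binary_mask()].
#' @param plane Cut index along the first axis; defaults to the middle.
#' @return A list with `left` and `right` masks.
#' @export
split_sagittal <- function(mask, plane = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$data)
  if (is.null(plane)) plane <- d[1] %/% 2L
  left <- mask$data
  left[(plane + 1L):d[1], , ] <- FALSE
  right <- mask$data
  right[1:plane, , ] <- FALSE
  list(left = binary_mask(left, mask$spacing, mask$affine),
       right = binary_mask(right, mask$spacing, mask$affine))
}
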