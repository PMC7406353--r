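#' Triangular surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat("<", class(x)[1], "> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

# unique undirected edges as a 2-column matrix (a < b)
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e[, 1] * (max(e) + 1) + e[, 2]), , drop = FALSE]
}

# sparse row-normalized vertex adjacency (neighbor averaging operator)
neighbor_average_matrix <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) stop("mesh has isolated vertices")
  Matrix::Diagonal(x = 1 / deg) %*% A
}

#' Euler characteristic of a mesh
#'
#' `V - E + F` with edges counted once (undirected). Every genus-0 closed
#' surface gives 2, a torus 0; this is the acceptance gate applied to every
#' cortical mesh before inflation.
#'
#' @param m A `trimesh`.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(m) {
  stopifnot(inherits(m, "trimesh"))
  nrow(m$vertices) - nrow(mesh_edges(m$faces)) + nrow(m$faces)
}

# ---------------------------------------------------------------------------
# standard icosphere

ico_base <- function() {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(V = V, F = F)
}

face_dets <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    b[, 1] * (a[, 2] * c_[, 3] - a[, 3] * c_[, 2]) +
    c_[, 1] * (a[, 2] * b[, 3] - a[, 3] * b[, 2])
}

#' Standard icosphere
#'
#' Recursive midpoint subdivision of the icosahedron; level L has
#' `10 * 4^L + 2` vertices (level 7: 163842, the standard high-density
#' sphere). Vertices of lower levels keep their indices at higher levels and
#' all faces are counter-clockwise seen from outside.
#'
#' @param level Subdivision level (>= 0).
#' @return A mesh of classes `icosphere`, `spherical_mesh`, `trimesh` with a
#'   `level` field.
#' @export
icosphere <- function(level) {
  stopifnot(level >= 0, level == round(level))
  base <- ico_base()
  V <- base$V
  F <- base$F
  for (l in seq_len(level)) {
    n <- nrow(V)
    key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
    e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(1, 3)])
    k <- key(e[, 1], e[, 2])
    uk <- unique(k)                        # same order as first occurrences
    mid_idx <- n + match(k, uk)            # index of each face-edge midpoint
    ua <- e[!duplicated(k), , drop = FALSE]
    mids <- (V[ua[, 1], , drop = FALSE] + V[ua[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    V <- rbind(V, mids)
    nf <- nrow(F)
    mab <- mid_idx[seq_len(nf)]
    mbc <- mid_idx[nf + seq_len(nf)]
    mac <- mid_idx[2 * nf + seq_len(nf)]
    F <- rbind(cbind(F[, 1], mab, mac),
               cbind(F[, 2], mbc, mab),
               cbind(F[, 3], mac, mbc),
               cbind(mab, mbc, mac))
  }
  if (any(face_dets(V, F) <= 0)) F <- F[, c(1, 3, 2)]
  m <- trimesh(V, F)
  m$level <- as.integer(level)
  class(m) <- c("icosphere", "spherical_mesh", "trimesh")
  m
}

# ---------------------------------------------------------------------------
# mesh extraction (marching tetrahedra on the 0.5 iso-level of a binary mask)

# 6-tetrahedra decomposition of the unit cube around the 0-7 diagonal;
# corners indexed by bits (x, y, z)
mt_tets <- rbind(c(0, 1, 3, 7), c(0, 3, 2, 7), c(0, 2, 6, 7),
                 c(0, 6, 4, 7), c(0, 4, 5, 7), c(0, 5, 1, 7))
mt_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
# triangles (rows of local edge ids) per 4-bit inside mask
mt_tris <- list(
  NULL,                                    #  0: 0000
  rbind(c(1, 2, 3)),                       #  1: v1
  rbind(c(1, 4, 5)),                       #  2: v2
  rbind(c(2, 4, 5), c(2, 5, 3)),           #  3: v1 v2
  rbind(c(2, 4, 6)),                       #  4: v3
  rbind(c(1, 4, 6), c(1, 6, 3)),           #  5: v1 v3
  rbind(c(1, 2, 6), c(1, 6, 5)),           #  6: v2 v3
  rbind(c(3, 5, 6)),                       #  7: v1 v2 v3
  rbind(c(3, 5, 6)),                       #  8: v4
  rbind(c(1, 2, 6), c(1, 6, 5)),           #  9: v1 v4
  rbind(c(1, 4, 6), c(1, 6, 3)),           # 10: v2 v4
  rbind(c(2, 4, 6)),                       # 11: v1 v2 v4
  rbind(c(2, 4, 5), c(2, 5, 3)),           # 12: v3 v4
  rbind(c(1, 4, 5)),                       # 13: v1 v3 v4
  rbind(c(1, 2, 3)),                       # 14: v2 v3 v4
  NULL)                                    # 15: all

#' Extract a closed surface mesh from a binary mask
#'
#' Marching tetrahedra on the 0.5 iso-level of the binary field, with one
#' voxel of zero padding so surfaces close at the volume border. To avoid
#' half-voxel staircase artifacts the binary field is first band-limited by a
#' small Gaussian (`presmooth`, in voxels) and iso-vertices are placed by
#' linear interpolation at the 0.5 level; set `presmooth = 0` for raw binary
#' extraction (vertices at voxel-edge midpoints). The mask must contain a
#' single 6-connected foreground component. Output coordinates are world mm
#' through the mask affine; faces are consistently oriented with outward
#' normals.
#'
#' @param mask A [binary_mask()].
#' @param presmooth Antialiasing smoothing of the binary field in voxels
#'   (default 1).
#' @return A closed, oriented `trimesh`.
#' @export
extract_mesh <- function(mask, presmooth = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("mask is empty")
  comp <- mask_components(mask$data)
  if (comp$n > 1L)
    stop(sprintf("mask has %d connected components (sizes: %s)", comp$n,
                 paste(sort(comp$sizes, decreasing = TRUE), collapse = ", ")))
  A <- array(0, dim(mask$data) + 2L)
  A[2:(dim(mask$data)[1] + 1), 2:(dim(mask$data)[2] + 1),
    2:(dim(mask$data)[3] + 1)] <- as.numeric(mask$data)
  if (presmooth > 0) A <- gaussian_smooth(A, presmooth)
  d <- dim(A)
  i <- seq_len(d[1] - 1L); j <- seq_len(d[2] - 1L); k <- seq_len(d[3] - 1L)
  corner_val <- function(dx, dy, dz) A[i + dx, j + dy, k + dz]
  offs <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)  # bit order x, y, z
  cvals <- lapply(seq_len(8), function(b)
    as.integer(corner_val(offs$dx[b], offs$dy[b], offs$dz[b]) > 0.5))
  S <- Reduce(`+`, cvals)
  active <- which(S > 0L & S < 8L)
  if (!length(active)) stop("mask is empty")
  ai <- arrayInd(active, d - 1L)
  cube_dim <- d - 1L
  # global corner ids (linear index into the padded grid) per active cube
  cid <- sapply(seq_len(8), function(b) {
    (ai[, 1] + offs$dx[b]) +
      (ai[, 2] + offs$dy[b] - 1L) * d[1] +
      (ai[, 3] + offs$dz[b] - 1L) * d[1] * d[2]
  })
  cin <- sapply(seq_len(8), function(b) cvals[[b]][active])
  if (length(active) == 1L) { cid <- matrix(cid, 1); cin <- matrix(cin, 1) }

  tri_a <- tri_b <- list()  # endpoints (global corner ids) of each tri vertex
  ins_c <- out_c <- list()  # per-triangle inside/outside corner centroids
  KEY <- as.numeric(prod(d)) + 1
  coord_of <- function(id) arrayInd(id, d)
  for (t in seq_len(6)) {
    lv <- mt_tets[t, ] + 1L
    verts <- cid[, lv, drop = FALSE]
    inb <- cin[, lv, drop = FALSE]
    msk <- inb[, 1] + 2L * inb[, 2] + 4L * inb[, 3] + 8L * inb[, 4]
    for (mval in 1:14) {
      tris <- mt_tris[[mval + 1L]]
      if (is.null(tris)) next
      rows <- which(msk == mval)
      if (!length(rows)) next
      vin <- matrix(as.logical(bitwAnd(mval, c(1L, 2L, 4L, 8L))), 1)[rep(1, length(rows)), , drop = FALSE]
      # centroids of inside and outside tet corners (padded-grid coords)
      pc <- lapply(1:4, function(c4) coord_of(verts[rows, c4]))
      nin <- sum(vin[1, ])
      ic <- Reduce(`+`, lapply(which(vin[1, ]), function(c4) pc[[c4]])) / nin


      oc <- Reduce(`+`, lapply(which(!vin[1, ]), function(c4) pc[[c4]])) /
        (4 - nin)
      for (r in seq_len(nrow(tris))) {
        ea <- mt_edges[tris[r, ], 1]
        eb <- mt_edges[tris[r, ], 2]
        tri_a[[length(tri_a) + 1L]] <- cbind(verts[rows, ea[1]],
                                             verts[rows, ea[2]],
                                             verts[rows, ea[3]])
        tri_b[[length(tri_b) + 1L]] <- cbind(verts[rows, eb[1]],
                                             verts[rows, eb[2]],
                                             verts[rows, eb[3]])
        ins_c[[length(ins_c) + 1L]] <- ic
        out_c[[length(out_c) + 1L]] <- oc
      }
    }
  }
  Ta <- do.call(rbind, tri_a)
  Tb <- do.call(rbind, tri_b)
  IC <- do.call(rbind, ins_c)
  OC <- do.call(rbind, out_c)
  keys <- pmin(Ta, Tb) * KEY + pmax(Ta, Tb)
  uk <- unique(as.vector(keys))
  Fidx <- matrix(match(as.vector(keys), uk), ncol = 3)
  ka <- floor(uk / KEY)
  kb <- uk - ka * KEY
  va <- A[ka]
  vb <- A[kb]
  tt <- (0.5 - va) / (vb - va)
  tt <- pmin(pmax(tt, 0.01), 0.99)
  pa <- coord_of(ka)
  pb <- coord_of(kb)
  Vpos <- pa + tt * (pb - pa)
  # orient: normal must point from the inside-corner centroid outwards
  p1 <- Vpos[Fidx[, 1], , drop = FALSE]
  p2 <- Vpos[Fidx[, 2], , drop = FALSE]
  p3 <- Vpos[Fidx[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)
  dvec <- OC - IC
  flip <- rowSums(nrm * dvec) < 0
  Fidx[flip, ] <- Fidx[flip, c(1, 3, 2), drop = FALSE]
  # padded-grid coords -> 0-based voxel coords -> world mm
  vox <- Vpos - 2
  world <- cbind(vox, 1) %*% t(mask$affine)
  trimesh(world[, 1:3, drop = FALSE], Fidx)
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# connected components of a 3D logical array (6-connectivity) via igraph
mask_components <- function(arr) {
  idx <- which(arr)
  if (!length(idx)) return(list(n = 0L, sizes = integer(0)))
  d <- dim(arr)
  lab <- array(0L, d)
  lab[idx] <- seq_along(idx)
  edges <- list()
  for (axis in 1:3) {
    sel <- slice.index(arr, axis) < d[axis]
    nb <- c(1L, d[1], d[1] * d[2])[axis]
    here <- which(arr & sel)
    there <- here + nb
    keep <- arr[there]
    edges[[axis]] <- cbind(lab[here[keep]], lab[there[keep]])
  }
  E <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(E, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(n = comp$no, sizes = comp$csize)
}

# ---------------------------------------------------------------------------
# decimation

# per-vertex quadric error matrices (sum of incident face plane quadrics),
# returned as an n x 10 matrix of the unique components of the symmetric 4x4
vertex_quadrics <- function(V, F) {
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)
  nn <- sqrt(rowSums(nrm^2))
  nn[nn == 0] <- 1
  nrm <- nrm / nn
  dpl <- -rowSums(nrm * p1)
  # plane vector (a, b, c, d); quadric = outer product, 10 unique components
  pl <- cbind(nrm, dpl)
  comb <- cbind(pl[, 1]^2, pl[, 1] * pl[, 2], pl[, 1] * pl[, 3],
                pl[, 1] * pl[, 4], pl[, 2]^2, pl[, 2] * pl[, 3],
                pl[, 2] * pl[, 4], pl[, 3]^2, pl[, 3] * pl[, 4], pl[, 4]^2)
  Q <- matrix(0, nrow(V), 10)
  for (c4 in 1:3) {
    rs <- rowsum(comb, F[, c4])
    rows <- as.integer(rownames(rs))
    Q[rows, ] <- Q[rows, ] + rs
  }
  Q
}

# optimal collapse position for quadric q (length 10), midpoint fallback
qem_position <- function(q, mid, maxdist) {
  A <- matrix(c(q[1], q[2], q[3],
                q[2], q[5], q[6],
                q[3], q[6], q[8]), 3, 3)
  b <- -c(q[4], q[7], q[9])
  x <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(x) || !all(is.finite(x)) ||
      sqrt(sum((x - mid)^2)) > maxdist) mid else x
}

#' Decimate a mesh to a target vertex count
#'
#' Iterative shortest-edge collapse with link-condition checks; collapsing
#' the shortest edges first equalizes edge lengths, and the merged vertex is
#' placed at the position minimizing the summed quadric (plane-distance)
#' error of the two endpoints, which prevents the shrinkage of curved
#' surfaces (midpoint fallback when the quadric is degenerate). The Euler
#' characteristic is preserved. Meshes already at or below the target are
#' returned unchanged.
#'
#' @param m A `trimesh`.
#' @param target_vertices Desired vertex count (>= 4).
#' @return A decimated `trimesh`.
#' @export
decimate <- function(m, target_vertices) {
  stopifnot(inherits(m, "trimesh"), target_vertices >= 4)
  V <- m$vertices
  F <- m$faces
  Q <- vertex_quadrics(V, F)  # accumulated through collapses (standard QEM)
  while (nrow(V) > target_vertices) {
    n <- nrow(V)
    E <- mesh_edges(F)
    len <- sqrt(rowSums((V[E[, 1], , drop = FALSE] -
                           V[E[, 2], , drop = FALSE])^2))
    A <- Matrix::sparseMatrix(i = c(E[, 1], E[, 2]), j = c(E[, 2], E[, 1]),
                              x = 1, dims = c(n, n))
    CN <- A %*% A
    common <- CN[cbind(E[, 1], E[, 2])]
    ok <- common == 2
    need <- n - target_vertices
    used <- logical(n)
    sel <- integer(0)
    for (e in order(len)) {
      if (!ok[e]) next
      a <- E[e, 1]; b <- E[e, 2]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      sel <- c(sel, e)
      if (length(sel) >= need) break
    }
    if (!length(sel))
      stop("no collapsible edges left; further decimation would break manifoldness")
    keep <- E[sel, 1]
    drop_ <- E[sel, 2]
    for (ii in seq_along(sel)) {
      a <- keep[ii]; b <- E[sel[ii], 2]
      mid <- (V[a, ] + V[b, ]) / 2
      Q[a, ] <- Q[a, ] + Q[b, ]
      V[a, ] <- qem_position(Q[a, ], mid, 3 * len[sel[ii]])
    }
    map <- seq_len(n)
    map[drop_] <- keep
    F2 <- matrix(map[F], ncol = 3)
    deg <- F2[, 1] == F2[, 2] | F2[, 2] == F2[, 3] | F2[, 1] == F2[, 3]
    F2 <- F2[!deg, , drop = FALSE]
    s1 <- pmin(F2[, 1], F2[, 2], F2[, 3])
    s3 <- pmax(F2[, 1], F2[, 2], F2[, 3])
    s2 <- F2[, 1] + F2[, 2] + F2[, 3] - s1 - s3
    F2 <- F2[!duplicated(cbind(s1, s2, s3)), , drop = FALSE]
    ref <- sort(unique(as.vector(F2)))
    remap <- integer(n)
    remap[ref] <- seq_along(ref)
    V <- V[ref, , drop = FALSE]
    Q <- Q[ref, , drop = FALSE]
    F <- matrix(remap[F2], ncol = 3)
  }
  trimesh(V, F)
}

# ---------------------------------------------------------------------------
# curvature, inflation, resampling

# outward area-weighted vertex normals
vertex_normals <- function(V, F) {
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  fn <- cross3(p2 - p1, p3 - p1)
  N <- matrix(0, nrow(V), 3)
  for (c4 in 1:3) {
    rs <- rowsum(fn, F[, c4])
    rows <- as.integer(rownames(rs))
    N[rows, ] <- N[rows, ] + rs
  }
  nn <- sqrt(rowSums(N^2))
  nn[nn == 0] <- 1
  N / nn
}

#' Smooth a per-vertex map by neighbor averaging
#'
#' @param mesh A `trimesh`.
#' @param values Numeric per-vertex vector.
#' @param rounds Number of averaging rounds (each replaces a value by the mean
#'   of its neighbors).
#' @return Smoothed values.
#' @export
smooth_vertex_map <- function(mesh, values, rounds) {
  A <- neighbor_average_matrix(mesh)
  v <- values
  for (r in seq_len(rounds)) v <- as.vector(A %*% v)
  v
}

#' Signed vertex curvature and its binarized map
#'
#' Smoothed mean curvature via the umbrella operator: the displacement of each
#' vertex from its neighbor average, projected on the outward normal. Sign
#' convention: sulci (concave) positive, gyri (convex) negative; the binarized
#' map thresholds at 0 into \{-1, +1\}.
#'
#' @param m A closed manifold `trimesh`.
#' @param smoothing_steps Rounds of neighbor averaging applied to the raw
#'   curvature (default 10).
#' @return A list with `curvature` (numeric) and `binary` (-1 gyrus /
#'   +1 sulcus).
#' @export
vertex_curvature <- function(m, smoothing_steps = 10) {
  stopifnot(inherits(m, "trimesh"))
  A <- neighbor_average_matrix(m)  # errors on isolated vertices
  N <- vertex_normals(m$vertices, m$faces)
  disp <- as.matrix(A %*% m$vertices) - m$vertices
  curv <- rowSums(disp * N)
  if (smoothing_steps > 0) curv <- smooth_vertex_map(m, curv, smoothing_steps)
  list(curvature = curv, binary = ifelse(curv >= 0, 1, -1))
}

#' Inflate a genus-0 mesh to the unit sphere
#'
#' Iterative Laplacian smoothing with per-step re-centering and projection to
#' the unit sphere. Vertex order (and hence any per-vertex map) is preserved;
#' the result is checked for flipped faces.
#'
#' @param m A `trimesh` with Euler characteristic 2.
#' @param n_steps Smoothing iterations (default 500).
#' @return A `spherical_mesh` whose vertices have unit norm; the source mesh
#'   is kept in the `source` field.
#' @export
inflate_to_sphere <- function(m, n_steps = 500) {
  stopifnot(inherits(m, "trimesh"))
  chi <- euler_characteristic(m)
  if (chi != 2L)
    stop(sprintf("mesh has Euler characteristic %d; inflation requires genus 0",
                 chi))
  A <- neighbor_average_matrix(m)
  V <- m$vertices
  for (s in seq_len(n_steps)) {
    V <- V + 0.5 * (as.matrix(A %*% V) - V)
    V <- sweep(V, 2, colMeans(V))
    V <- V / sqrt(rowSums(V^2))
  }
  out <- trimesh(V, m$faces)
  out$source <- m
  class(out) <- c("spherical_mesh", "trimesh")
  nflip <- sum(face_dets(V, m$faces) <= 0)
  attr(out, "flipped_faces") <- nflip
  if (nflip > 0)
    warning(sprintf("%d flipped face(s) after inflation", nflip))
  out
}

#' Interpolate per-vertex values of a spherical mesh at query directions
#'
#' Locates each unit query direction in the spherical triangulation (walking
#' point location with a brute-force fallback) and transports values by
#' barycentric interpolation (`kind = "scalar"`) or by the label of the
#' nearest triangle corner (`kind = "categorical"`).
#'
#' @param mesh A `spherical_mesh` (unit vertices).
#' @param values Per-vertex vector (numeric, or any type for categorical).
#' @param queries q x 3 matrix of unit directions.
#' @param kind `"scalar"` or `"categorical"`.
#' @return Interpolated values of length `nrow(queries)`.
#' @export
sphere_interp <- function(mesh, values, queries,
                          kind = c("scalar", "categorical")) {
  kind <- match.arg(kind)
  loc <- locate_on_sphere(mesh, queries)
  interp_from_loc(mesh, values, loc, kind)
}

locate_on_sphere <- function(mesh, queries) {
  queries <- as.matrix(queries)
  queries <- queries / sqrt(rowSums(queries^2))
  loc <- sphere_locate_cpp(mesh$vertices, mesh$faces - 1L, queries, integer(0))
  b <- loc$bary
  b[b < 1e-12] <- 0
  b <- b / rowSums(b)
  loc$bary <- b
  loc
}

interp_from_loc <- function(mesh, values, loc, kind) {
  Fm <- mesh$faces[loc$face, , drop = FALSE]
  if (kind == "scalar") {
    loc$bary[, 1] * values[Fm[, 1]] + loc$bary[, 2] * values[Fm[, 2]] +
      loc$bary[, 3] * values[Fm[, 3]]
  } else {
    corner <- max.col(loc$bary, ties.method = "first")
    values[Fm[cbind(seq_len(nrow(Fm)), corner)]]
  }
}

#' Resample a spherical mesh's maps onto the standard icosphere
#'
#' Transports per-vertex maps from an arbitrary spherical mesh to the
#' standard icosphere at the requested subdivision level (level 7 gives the
#' 163842-vertex high-density sphere). Scalar maps use barycentric
#' interpolation within the containing source triangle, categorical maps the
#' nearest source corner. Queries that hit no triangle numerically fall back
#' to the best-covering face; the count is reported in the result.
#'
#' @param s A `spherical_mesh`.
#' @param scalar_maps Named list of numeric per-vertex maps (may be empty).
#' @param label_maps Named list of categorical per-vertex maps (may be empty).
#' @param level Icosphere subdivision level (>= 0).
#' @return A list with `mesh` (the [icosphere()]), transported `scalar_maps`
#'   and `label_maps`, and the numeric `fallbacks` count.
#' @export
resample_to_standard <- function(s, scalar_maps = list(), label_maps = list(),
                                 level = 7) {
  stopifnot(inherits(s, "spherical_mesh") || inherits(s, "trimesh"))
  nrm <- sqrt(rowSums(s$vertices^2))
  if (max(abs(nrm - 1)) > 1e-6)
    stop("source mesh vertices are not on the unit sphere")
  target <- icosphere(level)
  loc <- locate_on_sphere(s, target$vertices)
  out_s <- lapply(scalar_maps, function(v) interp_from_loc(s, v, loc, "scalar"))
  out_l <- lapply(label_maps, function(v)
    interp_from_loc(s, v, loc, "categorical"))
  if (loc$fallbacks > 0)
    message(sprintf("resample_to_standard: %d point(s) used the nearest-face fallback",
                    loc$fallbacks))
  list(mesh = target, scalar_maps = out_s, label_maps = out_l,
       fallbacks = loc$fallbacks)
}

# ---------------------------------------------------------------------------
# plain-text IO

#' Read / write meshes as Wavefront OBJ
#' @param m A `trimesh`.
#' @param path File path.
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", m$vertices[, 1], m$vertices[, 2],
                     m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", m$faces[, 1], m$faces[, 2], m$faces[, 3]),
             con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  V <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  F <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  trimesh(V, F)
}

#' Write a per-vertex map as CSV (vertex_index, value); indices are 0-based
#' in the file, matching the package's file conventions.
#' @param values Per-vertex vector.
#' @param path File path.
#' @export
write_vertex_map_csv <- function(values, path) {
  write.csv(data.frame(vertex_index = seq_along(values) - 1L, value = values),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_map_csv
#' @export
read_vertex_map_csv <- function(path) {
  df <- utils::read.csv(path)
  df$value[order(df$vertex_index)]
}
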