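test_that("icosphere vertex counts follow 10 * 4^level + 2 and faces are outward", {
  for (lev in 0:4)
    expect_identical(nrow(icosphere(lev)$vertices),
                     as.integer(10 * 4^lev + 2))
  m <- icosphere(3)
  expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 1e-12)
  expect_true(all(cortexalign:::face_dets(m$vertices, m$faces) > 0))
  # lower-level vertices keep their indices (nesting used by the aligners)
  m2 <- icosphere(2)
  expect_equal(m$vertices[seq_len(nrow(m2$vertices)), ], m2$vertices)
})

test_that("euler characteristic: icosahedron 2, disjoint union additive, torus 0", {
  ico <- icosphere(0)
  expect_identical(euler_characteristic(ico), 2L)
  two <- trimesh(rbind(ico$vertices, ico$vertices + 5),
                 rbind(ico$faces, ico$faces + nrow(ico$vertices)))
  expect_identical(euler_characteristic(two), 4L)
  expect_identical(euler_characteristic(extract_mesh(torus_mask())), 0L)
})

test_that("mesh extraction: closed genus-0 surface from a ball, errors on bad masks", {
  m <- extract_mesh(ball_mask())
  expect_identical(euler_characteristic(m), 2L)
  ctr <- colMeans(m$vertices)
  rr <- sqrt(rowSums(sweep(m$vertices, 2, ctr)^2))
  expect_lt(max(abs(rr - 10)) / 10, 0.05)
  expect_error(extract_mesh(binary_mask(array(FALSE, c(5, 5, 5)))), "empty")
  two <- array(FALSE, c(9, 9, 9)); two[2:3, 2:3, 2:3] <- TRUE; two[7:8, 7:8, 7:8] <- TRUE
  expect_error(extract_mesh(binary_mask(two)), "2 connected components")
})

test_that("decimation hits the target, preserves topology and edge-length spread", {
  m <- extract_mesh(ball_mask(n = 40, r = 16))
  expect_identical(decimate(m, nrow(m$vertices) + 10), m)  # already small enough
  md <- decimate(m, 2000)
  expect_lte(abs(nrow(md$vertices) - 2000) / 2000, 0.02)
  expect_identical(euler_characteristic(md), 2L)
  edge_cv <- function(x) {
    e <- cortexalign:::mesh_edges(x$faces)
    l <- sqrt(rowSums((x$vertices[e[, 1], ] - x$vertices[e[, 2], ])^2))
    sd(l) / mean(l)
  }
  expect_lte(edge_cv(md), 1.2 * edge_cv(m))
  ctr <- colMeans(md$vertices)
  rr <- sqrt(rowSums(sweep(md$vertices, 2, ctr)^2))
  expect_lt(max(abs(rr - 16)) / 16, 0.02)
})

test_that("vertex curvature: constant sign on spheres, fold recovery, variance contraction", {
  sph <- icosphere(3)
  sph$vertices <- sph$vertices * 10
  cv <- vertex_curvature(sph, 0)
  expect_true(all(cv$binary == cv$binary[1]))  # constant sign everywhere
  # sinusoidally folded sphere: radial folds with known phase
  m <- icosphere(4)
  ll <- cortexalign:::vertex_latlon(m$vertices)
  phase <- sin(6 * cortexalign:::deg2rad(ll$lon)) * cos(cortexalign:::deg2rad(ll$lat))
  folded <- m
  folded$vertices <- m$vertices * (10 + 2 * phase)
  cv <- vertex_curvature(folded, 2)
  # curvature sign alternates with the fold phase: bulges (phase > 0) are
  # gyral (negative), indentations sulcal (positive); the sphere's global
  # convexity shifts the baseline, so compare against the median where the
  # phase is informative
  strong <- abs(phase) > 0.4
  centered <- cv$curvature - median(cv$curvature)
  agree <- mean(sign(-centered[strong]) == sign(phase[strong]))
  expect_gte(agree, 0.95)
  v0 <- vertex_curvature(folded, 0)$curvature
  v50 <- vertex_curvature(folded, 50)$curvature
  expect_lt(var(v50), var(v0))
})

test_that("inflation preserves combinatorics, lands on the unit sphere, no flips", {
  m <- decimate(extract_mesh(ball_mask()), 1500)
  s <- inflate_to_sphere(m, 300)
  expect_identical(dim(s$vertices), dim(m$vertices))
  expect_identical(s$faces, m$faces)
  expect_lt(max(abs(sqrt(rowSums(s$vertices^2)) - 1)), 1e-6)
  expect_identical(attr(s, "flipped_faces"), 0L)
  expect_error(inflate_to_sphere(extract_mesh(torus_mask()), 10),
               "Euler characteristic 0")
  # spherical input is (up to smoothing drift) unchanged after renormalization
  ic <- icosphere(2)
  s2 <- inflate_to_sphere(trimesh(ic$vertices * 3, ic$faces), 50)
  expect_lt(max(abs(sqrt(rowSums(s2$vertices^2)) - 1)), 1e-6)
})

test_that("resampling to the standard sphere transports constants and linear fields", {
  m <- decimate(extract_mesh(ball_mask()), 1500)
  s <- inflate_to_sphere(m, 300)
  const <- rep(3.5, nrow(s$vertices))
  lin <- 1.5 * s$vertices[, 1] - 0.5 * s$vertices[, 3]
  lab <- ifelse(s$vertices[, 3] > 0, "up", "down")
  out <- resample_to_standard(s, scalar_maps = list(c = const, l = lin),
                              label_maps = list(side = lab), level = 3)
  expect_identical(nrow(out$mesh$vertices), 642L)
  expect_equal(out$scalar_maps$c, rep(3.5, 642), tolerance = 1e-12)
  tgt <- out$mesh$vertices
  expect_lt(max(abs(out$scalar_maps$l - (1.5 * tgt[, 1] - 0.5 * tgt[, 3]))),
            2e-2)  # piecewise-linear transport of a smooth field
  # range stability (monotone barycentric transport)
  expect_gte(min(out$scalar_maps$l), min(lin) - 1e-9)
  expect_lte(max(out$scalar_maps$l), max(lin) + 1e-9)
  # categorical labels survive where unambiguous
  expect_gt(mean((out$label_maps$side == "up") == (tgt[, 3] > 0)), 0.97)
})

test_that("level-7 icosphere has exactly 163842 vertices", {
  m <- icosphere(7)
  expect_identical(nrow(m$vertices), 163842L)
  expect_identical(nrow(m$faces), 327680L)
})

test_that("OBJ and vertex-map CSV round-trips preserve geometry and values", {
  m <- icosphere(1)
  p <- tempfile(fileext = ".obj")
  write_obj(m, p)
  m2 <- read_obj(p)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-8)
  expect_identical(m2$faces, m$faces)
  unlink(p)
  vals <- rnorm(nrow(m$vertices))
  p2 <- tempfile(fileext = ".csv")
  write_vertex_map_csv(vals, p2)
  expect_equal(read_vertex_map_csv(p2), vals, tolerance = 1e-12)
  unlink(p2)
})
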