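test_that("landmark polylines follow shortest edge-paths and smooth to maps", {
  mesh <- icosphere(2)
  e <- cortexalign:::mesh_edges(mesh$faces)
  # two adjacent vertices -> the path is that single edge
  lm <- landmark_to_map(mesh, anchors = c(e[1, 1], e[1, 2]), name = "aHG")
  expect_identical(sort(lm$polyline$path), sort(c(e[1, 1], e[1, 2])))
  expect_identical(max(lm$map), 1)
  expect_identical(sum(lm$map), 2)
  # near-antipodal anchors on a level-4 icosphere: path length close to pi
  m4 <- icosphere(4)
  a <- 1L
  b <- which.min(m4$vertices %*% m4$vertices[a, ])
  lm2 <- landmark_to_map(m4, c(a, b))
  p <- lm2$polyline$path
  seg <- acos(pmin(1, rowSums(m4$vertices[p[-length(p)], ] *
                                m4$vertices[p[-1], ])))
  # exhaustive shortest-path oracle: the path length must equal the graph
  # distance, which exceeds the great-circle distance pi only by the
  # triangulation's metric stretch (about 6% on an icosphere)
  edges4 <- cortexalign:::mesh_edges(m4$faces)
  w4 <- acos(pmin(1, pmax(-1, rowSums(m4$vertices[edges4[, 1], ] *
                                        m4$vertices[edges4[, 2], ]))))
  g4 <- igraph::graph_from_edgelist(edges4, directed = FALSE)
  oracle <- as.numeric(igraph::distances(g4, a, b, weights = w4))
  expect_equal(sum(seg), oracle, tolerance = 1e-10)
  expect_lt(abs(sum(seg) - pi) / pi, 0.08)
  expect_error(landmark_to_map(mesh, c(5, 5, 5)), "distinct")
  expect_error(landmark_to_map(mesh, c(1, nrow(mesh$vertices) + 10)),
               "not vertices")
})

test_that("rigid alignment recovers a planted 20-degree rotation within 2 degrees", {
  mesh <- icosphere(4)
  curv <- smooth_random_map(mesh, 40, seed = 3)
  expect_lt(rotation_angle_deg(rigid_spherical_align(curv, curv, mesh)), 0.1)
  set.seed(13)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  Rtrue <- cortexalign:::rotvec_to_matrix(ax * 20 * pi / 180)
  tgt <- sphere_interp(mesh, curv, mesh$vertices %*% Rtrue)
  Rest <- rigid_spherical_align(curv, tgt, mesh)
  expect_lt(rotation_angle_deg(Rest, Rtrue), 2)
  expect_lte(attr(Rest, "residual"), attr(Rest, "residual_identity"))
  expect_warning(Rc <- rigid_spherical_align(rep(1, nrow(mesh$vertices)),
                                             curv, mesh), "no-signal")
  expect_equal(unclass(Rc), diag(3), ignore_attr = TRUE)
})

test_that("alignment schedule validates decreasing smoothing", {
  expect_error(alignment_schedule(curv_smooth = c(10, 10, 5, 2)),
               "strictly decreasing")
  expect_s3_class(alignment_schedule(), "alignment_schedule")
})

test_that("cba: identical subjects stay at identity; single subject errors", {
  mesh <- icosphere(2)
  curv <- smooth_random_map(mesh, 15, seed = 5)
  sch <- alignment_schedule(iters = c(20, 20, 10, 10))
  res <- cba(list(curv, curv, curv), mesh, sch)
  for (w in res$warps)
    expect_lt(max(acos(pmin(1, rowSums(w * mesh$vertices)))), 1e-6)
  expect_error(cba(list(curv), mesh, sch), "at least 2")
  cl <- curv; attr(cl, "hemisphere") <- "left"
  cr <- curv; attr(cr, "hemisphere") <- "right"
  expect_error(cba(list(cl, cr), mesh, sch), "mix hemispheres")
})

test_that("within-level cost traces are non-increasing and warps stay valid", {
  co <- .test_cohort()
  curvs <- lapply(co$subjects, `[[`, "curvature")
  sch <- alignment_schedule(iters = c(30, 30, 20, 15))
  res <- cba(curvs, co$mesh, sch)
  for (lev in seq_along(res$cost_traces))
    for (tr in res$cost_traces[[lev]])
      expect_true(all(diff(tr) <= 1e-12))
  for (w in res$warps) {
    expect_lt(max(abs(sqrt(rowSums(w^2)) - 1)), 1e-6)
    expect_true(all(cortexalign:::face_dets(w, co$mesh$faces) > 0))  # no flips
  }
})

test_that("cba_plus with zero landmark weight reproduces cba exactly", {
  co <- .test_cohort()
  curvs <- lapply(co$subjects, `[[`, "curvature")[1:3]
  lms <- lapply(co$subjects, `[[`, "landmark_maps")[1:3]
  sch <- alignment_schedule(iters = c(15, 15, 10, 10), lm_weight = 0)
  a <- cba(curvs, co$mesh, sch)
  b <- cba_plus(curvs, lms, co$mesh, sch)
  for (s in 1:3) expect_identical(a$warps[[s]], b$warps[[s]])
  # missing landmark errors name the subject and landmark
  lms2 <- lms
  lms2[[2]] <- lms2[[2]][c("aHG", "STG", "STS")]
  sch1 <- alignment_schedule(iters = c(15, 15, 10, 10), lm_weight = 1)
  expect_error(cba_plus(curvs, lms2, co$mesh, sch1), "subject 2.*MTG")
})

test_that("coincident landmark maps leave cba_plus close to cba", {
  co <- .test_cohort()
  curvs <- lapply(co$subjects, `[[`, "curvature")[1:3]
  shared <- co$template$landmark_maps  # identical for every subject
  lms <- list(shared, shared, shared)
  sch <- alignment_schedule(iters = c(15, 15, 10, 10))
  a <- cba(curvs, co$mesh, sch)
  b <- cba_plus(curvs, lms, co$mesh, sch)
  e <- cortexalign:::mesh_edges(co$mesh$faces)
  mean_edge <- mean(sqrt(rowSums((co$mesh$vertices[e[, 1], ] -
                                    co$mesh$vertices[e[, 2], ])^2)))
  # the shared-landmark term is only approximately constant along the
  # optimization path, so warps agree to within about one edge length
  for (s in 1:3) {
    gap <- max(sqrt(rowSums((a$warps[[s]] - b$warps[[s]])^2)))
    expect_lt(gap, mean_edge)
  }
})

test_that("apply_warp: identity transport, constants, planted rotation oracle", {
  mesh <- icosphere(4)
  curv <- smooth_random_map(mesh, 15, seed = 2)
  expect_equal(apply_warp(curv, mesh$vertices, mesh), curv, tolerance = 1e-9)
  anyw <- mesh$vertices %*% cortexalign:::rotvec_to_matrix(c(0.2, -0.1, 0.4))
  expect_equal(apply_warp(rep(2, length(curv)), anyw, mesh),
               rep(2, length(curv)), tolerance = 1e-12)
  fine <- icosphere(5)   # fine source sphere: piecewise-linear error ~1e-4
  lin <- fine$vertices %*% c(0.3, -1, 0.5)
  R <- cortexalign:::rotvec_to_matrix(c(0, 0, 0.3))
  got <- apply_warp(as.vector(lin), fine$vertices %*% R, fine)
  want <- (fine$vertices %*% R) %*% c(0.3, -1, 0.5)
  expect_lt(max(abs(got - want)), 1e-3)
  lab <- ifelse(mesh$vertices[, 3] > 0, "a", "b")
  expect_identical(apply_warp(lab, mesh$vertices, mesh, "categorical"), lab)
  expect_error(apply_warp(curv, mesh$vertices * 2, mesh), "unit")
})

test_that("group_average: single subject identity, opposite maps cancel", {
  mesh <- icosphere(2)
  curv <- smooth_random_map(mesh, 10, seed = 9)
  one <- group_average(list(curv), list(mesh$vertices), mesh)
  expect_equal(one$mean, curv, tolerance = 1e-9)
  two <- group_average(list(rep(1, length(curv)), rep(-1, length(curv))),
                       list(mesh$vertices, mesh$vertices), mesh)
  expect_equal(two$mean, rep(0, length(curv)), tolerance = 1e-12)
  expect_error(group_average(list(curv), list(mesh$vertices, mesh$vertices),
                             mesh), "mismatch")
})

test_that("warp CSV round-trips", {
  mesh <- icosphere(1)
  w <- mesh$vertices
  p <- tempfile(fileext = ".csv")
  write_warp_csv(w, p)
  expect_equal(read_warp_csv(p), w, tolerance = 1e-12, ignore_attr = TRUE)
  unlink(p)
})
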