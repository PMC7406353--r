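#' Landmark polyline and smooth landmark map
#'
#' Connects ordered anchor vertices by shortest edge-paths on the spherical
#' mesh (edge weights are great-circle arc lengths), giving a geodesic-like
#' polyline, and builds the corresponding indicator map (1 on path vertices,
#' 0 elsewhere), optionally smoothed by neighbor averaging.
#'
#' @param mesh A `spherical_mesh` / [icosphere()].
#' @param anchors Ordered vector of (1-based) anchor vertex indices, at least
#'   2 distinct vertices.
#' @param name Landmark name (e.g. "aHG", "STG", "STS", "MTG").
#' @param smoothing_steps Averaging rounds applied to the indicator
#'   (default 0: raw indicator, maximum exactly 1).
#' @return A list with `polyline` (name, anchors, path vertices) and `map`
#'   (per-vertex non-negative scalar).
#' @export
landmark_to_map <- function(mesh, anchors, name = "landmark",
                            smoothing_steps = 0) {
  n <- nrow(mesh$vertices)
  anchors <- as.integer(anchors)
  if (any(anchors < 1L | anchors > n))
    stop("anchors are not vertices of the mesh")
  if (length(unique(anchors)) < 2L)
    stop("need at least 2 distinct anchor vertices")
  e <- mesh_edges(mesh$faces)
  w <- acos(pmin(1, pmax(-1, rowSums(mesh$vertices[e[, 1], , drop = FALSE] *
                                       mesh$vertices[e[, 2], , drop = FALSE]))))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  path <- integer(0)
  for (s in seq_len(length(anchors) - 1L)) {
    sp <- igraph::shortest_paths(g, from = anchors[s], to = anchors[s + 1L],
                                 weights = w)$vpath[[1]]
    sp <- as.integer(sp)
    if (length(path)) sp <- sp[-1]
    path <- c(path, sp)
  }
  map <- numeric(n)
  map[path] <- 1
  if (smoothing_steps > 0) map <- smooth_vertex_map(mesh, map, smoothing_steps)
  list(polyline = list(name = name, anchors = anchors, path = path),
       map = map)
}

#' @rdname landmark_to_map
#' @param polyline A polyline list as returned in the `polyline` field.
#' @param path JSON file path.
#' @export
write_landmark_json <- function(polyline, path) {
  jsonlite::write_json(list(name = polyline$name,
                            anchor_vertices = polyline$anchors - 1L,
                            path_vertices = polyline$path - 1L),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rodrigues: axis-angle 3-vector -> rotation matrix
rotvec_to_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Geodesic angle (degrees) between two rotations
#' @param R1,R2 3x3 rotation matrices.
#' @export
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  R <- R1 %*% t(R2)
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Spherical rigid-body alignment of curvature maps
#'
#' Finds the rotation minimizing the mean squared difference between the
#' rotated-resampled source curvature and the target curvature, by a coarse
#' grid search over SO(3) (icosphere axes x angle steps) followed by
#' Nelder-Mead refinement of the axis-angle vector. The returned rotation's
#' residual never exceeds the residual at identity; constant (no-signal) maps
#' return identity with a warning.
#'
#' @param src_curv,tgt_curv Per-vertex curvature maps on `mesh`.
#' @param mesh The standard [icosphere()] both maps live on.
#' @param angle_step Coarse search angle step in degrees.
#' @param eval_level Icosphere level whose vertices serve as evaluation
#'   directions during the coarse search.
#' @param search_level When `mesh` is an icosphere finer than this level, the
#'   search runs on the nested sub-icosphere at this level (lower-level
#'   vertices keep their indices, so the truncated map is a valid map on the
#'   sub-sphere); the rigid stage needs only coarse curvature structure.
#' @return A 3x3 rotation matrix with attributes `residual` and
#'   `residual_identity`. The rotated source map is
#'   `sphere_interp(mesh, src_curv, mesh$vertices %*% R)`.
#' @export
rigid_spherical_align <- function(src_curv, tgt_curv, mesh, angle_step = 15,
                                  eval_level = 2, search_level = 4) {
  stopifnot(length(src_curv) == nrow(mesh$vertices),
            length(tgt_curv) == nrow(mesh$vertices))
  if (!is.null(mesh$level) && mesh$level > search_level) {
    sub <- icosphere(search_level)
    nsub <- nrow(sub$vertices)
    return(rigid_spherical_align(src_curv[seq_len(nsub)],
                                 tgt_curv[seq_len(nsub)], sub,
                                 angle_step, eval_level, search_level))
  }
  if (sd(src_curv) < 1e-12 || sd(tgt_curv) < 1e-12) {
    warning("no-signal (constant) curvature map; returning identity")
    R <- diag(3)
    attr(R, "residual") <- mean((src_curv - tgt_curv)^2)
    attr(R, "residual_identity") <- attr(R, "residual")
    return(R)
  }
  dirs <- icosphere(eval_level)$vertices
  tgt_at <- sphere_interp(mesh, tgt_curv, dirs)
  cost_R <- function(R) {
    src_at <- sphere_interp(mesh, src_curv, dirs %*% R)
    mean((src_at - tgt_at)^2)
  }
  # coarse: axes from a low-level icosphere (upper hemisphere), all angles;
  # all rotated query sets are stacked into one batched interpolation
  axes <- icosphere(1)$vertices
  axes <- axes[axes[, 3] > -1e-9, , drop = FALSE]
  angles <- seq(-180 + angle_step, 180, by = angle_step) * pi / 180
  rots <- c(list(c(0, 0, 0)),
            unlist(lapply(seq_len(nrow(axes)), function(a)
              lapply(angles, function(th) axes[a, ] * th)), recursive = FALSE))
  Q <- do.call(rbind, lapply(rots, function(r) dirs %*% rotvec_to_matrix(r)))
  vals <- sphere_interp(mesh, src_curv, Q)
  costs <- colMeans((matrix(vals, nrow = nrow(dirs)) - tgt_at)^2)
  bi <- which.min(costs)
  best <- list(r = rots[[bi]], cost = costs[bi])
  # refine on a denser evaluation set
  dirs <- icosphere(eval_level + 1)$vertices
  tgt_at <- sphere_interp(mesh, tgt_curv, dirs)
  opt <- optim(best$r, function(r) cost_R(rotvec_to_matrix(r)),
               method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-10))
  id_cost <- cost_R(diag(3))
  if (opt$value <= id_cost) {
    R <- rotvec_to_matrix(opt$par)
    res <- opt$value
  } else {
    R <- diag(3)
    res <- id_cost
  }
  attr(R, "residual") <- res
  attr(R, "residual_identity") <- id_cost
  R
}

#' Coarse-to-fine alignment schedule
#'
#' Four spatial scales from very smooth to slightly smooth maps. Smoothing
#' strengths must be strictly decreasing across levels.
#'
#' @param curv_smooth Curvature smoothing rounds per level.
#' @param lm_smooth Landmark-map smoothing rounds per level.
#' @param iters Gradient iterations per level.
#' @param step Initial step size per level (units of mean edge length).
#' @param lambda_reg Metric-distortion regularization weight.
#' @param lm_weight Landmark term weight (used by [cba_plus()]).
#' @return An `alignment_schedule`.
#' @export
alignment_schedule <- function(curv_smooth = c(120, 60, 20, 5),
                               lm_smooth = c(60, 30, 10, 3),
                               iters = c(100, 100, 80, 60),
                               step = c(0.3, 0.15, 0.075, 0.0375),
                               lambda_reg = 30,
                               lm_weight = 0.25) {
  nlev <- length(curv_smooth)
  stopifnot(length(lm_smooth) == nlev, length(iters) == nlev,
            length(step) == nlev, lambda_reg >= 0, lm_weight >= 0)
  if (any(diff(curv_smooth) >= 0) || any(diff(lm_smooth) >= 0))
    stop("smoothing strengths must be strictly decreasing across levels")
  structure(list(curv_smooth = curv_smooth, lm_smooth = lm_smooth,
                 iters = as.integer(iters), step = step,
                 lambda_reg = lambda_reg, lm_weight = lm_weight,
                 n_levels = nlev),
            class = "alignment_schedule")
}

# shared engine behind cba() and cba_plus()
align_nonlinear <- function(curvs, landmark_maps, mesh, schedule, init_warps,
                            lm_weight, verbose = FALSE) {
  n_sub <- length(curvs)
  if (n_sub < 2L) stop("need at least 2 subjects")
  nv <- nrow(mesh$vertices)
  for (s in seq_len(n_sub))
    if (length(curvs[[s]]) != nv)
      stop(sprintf("subject %d curvature has wrong length", s))
  # hemispheres are aligned separately, never mixed in one run
  hemis <- unique(unlist(lapply(curvs, attr, "hemisphere")))
  if (length(hemis) > 1L)
    stop(sprintf("refusing to mix hemispheres in one alignment run: %s",
                 paste(hemis, collapse = ", ")))
  use_lm <- lm_weight > 0 && !is.null(landmark_maps)
  lm_names <- if (use_lm) names(landmark_maps[[1]]) else character(0)
  if (use_lm) {
    for (s in seq_len(n_sub)) {
      missing_lm <- setdiff(lm_names, names(landmark_maps[[s]]))
      if (length(missing_lm))
        stop(sprintf("subject %d is missing landmark(s): %s", s,
                     paste(missing_lm, collapse = ", ")))
    }
  }
  if (is.null(init_warps))
    init_warps <- replicate(n_sub, mesh$vertices, simplify = FALSE)
  E <- mesh_edges(mesh$faces)
  rest <- sqrt(rowSums((mesh$vertices[E[, 1], ] - mesh$vertices[E[, 2], ])^2))
  A <- neighbor_average_matrix(mesh)
  smooth_rounds <- function(v, rounds) {
    for (r in seq_len(rounds)) v <- as.vector(A %*% v)
    v
  }
  warps <- init_warps
  traces <- vector("list", schedule$n_levels)
  for (lev in seq_len(schedule$n_levels)) {
    subj_maps <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      cs <- smooth_rounds(curvs[[s]], schedule$curv_smooth[lev])
      cs <- (cs - mean(cs)) / max(sd(cs), 1e-12)
      cols <- list(cs)
      if (use_lm) {
        for (nm in lm_names) {
          ls <- smooth_rounds(landmark_maps[[s]][[nm]],
                              schedule$lm_smooth[lev])
          cols[[length(cols) + 1L]] <- ls / max(sd(ls), 1e-12)
        }
      }
      subj_maps[[s]] <- do.call(cbind, cols)
    }
    K <- ncol(subj_maps[[1]])
    wk <- c(1, rep(lm_weight, K - 1L))
    # dynamic group averaging: template from current warps, refreshed per level
    templ <- matrix(0, nv, K)
    for (s in seq_len(n_sub)) {
      loc <- locate_on_sphere(mesh, warps[[s]])
      for (k in seq_len(K))
        templ[, k] <- templ[, k] +
          interp_from_loc(mesh, subj_maps[[s]][, k], loc, "scalar")
    }
    templ <- templ / n_sub
    lev_trace <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      res <- warp_level_cpp(mesh$vertices, mesh$faces - 1L, subj_maps[[s]],
                            templ, wk, warps[[s]], E - 1L, rest,
                            schedule$lambda_reg, schedule$step[lev],
                            schedule$iters[lev])
      if (res$flips > 0)
        warning(sprintf("subject %d, level %d: %d flipped triangle(s)",
                        s, lev, res$flips))
      warps[[s]] <- res$warp
      lev_trace[[s]] <- res$cost_trace
      if (verbose)
        message(sprintf("level %d subject %d: cost %.5g -> %.5g (%d steps)",
                        lev, s, res$cost_trace[1],
                        tail(res$cost_trace, 1), res$accepted))
    }
    traces[[lev]] <- lev_trace
  }
  template <- group_average(curvs, warps, mesh)
  structure(list(warps = warps, template = template, cost_traces = traces,
                 schedule = schedule, landmark_names = lm_names),
            class = "cba_result")
}

#' Curvature-based alignment (CBA)
#'
#' Nonlinear registration of spherical curvature maps across subjects by
#' coarse-to-fine gradient descent on a curvature-matching cost with a
#' metric-distortion penalty, using dynamic group averaging (the template is
#' recomputed from the currently warped subjects at each scale). Subjects are
#' expected to be rigidly pre-aligned (pass the rigid warps as `init_warps`).
#'
#' @param curvs List (length >= 2) of per-vertex curvature maps.
#' @param mesh The standard [icosphere()].
#' @param schedule An [alignment_schedule()].
#' @param init_warps Optional list of n x 3 initial warp positions (e.g. from
#'   the rigid stage); identity when `NULL`.
#' @param verbose Report per-level costs.
#' @return A `cba_result` with `warps` (per subject, per-vertex unit target
#'   positions), the final group `template`, and per-level cost traces.
#' @export
cba <- function(curvs, mesh, schedule = alignment_schedule(),
                init_warps = NULL, verbose = FALSE) {
  align_nonlinear(curvs, landmark_maps = NULL, mesh = mesh,
                  schedule = schedule, init_warps = init_warps,
                  lm_weight = 0, verbose = verbose)
}

#' Landmark-augmented curvature-based alignment (CBA+)
#'
#' [cba()] with anatomical priors: smoothed indicator maps of explicit
#' landmarks (anterior Heschl's gyrus, superior temporal gyrus and sulcus,
#' middle temporal gyrus) are added to the matching cost with weight
#' `schedule$lm_weight`, each variance-normalized per scale alongside the
#' curvature term. With `lm_weight = 0` the landmark maps are ignored and the
#' result is identical to [cba()].
#'
#' @inheritParams cba
#' @param landmark_maps List (one element per subject) of named lists of
#'   per-vertex landmark indicator maps; every subject must provide all
#'   landmarks.
#' @return A `cba_result`.
#' @export
cba_plus <- function(curvs, landmark_maps, mesh,
                     schedule = alignment_schedule(), init_warps = NULL,
                     verbose = FALSE) {
  if (!is.null(landmark_maps) && length(landmark_maps) != length(curvs))
    stop("need one set of landmark maps per subject")
  align_nonlinear(curvs, landmark_maps = landmark_maps, mesh = mesh,
                  schedule = schedule, init_warps = init_warps,
                  lm_weight = schedule$lm_weight, verbose = verbose)
}

#' Transport a per-vertex map through a spherical warp
#'
#' Reads the subject's map at each warped position: scalar maps by
#' barycentric interpolation, categorical maps by the nearest-corner label.
#' The identity warp is the identity transport.
#'
#' @param map Per-vertex values on `mesh`.
#' @param warp n x 3 matrix of unit target positions (a `cba_result` warp or
#'   rigidly rotated vertices).
#' @param mesh The standard [icosphere()].
#' @param kind `"scalar"` or `"categorical"`.
#' @return The transported per-vertex map.
#' @export
apply_warp <- function(map, warp, mesh, kind = c("scalar", "categorical")) {
  kind <- match.arg(kind)
  warp <- as.matrix(warp)
  if (nrow(warp) != nrow(mesh$vertices))
    stop("warp and mesh sizes are incompatible")
  nn <- sqrt(rowSums(warp^2))
  if (max(abs(nn - 1)) > 1e-6)
    stop("warp positions are not unit vectors")
  sphere_interp(mesh, map, warp, kind)
}

#' Group average of warped maps or folded coordinates
#'
#' Per-vertex arithmetic mean of the subjects' maps (or of their original 3D
#' folded coordinates) transported through the warps, yielding the group
#' template curvature map or average folded mesh.
#'
#' @param maps_or_coords List of per-vertex vectors, or of n x 3 coordinate
#'   matrices.
#' @param warps List of warps (same length).
#' @param mesh The standard [icosphere()].
#' @return A list with `mean` (vector or matrix) and `n_subjects`.
#' @export
group_average <- function(maps_or_coords, warps, mesh) {
  if (length(maps_or_coords) != length(warps))
    stop("subject-count mismatch between maps and warps")
  n_sub <- length(warps)
  acc <- NULL
  for (s in seq_len(n_sub)) {
    x <- maps_or_coords[[s]]
    loc <- locate_on_sphere(mesh, warps[[s]])
    v <- if (is.matrix(x)) {
      sapply(seq_len(ncol(x)), function(j)
        interp_from_loc(mesh, x[, j], loc, "scalar"))
    } else {
      interp_from_loc(mesh, x, loc, "scalar")
    }
    acc <- if (is.null(acc)) v else acc + v
  }
  list(mean = acc / n_sub, n_subjects = n_sub)
}

#' Serialize warps as CSV (per-vertex unit target positions)
#' @param warp n x 3 warp matrix.
#' @param path File path.
#' @export
write_warp_csv <- function(warp, path) {
  write.csv(data.frame(vertex_index = seq_len(nrow(warp)) - 1L,
                       x = warp[, 1], y = warp[, 2], z = warp[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_warp_csv
#' @export
read_warp_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$vertex_index), ]
  as.matrix(df[, c("x", "y", "z")])
}
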