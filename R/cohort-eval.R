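#' Align a synthetic cohort with rigid, CBA and CBA+ pipelines
#'
#' Runs the three-stage comparison on a [make_cohort()] cohort: (1) spherical
#' rigid alignment (subjects aligned to a first-pass reference, then to the
#' rigid group mean), (2) curvature-based alignment initialized at the rigid
#' warps, (3) landmark-augmented alignment from the same initialization.
#' Hemispheres are never mixed: a cohort represents one hemisphere.
#'
#' @param cohort A `synthetic_cohort`.
#' @param schedule An [alignment_schedule()].
#' @param methods Subset of `c("rigid", "cba", "cba_plus")`.
#' @param verbose Report progress.
#' @return A list of per-method warp lists (`rigid`, `cba`, `cba_plus`), plus
#'   `rotations` (estimated rigid rotations).
#' @export
align_cohort <- function(cohort, schedule = alignment_schedule(),
                         methods = c("rigid", "cba", "cba_plus"),
                         verbose = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mesh <- cohort$mesh
  curvs <- lapply(cohort$subjects, `[[`, "curvature")
  n <- length(curvs)
  # pass 1: align everyone to subject 1; pass 2: to the rigid group mean
  rots <- vector("list", n)
  rots[[1]] <- diag(3)
  for (s in 2:n)
    rots[[s]] <- rigid_spherical_align(curvs[[s]], curvs[[1]], mesh)
  aligned <- lapply(seq_len(n), function(s)
    apply_warp(curvs[[s]], mesh$vertices %*% rots[[s]], mesh))
  ref <- Reduce(`+`, aligned) / n
  for (s in seq_len(n))
    rots[[s]] <- rigid_spherical_align(curvs[[s]], ref, mesh)
  rigid_warps <- lapply(rots, function(R) mesh$vertices %*% R)
  out <- list(rigid = rigid_warps, rotations = rots)
  if ("cba" %in% methods) {
    res <- cba(curvs, mesh, schedule, init_warps = rigid_warps,
               verbose = verbose)
    out$cba <- res$warps
    out$cba_result <- res
  }
  if ("cba_plus" %in% methods) {
    lms <- lapply(cohort$subjects, `[[`, "landmark_maps")
    res <- cba_plus(curvs, lms, mesh, schedule, init_warps = rigid_warps,
                    verbose = verbose)
    out$cba_plus <- res$warps
    out$cba_plus_result <- res
  }
  out
}

#' Mean pairwise correlation of warped curvature maps
#'
#' Transports each subject's curvature through its warp and averages the
#' Pearson correlation over all subject pairs; higher means better
#' macro-anatomical correspondence.
#'
#' @param curvs List of per-vertex curvature maps.
#' @param warps List of warps (same length).
#' @param mesh Standard [icosphere()].
#' @return Mean pairwise correlation.
#' @export
pairwise_curvature_correlation <- function(curvs, warps, mesh) {
  mapped <- lapply(seq_along(curvs), function(s)
    apply_warp(curvs[[s]], warps[[s]], mesh))
  n <- length(mapped)
  cc <- c()
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    cc <- c(cc, cor(mapped[[a]], mapped[[b]]))
  mean(cc)
}

#' Mean pairwise DICE of warped landmark supports
#'
#' Transports each subject's landmark band indicators through its warp
#' (categorical transport) and averages the pairwise DICE over subjects and
#' landmarks.
#'
#' @param cohort A `synthetic_cohort`.
#' @param warps List of warps.
#' @return Mean pairwise landmark-support DICE.
#' @export
landmark_overlap_dice <- function(cohort, warps) {
  mesh <- cohort$mesh
  nms <- names(cohort$subjects[[1]]$landmark_maps)
  n <- length(warps)
  vals <- c()
  for (nm in nms) {
    mapped <- lapply(seq_len(n), function(s)
      apply_warp(cohort$subjects[[s]]$landmark_maps[[nm]], warps[[s]], mesh,
                 kind = "categorical") == 1)
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      vals <- c(vals, dice(mapped[[a]], mapped[[b]]))
  }
  mean(vals)
}

#' Leave-one-out DICE of warped area labels
#'
#' Transports each subject's area labels through its warp and evaluates the
#' leave-one-subject-out DICE table ([loo_dice()]).
#'
#' @param cohort A `synthetic_cohort`.
#' @param warps List of warps.
#' @param min_overlap Training-atlas threshold (default 4).
#' @return A `dice_table`.
#' @export
cohort_loo_dice <- function(cohort, warps, min_overlap = 4) {
  mesh <- cohort$mesh
  labels <- lapply(seq_along(warps), function(s)
    apply_warp(cohort$subjects[[s]]$labels, warps[[s]], mesh,
               kind = "categorical"))
  loo_dice(labels, min_overlap = min_overlap)
}
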