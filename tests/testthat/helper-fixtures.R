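# programmatic fixtures shared across test files

# voxelized ball mask of radius r in an n^3 grid
ball_mask <- function(n = 28, r = 10) {
  ctr <- rep((n + 1) / 2, 3)
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  d <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  binary_mask(array(d < r, c(n, n, n)))
}

# voxelized solid torus (major radius R0, minor r0)
torus_mask <- function(n = 28, R0 = 9, r0 = 4) {
  ctr <- rep((n + 1) / 2, 3)
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  rho <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
  binary_mask(array((rho - R0)^2 + (g$z - ctr[3])^2 < r0^2, c(n, n, n)))
}

# random symmetric PSD 3x3 tensors as an n x 6 component matrix
random_psd_tensors <- function(n, seed = 1) {
  set.seed(seed)
  t(sapply(seq_len(n), function(i) {
    A <- matrix(rnorm(9), 3)
    S <- A %*% t(A)
    c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
  }))
}

# smooth random curvature map on a mesh
smooth_random_map <- function(mesh, rounds = 40, seed = 1) {
  set.seed(seed)
  v <- smooth_vertex_map(mesh, rnorm(nrow(mesh$vertices)), rounds)
  (v - mean(v)) / sd(v)
}

# small cohort reused by alignment tests (cached per session)
.test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_cohort(cohort_spec(n_subjects = 5, level = 3, seed = 7))
    cache
  }
})
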