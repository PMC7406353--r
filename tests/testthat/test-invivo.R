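test_that("myelin index: bounds, constant rule, min-max formula, outlier removal", {
  d <- c(8, 8, 8)
  msk <- binary_mask(array(TRUE, d))
  t2 <- scalar_volume(array(1, d))
  # constant ratio -> all zeros with a warning
  t1 <- scalar_volume(array(2, d))
  expect_warning(m <- myelin_index(t1, t2, msk), "constant")
  expect_true(all(m$data[!is.na(m$data)] == 0))
  # values {1,2,3,4} with no outliers -> {0, 33.33, 66.67, 100}
  vals <- array(rep(1:4, length.out = prod(d)), d)
  m2 <- myelin_index(scalar_volume(vals), t2, msk)
  got <- sort(unique(round(m2$data[!is.na(m2$data)], 2)))
  expect_equal(got, c(0, 33.33, 66.67, 100))
  # planted vessel-like outliers are excluded, rank order preserved
  set.seed(6)
  base <- array(rnorm(prod(d), 10, 1), d)
  out_idx <- sample(prod(d), round(0.01 * prod(d)))
  ratio <- base
  ratio[out_idx] <- ratio[out_idx] * 10
  m3 <- myelin_index(scalar_volume(ratio), t2, msk)
  expect_true(all(is.na(m3$data[out_idx])))
  surv <- which(!is.na(m3$data))
  expect_identical(order(m3$data[surv]), order(ratio[surv]))
  expect_true(min(m3$data, na.rm = TRUE) >= 0 &&
                max(m3$data, na.rm = TRUE) <= 100)
  expect_gte(attr(m3, "n_excluded_outlier"), length(out_idx))
})

test_that("cochlear features: tone selectivity, silence, white-noise flatness", {
  fs <- 16000
  t <- seq(0, 1, length.out = fs)
  feats0 <- cochlear_features(list(sin(2 * pi * 1000 * t)), fs)
  centers <- attr(feats0, "centers")
  for (k in c(10, 64, 120)) {
    tone <- sin(2 * pi * centers[k] * t)
    f <- cochlear_features(list(tone), fs)
    expect_identical(which.max(f[1, ]), as.integer(k))
  }
  expect_true(all(cochlear_features(list(numeric(fs)), fs) == 0))
  # Monte-Carlo flatness: narrow low bands need several long realizations
  # before their per-Hz energies stabilize
  set.seed(12)
  noises <- lapply(1:6, function(i) rnorm(fs * 16))
  fn <- cochlear_features(noises, fs, normalize = "bandwidth")
  rel <- colMeans(fn) / mean(colMeans(fn))
  expect_true(all(rel > 0.8 & rel < 1.2))
  expect_error(cochlear_features(list(noise), fs, fmin = 0), "Nyquist")
  expect_error(cochlear_features(list(noise), fs, fmax = 9000), "Nyquist")
})

test_that("HRF deconvolution is exact on noiseless data", {
  set.seed(3)
  kernel <- cortexalign:::hrf_kernel()
  onsets <- c(5, 30, 52, 80, 110, 140)
  nt <- 170
  amp <- c(1, 0.5, 2, 1.5, 0.8, 1.2)
  ts <- matrix(0, nt, 2)
  for (i in seq_along(onsets)) {
    idx <- onsets[i] + 0:8
    ts[idx, 1] <- ts[idx, 1] + kernel          # unit events
    ts[idx, 2] <- ts[idx, 2] + kernel          # same kernel, second vertex
  }
  h <- estimate_hrf(ts, onsets)
  expect_lt(max(abs(h[, 1] - kernel)), 1e-8)
  expect_lt(max(abs(estimate_hrf(matrix(0, nt, 1), onsets))), 1e-12)
  # overlapping events, noiseless
  on2 <- c(5, 9, 14, 30, 33, 60, 64, 90, 120, 123)
  ts2 <- matrix(0, 170, 1)
  for (o in on2) ts2[o + 0:8, 1] <- ts2[o + 0:8, 1] + kernel
  h2 <- estimate_hrf(ts2, on2)
  expect_lt(max(abs(h2[, 1] - kernel)), 1e-6)
  expect_error(estimate_hrf(ts, onsets, noise_regs = matrix(1, nt, 1)),
               "rank deficient")
})

test_that("sound responses recover betas and ignore orthogonal noise regressors", {
  set.seed(8)
  kernel <- cortexalign:::hrf_kernel()
  n_sounds <- 6
  onsets <- seq(4, by = 14, length.out = 12)
  sound_ids <- rep(1:n_sounds, 2)
  betas_true <- matrix(runif(n_sounds * 3, 0.5, 2), n_sounds, 3)
  nt <- max(onsets) + 12
  hrf <- matrix(kernel, 9, 3)
  ts <- cortexalign:::predict_series(betas_true, hrf, onsets, sound_ids, nt)
  b <- sound_responses(ts, hrf, onsets, sound_ids, n_sounds)
  expect_lt(max(abs(b - betas_true)), 1e-6)
  expect_lt(max(abs(sound_responses(matrix(0, nt, 1), hrf[, 1, drop = FALSE],
                                    onsets, sound_ids, n_sounds))), 1e-12)
  # a noise regressor orthogonal to all sound predictors leaves betas unchanged
  ortho <- sin(2 * pi * seq_len(nt) / 2)  # Nyquist oscillation
  Xs <- sapply(1:n_sounds, function(sd) {
    p <- numeric(nt)
    for (ev in which(sound_ids == sd)) {
      idx <- onsets[ev] + 0:8
      p[idx] <- p[idx] + kernel
    }
    p
  })
  ortho <- ortho - Xs %*% solve(crossprod(Xs), crossprod(Xs, ortho))
  ortho <- ortho - mean(ortho)
  b2 <- sound_responses(ts, hrf, onsets, sound_ids, n_sounds,
                        noise_regs = ortho)
  expect_lt(max(abs(b2 - b)), 1e-8)
})

test_that("ridge encoding: OLS limit, shrinkage limit, tie-break to lowest band", {
  set.seed(15)
  X <- matrix(rnorm(60 * 8), 60, 8)
  W <- matrix(0, 8, 3); W[cbind(c(2, 5, 8), 1:3)] <- 1
  Y <- X %*% W
  Xs <- scale(X)
  Yc <- scale(Y, scale = FALSE)
  w0 <- cortexalign:::ridge_weights(Xs, Yc, 0)
  wls <- qr.coef(qr(Xs), Yc)
  expect_lt(max(abs(w0 - wls)), 1e-8)
  wbig <- cortexalign:::ridge_weights(Xs, Yc, 1e12)
  expect_lt(max(abs(wbig)), 1e-6)
  expect_error(ridge_encoding(X, list(Y), list(Y),
                              list(list(train = 1:60, test = 1:60)),
                              penalties = numeric(0)), "empty penalty")
  model <- ridge_encoding(X, list(Y[1:40, ]), list(Y[41:60, ]),
                          list(list(train = 1:40, test = 41:60)),
                          penalties = c(0.01, 1))
  expect_identical(model$best_band, c(2L, 5L, 8L))
})

test_that("best frequency map reads the argmax band and transports through warps", {
  mesh <- icosphere(2)
  nv <- nrow(mesh$vertices)
  centers <- attr(cochlear_features(list(rep(0, 100)), 16000), "centers")
  model <- structure(list(weights = NULL, best_band = rep(128L, nv),
                          best_frequency = rep(centers[128], nv),
                          centers = centers), class = "encoding_model")
  bf <- best_frequency_map(model)
  expect_equal(bf, rep(centers[128], nv))
  bf2 <- best_frequency_map(model, warp = mesh$vertices, mesh = mesh)
  expect_equal(bf2, rep(centers[128], nv), tolerance = 1e-9)
})
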