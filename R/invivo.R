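#' Adaptive upper-percentile threshold
#'
#' Scans upper percentiles p = `p_start` .. `p_end` (step `p_step`), computes
#' the forward differences of the percentile values, and thresholds at the
#' first percentile where the difference falls below `c_factor` times the
#' median difference after the sequence has decelerated (decreasing
#' differences) for 3 consecutive steps. Captures the transition from the
#' tissue bulk to the outlier tail (vessels, low-quality T2*w regions).
#'
#' @param x Numeric values.
#' @param p_start,p_end,p_step Percentile scan range (defaults 90..99.9 by
#'   0.1).
#' @param c_factor Multiplier on the median difference (default 2).
#' @return The threshold value (or `Inf` when no deceleration point is
#'   found), with attribute `percentile`.
#' @export
adaptive_percentile_threshold <- function(x, p_start = 90, p_end = 99.9,
                                          p_step = 0.1, c_factor = 2) {
  ps <- seq(p_start, p_end, by = p_step)
  vals <- quantile(x, ps / 100, names = FALSE)
  d <- diff(vals)
  med <- median(d)
  dec <- c(FALSE, diff(d) < 0)
  run <- 0L
  armed <- FALSE
  for (i in seq_along(d)) {
    run <- if (dec[i]) run + 1L else 0L
    if (run >= 3L) armed <- TRUE
    if (armed && d[i] < c_factor * med) {
      out <- vals[i]
      attr(out, "percentile") <- ps[i]
      return(out)
    }
  }
  out <- Inf
  attr(out, "percentile") <- NA_real_
  out
}

#' Myelin index volume from T1w and T2*w images
#'
#' Divides T1w by T2*w within the gray-matter mask, removes extreme values
#' above an adaptive upper-percentile threshold (vessels and regions of
#' insufficient T2*w quality), and min-max rescales the survivors to
#' \[0, 100\]. Zero-valued T2*w voxels are excluded (with a message); the
#' rescaling is monotone, so rank order among survivors is preserved.
#'
#' @param t1w,t2sw Co-registered [scalar_volume()]s.
#' @param gm_mask A non-empty [binary_mask()].
#' @param ... Passed to [adaptive_percentile_threshold()].
#' @return A [scalar_volume()] with values in \[0, 100\] inside the surviving
#'   mask and `NA` elsewhere; attributes `n_excluded_zero` and
#'   `n_excluded_outlier`.
#' @export
myelin_index <- function(t1w, t2sw, gm_mask, ...) {
  stopifnot(inherits(gm_mask, "binary_mask"))
  t1 <- as_volume(t1w)
  t2 <- as_volume(t2sw)
  if (!identical(dim(t1$data), dim(t2$data)) ||
      !identical(dim(t1$data), dim(gm_mask$data)))
    stop("volumes and mask must share one grid")
  if (!any(gm_mask$data)) stop("gray-matter mask is empty")
  sel <- gm_mask$data & t2$data != 0
  nzero <- sum(gm_mask$data) - sum(sel)
  if (nzero > 0)
    message(sprintf("myelin_index: excluded %d zero-valued T2*w voxel(s)",
                    nzero))
  ratio <- t1$data[sel] / t2$data[sel]
  thr <- adaptive_percentile_threshold(ratio, ...)
  survive <- ratio <= thr
  nout <- sum(!survive)
  if (!any(survive)) stop("no voxels survive the adaptive threshold")
  out <- array(NA_real_, dim(t1$data))
  vals <- ratio[survive]
  rng <- range(vals)
  scaled <- if (rng[1] == rng[2]) {
    warning("constant ratio within mask; all values mapped to 0")
    rep(0, length(vals))
  } else {
    (vals - rng[1]) / (rng[2] - rng[1]) * 100
  }
  idx <- which(sel)[survive]
  out[idx] <- scaled
  res <- scalar_volume(ifelse(is.na(out), 0, out), t1$spacing, t1$affine)
  res$data[is.na(out)] <- NA
  attr(res, "n_excluded_zero") <- nzero
  attr(res, "n_excluded_outlier") <- nout
  attr(res, "threshold") <- thr
  res
}

#' Sample a volume at vertex positions
#'
#' Nearest-voxel (default) or trilinear sampling of a volume at world-mm
#' vertex coordinates (e.g. mid-gray surface vertices), through the volume
#' affine.
#'
#' @param vol A [scalar_volume()].
#' @param vertices n x 3 world coordinates.
#' @param method `"nearest"` or `"trilinear"`.
#' @return Numeric vector of sampled values (`NA` outside the grid).
#' @export
sample_volume_at_vertices <- function(vol, vertices,
                                      method = c("nearest", "trilinear")) {
  method <- match.arg(method)
  vox <- cbind(vertices, 1) %*% t(solve(vol$affine))
  d <- dim(vol$data)
  if (method == "nearest") {
    ijk <- round(vox[, 1:3]) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 &
      ijk[, 2] <= d[2] & ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    out <- rep(NA_real_, nrow(ijk))
    out[ok] <- vol$data[cbind(ijk[ok, 1], ijk[ok, 2], ijk[ok, 3])]
    out
  } else {
    p <- vox[, 1:3] + 1
    p0 <- pmax(pmin(floor(p), matrix(d - 1, nrow(p), 3, byrow = TRUE)), 1)
    t <- p - p0
    out <- numeric(nrow(p))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) t[, 1] else 1 - t[, 1]) *
        (if (dy) t[, 2] else 1 - t[, 2]) *
        (if (dz) t[, 3] else 1 - t[, 3])
      out <- out + w * vol$data[cbind(p0[, 1] + dx, p0[, 2] + dy,
                                      p0[, 3] + dz)]
    }
    out
  }
}

#' Cochleagram-style band energies of sound waveforms
#'
#' Passes each sound through a bank of `n_bands` logarithmically spaced
#' band-pass filters (rectangular bands in the Fourier domain between
#' geometric edge frequencies) and returns the mean-square energy per band.
#' With `normalize = "bandwidth"` energies are divided by the band width in
#' Hz (energy density), under which white noise is flat.
#'
#' @param sounds List of numeric waveforms at a common sampling rate.
#' @param sample_rate Sampling rate in Hz.
#' @param fmin,fmax Filterbank range (defaults 180 Hz to 8 kHz); must satisfy
#'   `0 < fmin < fmax < sample_rate / 2`.
#' @param n_bands Number of bands (default 128).
#' @param normalize `"none"` (band energy) or `"bandwidth"` (energy per Hz).
#' @return sounds x n_bands matrix with attribute `centers` (band center
#'   frequencies, Hz).
#' @export
cochlear_features <- function(sounds, sample_rate, fmin = 180, fmax = 8000,
                              n_bands = 128, normalize = c("none", "bandwidth")) {
  normalize <- match.arg(normalize)
  if (!(fmin > 0 && fmin < fmax && fmax <= sample_rate / 2))
    stop("need 0 < fmin < fmax <= Nyquist")
  if (!is.list(sounds)) sounds <- list(sounds)
  edges <- exp(seq(log(fmin), log(fmax), length.out = n_bands + 1L))
  centers <- sqrt(edges[-1] * edges[-(n_bands + 1L)])
  out <- matrix(0, length(sounds), n_bands)
  for (s in seq_along(sounds)) {
    x <- sounds[[s]]
    n <- length(x)
    X <- fft(x)
    freqs <- (seq_len(n) - 1L) * sample_rate / n
    half <- freqs <= sample_rate / 2
    pow <- (Mod(X)^2) / n^2
    pow[!half] <- 0
    pow[-1] <- 2 * pow[-1]  # one-sided spectrum (fold negative frequencies)
    band <- findInterval(freqs, edges, rightmost.closed = TRUE)
    inband <- band >= 1L & band <= n_bands & half & freqs > 0
    if (any(inband)) {
      acc <- rowsum(pow[inband], band[inband])
      out[s, as.integer(rownames(acc))] <- acc
    }
  }
  if (normalize == "bandwidth") out <- sweep(out, 2, diff(edges), "/")
  attr(out, "centers") <- centers
  out
}

# stick design matrix: one column per post-onset lag
stick_design <- function(n_time, onsets, n_sticks) {
  X <- matrix(0, n_time, n_sticks)
  for (s in seq_len(n_sticks)) {
    t <- onsets + s - 1L
    t <- t[t >= 1L & t <= n_time]
    X[cbind(t, rep(s, length(t)))] <- X[cbind(t, rep(s, length(t)))] + 1
  }
  X
}

check_full_rank <- function(X, what) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    stop(sprintf("%s design is rank deficient (offending column(s): %s)",
                 what, paste(bad, collapse = ", ")))
  }
  qx
}

#' Voxel-wise HRF estimation by stick deconvolution
#'
#' Deconvolution GLM with `n_sticks` post-onset stick predictors (plus an
#' intercept and optional noise regressors): the least-squares estimate of
#' the hemodynamic response at volume resolution. Exact on noiseless data
#' with a full-rank design.
#'
#' @param ts T x V matrix of time series (volumes x vertices/voxels).
#' @param onsets Event onset volume indices (1-based).
#' @param n_sticks Number of post-onset samples (default 9).
#' @param noise_regs Optional T x k matrix of noise regressors.
#' @return An `n_sticks` x V matrix of HRF amplitude estimates.
#' @export
estimate_hrf <- function(ts, onsets, n_sticks = 9, noise_regs = NULL) {
  ts <- as.matrix(ts)
  X <- stick_design(nrow(ts), onsets, n_sticks)
  D <- cbind(X, 1, noise_regs)
  qx <- check_full_rank(D, "deconvolution")
  B <- qr.coef(qx, ts)
  matrix(B[seq_len(n_sticks), ], nrow = n_sticks,
         dimnames = list(NULL, colnames(ts)))
}

#' Per-sound response estimation with a voxel-specific HRF
#'
#' For each vertex, builds one predictor per sound (the sound's onset train
#' convolved with the vertex's HRF) plus an intercept and optional noise
#' regressors, and estimates the per-sound response amplitudes by least
#' squares.
#'
#' @param ts T x V time-series matrix.
#' @param hrf n_sticks x V HRF matrix from [estimate_hrf()].
#' @param onsets Event onset volume indices.
#' @param sound_ids Sound identity per onset (values 1..n_sounds).
#' @param n_sounds Total number of sounds (columns of the output).
#' @param noise_regs Optional T x k noise regressors.
#' @return n_sounds x V matrix of beta estimates.
#' @export
sound_responses <- function(ts, hrf, onsets, sound_ids,
                            n_sounds = max(sound_ids), noise_regs = NULL) {
  ts <- as.matrix(ts)
  nt <- nrow(ts)
  V <- ncol(ts)
  n_sticks <- nrow(hrf)
  betas <- matrix(0, n_sounds, V)
  onset_mat <- matrix(0, nt, n_sounds)
  for (ev in seq_along(onsets))
    onset_mat[onsets[ev], sound_ids[ev]] <- onset_mat[onsets[ev], sound_ids[ev]] + 1
  present <- which(colSums(onset_mat) > 0)
  for (v in seq_len(V)) {
    h <- hrf[, v]
    Xs <- sapply(present, function(sd) {
      p <- numeric(nt)
      for (s in seq_len(n_sticks)) {
        t <- which(onset_mat[, sd] > 0) + s - 1L
        t <- t[t <= nt]
        p[t] <- p[t] + h[s] * onset_mat[t - s + 1L, sd][seq_along(t)]
      }
      p
    })
    D <- cbind(Xs, 1, noise_regs)
    qx <- check_full_rank(D, sprintf("vertex %d response", v))
    b <- qr.coef(qx, ts[, v])
    betas[present, v] <- b[seq_along(present)]
  }
  betas
}

#' Noise regressors from training-run residual principal components
#'
#' Fits a sound-only model to the training series, takes the top-k principal
#' components of the residuals (across vertices), and returns them as noise
#' regressors. Estimated on training data only; apply per cross-validation
#' fold.
#'
#' @param ts T x V training series.
#' @param onsets,sound_ids,n_sounds As in [sound_responses()].
#' @param hrf HRF matrix for the sound-only model.
#' @param k Number of components (default 5).
#' @return T x k matrix of noise regressors.
#' @export
noise_pcs <- function(ts, hrf, onsets, sound_ids, n_sounds = max(sound_ids),
                      k = 5) {
  betas <- sound_responses(ts, hrf, onsets, sound_ids, n_sounds)
  fitted <- predict_series(betas, hrf, onsets, sound_ids, nrow(ts))
  resid <- as.matrix(ts) - fitted
  p <- svd(scale(resid, scale = FALSE), nu = min(k, ncol(resid)), nv = 0)
  p$u[, seq_len(min(k, ncol(p$u))), drop = FALSE]
}

# forward model: series implied by betas and per-vertex HRFs
predict_series <- function(betas, hrf, onsets, sound_ids, n_time) {
  V <- ncol(betas)
  n_sticks <- nrow(hrf)
  out <- matrix(0, n_time, V)
  for (ev in seq_along(onsets)) {
    idx <- onsets[ev] + seq_len(n_sticks) - 1L
    keep <- idx <= n_time
    out[idx[keep], ] <- out[idx[keep], ] +
      hrf[keep, , drop = FALSE] *
      matrix(betas[sound_ids[ev], ], sum(keep), V, byrow = TRUE)
  }
  out
}

# closed-form ridge via SVD; X already standardized, y centered by caller
ridge_weights <- function(X, Y, lambda) {
  s <- svd(X)
  d <- s$d / (s$d^2 + lambda)
  s$v %*% (d * (t(s$u) %*% Y))
}

#' Ridge-regression encoding of band energies
#'
#' Linearized encoding: per vertex, fits responses to the cochleagram
#' features with an L2 penalty, `w = argmin ||y - Xw||^2 + lambda ||w||^2`.
#' Features are standardized on the training data of each fold only; the
#' penalty is chosen per vertex by test-fold prediction accuracy (correlation)
#' averaged over the folds, and the final weights are the across-fold average
#' at the selected penalty. The best frequency of a vertex is the center
#' frequency of its largest weight (ties resolved to the lowest band).
#'
#' @param features sounds x bands matrix (with `centers` attribute, as from
#'   [cochlear_features()]).
#' @param responses_train,responses_test Lists (one per fold) of
#'   sounds x vertices beta matrices, rows indexed like `features` rows of
#'   the corresponding fold sound sets.
#' @param folds List (one per fold) of `list(train = ids, test = ids)` sound
#'   indices into `features` rows.
#' @param penalties Non-empty numeric grid of ridge penalties.
#' @return An `encoding_model` with `weights` (bands x vertices), `lambda`
#'   (per vertex), `best_band`, `best_frequency` and `accuracy` (per vertex,
#'   at the selected penalty).
#' @export
ridge_encoding <- function(features, responses_train, responses_test, folds,
                           penalties = 10^seq(-2, 4)) {
  if (!length(penalties)) stop("empty penalty grid")
  centers <- attr(features, "centers")
  if (is.null(centers)) centers <- seq_len(ncol(features))
  n_folds <- length(folds)
  V <- ncol(responses_train[[1]])
  nb <- ncol(features)
  acc <- array(0, c(length(penalties), V, n_folds))
  Ws <- array(0, c(nb, V, length(penalties), n_folds))
  for (f in seq_len(n_folds)) {
    Xtr <- features[folds[[f]]$train, , drop = FALSE]
    Xte <- features[folds[[f]]$test, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(Xtr, mu, sdv)
    Xte <- scale(Xte, mu, sdv)
    Ytr <- responses_train[[f]]
    ybar <- colMeans(Ytr)
    Ytr <- sweep(Ytr, 2, ybar)
    Yte <- responses_test[[f]]
    for (li in seq_along(penalties)) {
      W <- ridge_weights(Xtr, Ytr, penalties[li])
      Ws[, , li, f] <- W
      pred <- Xte %*% W
      pc <- sapply(seq_len(V), function(v) {
        if (sd(pred[, v]) == 0 || sd(Yte[, v]) == 0) 0
        else cor(pred[, v], Yte[, v])
      })
      acc[li, , f] <- pc
    }
  }
  mean_acc <- apply(acc, c(1, 2), mean)
  best_li <- apply(mean_acc, 2, which.max)
  weights <- sapply(seq_len(V), function(v)
    rowMeans(matrix(Ws[, v, best_li[v], ], nrow = nb)))
  weights <- matrix(weights, nrow = nb)
  best_band <- apply(weights, 2, which.max)   # ties -> lowest band
  structure(list(weights = weights, lambda = penalties[best_li],
                 best_band = best_band,
                 best_frequency = centers[best_band],
                 accuracy = mean_acc[cbind(best_li, seq_len(V))],
                 centers = centers),
            class = "encoding_model")
}

#' Best-frequency map, optionally transported to the group template
#'
#' Per-vertex preferred frequency from an encoding model. When a warp is
#' given the map is transported to the group template by barycentric
#' interpolation in log-frequency (then exponentiated), matching the
#' red-to-blue low-to-high display convention.
#'
#' @param model An `encoding_model`.
#' @param warp Optional warp (see [apply_warp()]).
#' @param mesh Standard [icosphere()] (required with `warp`).
#' @return Per-vertex best frequency (Hz).
#' @export
best_frequency_map <- function(model, warp = NULL, mesh = NULL) {
  bf <- model$best_frequency
  if (is.null(warp)) return(bf)
  stopifnot(!is.null(mesh))
  exp(apply_warp(log(bf), warp, mesh, kind = "scalar"))
}
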