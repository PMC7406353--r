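#' Specification of a two-tissue volume phantom
#'
#' Emulates the statistical structure of postmortem anatomical volumes: two
#' tissue classes (white and gray matter) separated by a folded analytic
#' boundary, blurred by a small acquisition point-spread function and
#' corrupted by additive Gaussian noise. All randomness is fixed by `seed`.
#'
#' @param dims Grid size (default 48^3).
#' @param wm_mean,gm_mean Tissue means (defaults 100 and 60).
#' @param noise_sd Additive noise standard deviation (default 10).
#' @param fold_wavelength,fold_amplitude Boundary fold wavelength and
#'   amplitude in voxels (defaults 24 and 5).
#' @param psf_sd Acquisition blur standard deviation in voxels (default 0.7).
#' @param spacing Voxel size (mm).
#' @param seed RNG seed.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(48, 48, 48), wm_mean = 100, gm_mean = 60,
                         noise_sd = 10, fold_wavelength = 24,
                         fold_amplitude = 5, psf_sd = 0.7,
                         spacing = c(1, 1, 1), seed = 1) {
  if (wm_mean == gm_mean) stop("tissue means must be distinct")
  structure(list(dims = as.integer(dims), wm_mean = wm_mean,
                 gm_mean = gm_mean, noise_sd = noise_sd,
                 fold_wavelength = fold_wavelength,
                 fold_amplitude = fold_amplitude, psf_sd = psf_sd,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a two-tissue volume phantom with ground truth
#'
#' The white-matter compartment lies below the folded surface
#' `z0 + A sin(2 pi x / L) sin(2 pi y / L)`; the truth masks (white matter and
#' one-voxel interface band) and analytic interface normals are exact.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` ([scalar_volume()]), `wm_mask`, `interface`
#'   (both [binary_mask()]), `normals` (interface-voxel normal matrix),
#'   `interface_idx` (linear indices), `wm_fraction` and
#'   `wm_fraction_analytic`.
#' @export
make_volume_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  z0 <- d[3] / 2
  if (spec$fold_amplitude >= min(z0, d[3] - z0))
    stop("fold amplitude exceeds the grid")
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  bxy <- z0 + spec$fold_amplitude *
    outer(sin(2 * pi * x / spec$fold_wavelength),
          sin(2 * pi * y / spec$fold_wavelength))
  B <- array(bxy, d)  # boundary height replicated over z
  Z <- array(rep(z, each = d[1] * d[2]), d)
  wm <- Z < B
  vol <- ifelse(wm, spec$wm_mean, spec$gm_mean)
  if (spec$psf_sd > 0) vol <- gaussian_smooth(vol, spec$psf_sd)
  if (spec$noise_sd > 0)
    vol <- vol + local_seed(spec$seed,
                            array(rnorm(prod(d), sd = spec$noise_sd), d))
  interface <- abs(Z - B) <= 1
  # analytic normal of z - b(x, y), normalized
  dbx <- spec$fold_amplitude * (2 * pi / spec$fold_wavelength) *
    outer(cos(2 * pi * x / spec$fold_wavelength),
          sin(2 * pi * y / spec$fold_wavelength))
  dby <- spec$fold_amplitude * (2 * pi / spec$fold_wavelength) *
    outer(sin(2 * pi * x / spec$fold_wavelength),
          cos(2 * pi * y / spec$fold_wavelength))
  idx <- which(interface)
  ai <- arrayInd(idx, d)
  nx <- -dbx[cbind(ai[, 1], ai[, 2])]
  ny <- -dby[cbind(ai[, 1], ai[, 2])]
  nz <- rep(1, length(idx))
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  list(volume = scalar_volume(vol, spec$spacing),
       wm_mask = binary_mask(wm, spec$spacing),
       interface = binary_mask(interface, spec$spacing),
       normals = cbind(nx, ny, nz) / nn,
       interface_idx = idx,
       wm_fraction = mean(wm),
       wm_fraction_analytic = z0 / d[3],
       spec = spec)
}

#' Mean absolute boundary-normal gradient at the true interface
#'
#' Projects the central-difference intensity gradient onto the analytic
#' interface normal and averages its absolute value over the interface band;
#' the statistic the edge-enhancing filter is expected to increase.
#'
#' @param v A [scalar_volume()] or 3D array.
#' @param phantom Output of [make_volume_phantom()].
#' @return Mean absolute normal gradient.
#' @export
interface_gradient <- function(v, phantom) {
  vol <- as_volume(v)
  g <- grad_cd(vol$data, vol$spacing)
  idx <- phantom$interface_idx
  gn <- g[[1]][idx] * phantom$normals[, 1] +
    g[[2]][idx] * phantom$normals[, 2] +
    g[[3]][idx] * phantom$normals[, 3]
  mean(abs(gn))
}

# ---------------------------------------------------------------------------
# spherical cohort with landmark-tied areas

deg2rad <- function(x) x * pi / 180

# unit direction from latitude/longitude in degrees
sph_dir <- function(lat, lon) {
  cbind(cos(deg2rad(lat)) * cos(deg2rad(lon)),
        cos(deg2rad(lat)) * sin(deg2rad(lon)),
        sin(deg2rad(lat)))
}

# angular distance (radians) from each vertex to a latitude arc segment
arc_distance <- function(V, lat, lon_range, n_samp = 200) {
  P <- sph_dir(lat, seq(lon_range[1], lon_range[2], length.out = n_samp))
  dots <- V %*% t(P)
  acos(pmin(1, pmax(-1, apply(dots, 1, max))))
}

vertex_latlon <- function(V) {
  list(lat = asin(pmin(1, pmax(-1, V[, 3]))) / pi * 180,
       lon = atan2(V[, 2], V[, 1]) / pi * 180)
}

#' Specification of a synthetic cortical cohort
#'
#' A cohort of genus-0 spherical subjects sharing a template curvature
#' pattern: a band-limited random field plus ridge/valley strips for four
#' anatomical landmarks (aHG, STG, STS, MTG), with eight area labels tied to
#' the landmark strips. Each subject is a smooth spherical deformation plus a
#' small rigid rotation of the template; labels, landmarks and curvature are
#' transported through the same known correspondence.
#'
#' @param n_subjects Cohort size (default 10).
#' @param level Icosphere subdivision level (default 4 for fast runs; use 6
#'   for full-scale evaluation).
#' @param deform_amplitude Maximum angular displacement of the planted
#'   deformation, radians (default 0.18, about 10 degrees — the scale of
#'   Heschl's-gyrus positional variability across individuals).
#' @param deform_fields Number of random tangent fields summed (default 8).
#' @param rotation_deg Rigid rotation magnitude per subject, degrees
#'   (default 8).
#' @param ridge_amp Landmark ridge/valley amplitude in curvature z-units
#'   (default 2).
#' @param ridge_sd Ridge width, degrees (default 6).
#' @param band_halfwidth Landmark support band half-width, degrees
#'   (default 4).
#' @param dup_prob Probability that a subject carries a posterior duplicate
#'   of the Heschl ridge (default 0.4, the prevalence of duplicated
#'   transverse temporal gyri). The duplicate is a curvature feature only —
#'   it carries no area labels and no landmark — creating the gyral
#'   ambiguity that purely curvature-driven alignment can confuse and an
#'   explicit aHG landmark resolves.
#' @param dup_amp Duplicate-ridge amplitude as a fraction of `ridge_amp`
#'   (default 0.5: duplicates are typically lower and less complete than
#'   the main transverse gyrus).
#' @param seed RNG seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, level = 4, deform_amplitude = 0.18,
                        deform_fields = 8, rotation_deg = 8, ridge_amp = 2,
                        ridge_sd = 6, band_halfwidth = 4, dup_prob = 0.4,
                        dup_amp = 0.5, seed = 1) {
  structure(list(n_subjects = as.integer(n_subjects), level = as.integer(level),
                 deform_amplitude = deform_amplitude,
                 deform_fields = as.integer(deform_fields),
                 rotation_deg = rotation_deg, ridge_amp = ridge_amp,
                 ridge_sd = ridge_sd, band_halfwidth = band_halfwidth,
                 dup_prob = dup_prob, dup_amp = dup_amp,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# landmark arcs: latitude, longitude range, curvature sign (gyrus -1/sulcus +1)
cohort_landmark_defs <- function() {
  list(aHG = list(lat = 30, lon = c(-30, 15), sign = -1),
       STG = list(lat = 12, lon = c(-60, 60), sign = -1),
       STS = list(lat = -6, lon = c(-60, 60), sign = +1),
       MTG = list(lat = -24, lon = c(-60, 60), sign = -1))
}

# area boxes in (lat, lon) degrees, tied to the landmark strips
cohort_area_defs <- function() {
  list(`Te1.0` = list(lat = c(24, 36), lon = c(-15, 0)),
       `Te1.1` = list(lat = c(24, 36), lon = c(-30, -15)),
       `Te1.2` = list(lat = c(24, 36), lon = c(0, 15)),
       `Te2.1` = list(lat = c(6, 18), lon = c(-60, 0)),
       `Te2.2` = list(lat = c(6, 18), lon = c(0, 60)),
       `Te3`   = list(lat = c(0, 6), lon = c(-60, 60)),
       `STS1`  = list(lat = c(-12, 0), lon = c(-60, 0)),
       `STS2`  = list(lat = c(-12, 0), lon = c(0, 60)))
}

#' Generate a synthetic cortical cohort with ground truth
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: `mesh` (the standard [icosphere()]),
#'   `template` (curvature, labels, landmark polylines and band maps) and
#'   `subjects`, each with `curvature`, `labels`, `landmark_maps` (band
#'   indicators), the true `correspondence` (per-vertex template positions)
#'   and the planted `rotation`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  mesh <- icosphere(spec$level)
  V <- mesh$vertices
  nv <- nrow(V)
  base_rounds <- max(4L, as.integer(round(2.5 * 4^(spec$level - 2))))
  lm_defs <- cohort_landmark_defs()
  local_seed(spec$seed, {
    base <- smooth_vertex_map(mesh, rnorm(nv), base_rounds)
    base <- (base - mean(base)) / sd(base)
    curv <- 1.0 * base   # secondary-folding texture alongside the landmark strips
    lm_maps <- list()
    lm_lines <- list()
    for (nm in names(lm_defs)) {
      def <- lm_defs[[nm]]
      dmat <- arc_distance(V, def$lat, def$lon)
      curv <- curv + def$sign * spec$ridge_amp *
        exp(-(dmat / deg2rad(spec$ridge_sd))^2)
      lm_maps[[nm]] <- as.numeric(dmat < deg2rad(spec$band_halfwidth))
      ends <- sph_dir(def$lat, def$lon)
      midp <- sph_dir(def$lat, mean(def$lon))
      anchors <- apply(rbind(ends[1, ], midp, ends[2, ]), 1, function(p)
        which.max(V %*% p))
      lm_lines[[nm]] <- landmark_to_map(mesh, anchors, name = nm)$polyline
    }
    ll <- vertex_latlon(V)
    labels <- rep("none", nv)
    for (nm in names(cohort_area_defs())) {
      a <- cohort_area_defs()[[nm]]
      inbox <- ll$lat >= a$lat[1] & ll$lat < a$lat[2] &
        ll$lon >= a$lon[1] & ll$lon < a$lon[2]
      labels[inbox] <- nm
    }
    # posterior duplicate of the Heschl ridge: curvature only, no labels
    dup_ridge <- -spec$ridge_amp * spec$dup_amp *
      exp(-(arc_distance(V, 21, c(-25, 10)) / deg2rad(spec$ridge_sd))^2)
    deform_rounds <- max(4L, as.integer(round(1.5 * 4^(spec$level - 2))))
    subjects <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      has_dup <- runif(1) < spec$dup_prob
      subj_curv_src <- if (has_dup) curv + dup_ridge else curv
      amp <- spec$deform_amplitude
      for (try in 1:10) {
        u <- matrix(0, nv, 3)
        if (amp > 0) {
          for (f in seq_len(spec$deform_fields)) {
            fld <- sapply(1:3, function(c3)
              smooth_vertex_map(mesh, rnorm(nv), deform_rounds))
            u <- u + fld
          }
          # tangent projection and scaling to the requested amplitude
          u <- u - V * rowSums(u * V)
          mx <- max(sqrt(rowSums(u^2)))
          if (mx > 0) u <- u * (amp / mx)
        }
        R <- diag(3)
        if (spec$rotation_deg > 0) {
          ax <- rnorm(3)
          ax <- ax / sqrt(sum(ax^2))
          R <- rotvec_to_matrix(ax * deg2rad(spec$rotation_deg))
        }
        Q <- V + u
        Q <- Q / sqrt(rowSums(Q^2))
        Q <- Q %*% t(R)
        if (all(face_dets(Q, mesh$faces) > 0)) break
        amp <- amp * 0.8
        message(sprintf("subject %d: deformation flipped faces; amplitude reduced to %.3g",
                        s, amp))
      }
      loc <- locate_on_sphere(mesh, Q)
      subjects[[s]] <- list(
        curvature = interp_from_loc(mesh, subj_curv_src, loc, "scalar"),
        labels = interp_from_loc(mesh, labels, loc, "categorical"),
        landmark_maps = lapply(lm_maps, function(m)
          interp_from_loc(mesh, m, loc, "categorical")),
        correspondence = Q,
        rotation = R,
        has_duplicate = has_dup)
    }
    structure(list(mesh = mesh,
                   template = list(curvature = curv, labels = labels,
                                   landmarks = lm_lines,
                                   landmark_maps = lm_maps),
                   subjects = subjects, spec = spec),
              class = "synthetic_cohort")
  })
}

# ---------------------------------------------------------------------------
# sound experiment

# canonical double-gamma HRF sampled at the volume time
hrf_kernel <- function(n_sticks = 9, tr = 2.6) {
  t <- (seq_len(n_sticks) - 1) * tr
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    0.35 * stats::dgamma(t, shape = 16, rate = 1)
  h / max(h)
}

#' Specification of a synthetic natural-sound experiment
#'
#' Emulates the in-vivo design: 168 natural sounds in four cross-validation
#' splits of 126 training and 42 testing sounds, responses generated from a
#' known frequency-preference map through band-energy features and a
#' canonical HRF at 2.6 s volume time, plus seeded noise at a stated SNR.
#'
#' @param n_sounds Total sounds (default 168).
#' @param n_folds Cross-validation splits (default 4).
#' @param n_vertices Simulated vertices (default 80).
#' @param n_bands Feature bands (default 128).
#' @param snr Signal-to-noise variance ratio (> 0; `Inf` = noiseless).
#' @param tr Volume time in seconds (default 2.6).
#' @param isi Inter-stimulus interval range in volumes (default 3 to 5).
#' @param n_sticks HRF length in volumes (default 9).
#' @param fmin,fmax Filterbank range labels for the feature bands.
#' @param seed RNG seed.
#' @return A `sound_spec`.
#' @export
sound_spec <- function(n_sounds = 168, n_folds = 4, n_vertices = 80,
                       n_bands = 128, snr = 2, tr = 2.6, isi = c(3, 5),
                       n_sticks = 9, fmin = 180, fmax = 8000, seed = 1) {
  if (snr <= 0) stop("SNR must be positive (use Inf for noiseless)")
  if (n_sounds %% n_folds != 0)
    stop("n_sounds must be divisible by n_folds")
  structure(list(n_sounds = as.integer(n_sounds),
                 n_folds = as.integer(n_folds),
                 n_vertices = as.integer(n_vertices),
                 n_bands = as.integer(n_bands), snr = snr, tr = tr,
                 isi = as.integer(isi), n_sticks = as.integer(n_sticks),
                 fmin = fmin, fmax = fmax, seed = as.integer(seed)),
            class = "sound_spec")
}

#' Generate a synthetic sound-encoding experiment with ground truth
#'
#' @param spec A [sound_spec()].
#' @return A `sound_experiment`: `features` (sounds x bands, with band-center
#'   attribute), `folds` (train/test sound ids per split), `runs` (per fold:
#'   train and test series with onsets and sound ids), and `truth`
#'   (per-vertex preferred band and frequency, true weights, HRF, betas,
#'   per-fold noise-free signals).
#' @export
make_sound_experiment <- function(spec = sound_spec()) {
  stopifnot(inherits(spec, "sound_spec"))
  ns <- spec$n_sounds
  nb <- spec$n_bands
  V <- spec$n_vertices
  edges <- exp(seq(log(spec$fmin), log(spec$fmax), length.out = nb + 1))
  centers <- sqrt(edges[-1] * edges[-(nb + 1)])
  local_seed(spec$seed, {
    bump_center <- runif(ns, 1, nb)
    bump_amp <- runif(ns, 0.5, 1.5)
    features <- t(sapply(seq_len(ns), function(i)
      bump_amp[i] * exp(-((seq_len(nb) - bump_center[i]) / 4)^2) +
        0.05 * abs(rnorm(nb))))
    attr(features, "centers") <- centers
    best_band <- as.integer(round(seq(1, nb, length.out = V)))
    W_true <- matrix(0, nb, V)
    W_true[cbind(best_band, seq_len(V))] <- 1
    betas <- features %*% W_true
    kernel <- hrf_kernel(spec$n_sticks, spec$tr)
    hrf_mat <- matrix(kernel, spec$n_sticks, V)
    test_block <- ns / spec$n_folds
    folds <- lapply(seq_len(spec$n_folds), function(k) {
      test <- ((k - 1) * test_block + 1):(k * test_block)
      list(train = setdiff(seq_len(ns), test), test = test)
    })
    make_series <- function(ids) {
      ids <- sample(ids)
      gaps <- sample(seq(spec$isi[1], spec$isi[2]), length(ids),
                     replace = TRUE)
      onsets <- cumsum(gaps) - gaps[1] + 2L
      nt <- max(onsets) + spec$n_sticks + 3L
      signal <- predict_series(betas, hrf_mat, onsets, ids, nt)
      noise_sd <- if (is.infinite(spec$snr)) rep(0, V) else
        pmax(apply(signal, 2, sd), 1e-12) / sqrt(spec$snr)
      ts <- signal + matrix(rnorm(nt * V), nt, V) %*% diag(noise_sd, V)
      list(ts = ts, onsets = onsets, sound_ids = ids, signal = signal)
    }
    runs <- lapply(folds, function(fl)
      list(train = make_series(fl$train), test = make_series(fl$test)))
    structure(list(features = features, folds = folds, runs = runs,
                   truth = list(best_band = best_band,
                                best_frequency = centers[best_band],
                                weights = W_true, hrf = kernel,
                                betas = betas),
                   spec = spec),
              class = "sound_experiment")
  })
}

#' Run the full encoding pipeline on a synthetic experiment
#'
#' Per cross-validation fold: estimate each vertex's HRF on the training
#' series by stick deconvolution, estimate per-sound responses on training
#' and test series with the optimized HRF, then fit the ridge encoding model
#' across folds and read out each vertex's best frequency.
#'
#' @param exper A `sound_experiment` from [make_sound_experiment()].
#' @param penalties Ridge penalty grid.
#' @return A list with the `encoding_model` and `recovery` (fraction of
#'   vertices whose best band is within +-1 band of the planted tuning).
#' @export
run_encoding <- function(exper, penalties = 10^seq(-2, 4)) {
  stopifnot(inherits(exper, "sound_experiment"))
  ns <- exper$spec$n_sounds
  resp_tr <- list()
  resp_te <- list()
  for (f in seq_along(exper$folds)) {
    tr <- exper$runs[[f]]$train
    te <- exper$runs[[f]]$test
    hrf <- estimate_hrf(tr$ts, tr$onsets, exper$spec$n_sticks)
    btr <- sound_responses(tr$ts, hrf, tr$onsets, tr$sound_ids, ns)
    bte <- sound_responses(te$ts, hrf, te$onsets, te$sound_ids, ns)
    resp_tr[[f]] <- btr[exper$folds[[f]]$train, , drop = FALSE]
    resp_te[[f]] <- bte[exper$folds[[f]]$test, , drop = FALSE]
  }
  model <- ridge_encoding(exper$features, resp_tr, resp_te, exper$folds,
                          penalties)
  recovery <- mean(abs(model$best_band - exper$truth$best_band) <= 1)
  list(model = model, recovery = recovery)
}
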