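test_that("volume phantom: determinism, noiseless two-value rule, WM fraction", {
  sp0 <- phantom_spec(dims = c(24, 24, 24), noise_sd = 0, psf_sd = 0, seed = 1)
  ph0 <- make_volume_phantom(sp0)
  expect_identical(sort(unique(as.vector(ph0$volume$data))), c(60, 100))
  a <- make_volume_phantom(phantom_spec(dims = c(24, 24, 24), seed = 3))
  b <- make_volume_phantom(phantom_spec(dims = c(24, 24, 24), seed = 3))
  expect_identical(a$volume$data, b$volume$data)
  c2 <- make_volume_phantom(phantom_spec(dims = c(24, 24, 24), seed = 4))
  expect_false(identical(a$volume$data, c2$volume$data))
  # analytic volume fraction within one voxel layer
  expect_lt(abs(ph0$wm_fraction - ph0$wm_fraction_analytic), 1 / 24)
  expect_error(make_volume_phantom(phantom_spec(dims = c(16, 16, 16),
                                                fold_amplitude = 20)),
               "exceeds the grid")
})

test_that("cohort: determinism, identity at zero amplitude, stored correspondence", {
  sp <- cohort_spec(n_subjects = 3, level = 2, seed = 5)
  a <- make_cohort(sp)
  b <- make_cohort(sp)
  expect_identical(a$subjects[[2]]$curvature, b$subjects[[2]]$curvature)
  expect_identical(a$subjects[[3]]$labels, b$subjects[[3]]$labels)
  # amplitude 0, no rotation: all subjects identical to the template
  z <- make_cohort(cohort_spec(n_subjects = 3, level = 2,
                               deform_amplitude = 0, rotation_deg = 0,
                               dup_prob = 0, seed = 2))
  for (s in z$subjects) {
    expect_equal(s$curvature, z$template$curvature, tolerance = 1e-9)
    expect_identical(s$labels, z$template$labels)
  }
  tab <- cohort_loo_dice(z, lapply(z$subjects, function(s) z$mesh$vertices),
                         min_overlap = 2)
  expect_true(all(abs(as.matrix(tab[, 1:3]) - 1) < 1e-12))
  # the stored correspondence regenerates each subject from the template
  co <- make_cohort(cohort_spec(n_subjects = 2, level = 3, dup_prob = 0,
                                seed = 8))
  for (s in co$subjects) {
    rec <- sphere_interp(co$mesh, co$template$curvature, s$correspondence)
    expect_lt(max(abs(rec - s$curvature)), 1e-6)
    expect_true(all(cortexalign:::face_dets(s$correspondence,
                                            co$mesh$faces) > 0))
  }
  # labels mutually exclusive with 8 areas tied to the landmark strips
  areas <- setdiff(unique(co$template$labels), "none")
  expect_setequal(areas, c("Te1.0", "Te1.1", "Te1.2", "Te2.1", "Te2.2",
                           "Te3", "STS1", "STS2"))
})

test_that("sound experiment: determinism, noiseless identifiability, stated SNR", {
  sp <- sound_spec(n_sounds = 24, n_folds = 4, n_vertices = 10, n_bands = 32,
                   seed = 3)
  a <- make_sound_experiment(sp)
  b <- make_sound_experiment(sp)
  expect_identical(a$runs[[1]]$train$ts, b$runs[[1]]$train$ts)
  expect_identical(a$truth$best_band, b$truth$best_band)
  # fold structure: disjoint test blocks covering all sounds
  tests <- unlist(lapply(a$folds, `[[`, "test"))
  expect_identical(sort(tests), 1:24)
  for (f in a$folds) expect_identical(sort(union(f$train, f$test)), 1:24)
  expect_error(sound_spec(snr = 0), "positive")
  # noiseless experiment recovers every vertex's preferred band (training
  # sounds per fold must exceed the band count for identifiability)
  nl <- make_sound_experiment(sound_spec(n_sounds = 64, n_folds = 4,
                                         n_vertices = 10, n_bands = 16,
                                         snr = Inf, seed = 3))
  res <- run_encoding(nl, penalties = c(0.01, 1))
  expect_identical(res$model$best_band, nl$truth$best_band)
  expect_identical(res$recovery, 1)
})

test_that("generated series realize the requested SNR within 10%", {
  snrs <- sapply(1:30, function(seed) {
    ex <- make_sound_experiment(sound_spec(n_sounds = 8, n_folds = 2,
                                           n_vertices = 6, n_bands = 16,
                                           snr = 2, seed = seed))
    r <- ex$runs[[1]]$train
    noise <- r$ts - r$signal
    mean(apply(r$signal, 2, var) / apply(noise, 2, var))
  })
  expect_lt(abs(mean(snrs) - 2) / 2, 0.1)
})
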