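test_that("deposit generation is deterministic under the seed", {
  sp <- deposit_spec(seed = 42)
  a <- generate_deposit(sp)
  b <- generate_deposit(sp)
  expect_identical(a$pixels, b$pixels)
  # crystal-free noiseless spec renders only disc + ring, always identically
  clean <- deposit_spec(crystal_density = 0, noise_sd = 0, seed = 1)
  c1 <- generate_deposit(clean)
  c2 <- generate_deposit(clean)
  expect_identical(c1$pixels, c2$pixels)
  expect_equal(attr(c1, "n_crystals"), 0L)
  expect_true(all(unique(as.vector(c1$pixels)) %in%
                    c(clean$background, clean$disc_intensity,
                      clean$ring_intensity)))
  # different seeds change the realization
  expect_false(identical(generate_deposit(deposit_spec(seed = 7))$pixels,
                         generate_deposit(deposit_spec(seed = 8))$pixels))
})

test_that("crystal counts follow the Poisson intensity", {
  dens <- 0.004
  counts1 <- vapply(1:100, function(s)
    attr(generate_deposit(deposit_spec(crystal_density = dens, seed = s)),
         "n_crystals"), integer(1))
  R <- 0.45 * 96
  lambda <- dens * pi * R^2
  # mean within 3 standard errors of the Poisson mean
  expect_lt(abs(mean(counts1) - lambda), 3 * sqrt(lambda / 100))
  counts2 <- vapply(1:100, function(s)
    attr(generate_deposit(deposit_spec(crystal_density = 2 * dens,
                                       seed = 10000 + s)),
         "n_crystals"), integer(1))
  expect_lt(abs(mean(counts2) - 2 * lambda), 3 * sqrt(2 * lambda / 100))
})

test_that("texture responds to crystal density in the physical direction", {
  dens <- c(0, 0.003, 0.008, 0.02)
  feats <- lapply(dens, function(d) {
    imgs <- lapply(1:4, function(s)
      generate_deposit(deposit_spec(crystal_density = d, seed = 100 * s)))
    rows <- lapply(imgs, function(im) {
      g <- glcm_features_protocol(im)
      data.frame(entropy = g$entropy, inertia = g$inertia,
                 energy = g$energy, idm = g$idm)
    })
    colMeans(do.call(rbind, rows))
  })
  feats <- do.call(rbind, feats)
  expect_true(all(diff(feats[, "entropy"]) >= 0))
  expect_true(all(diff(feats[, "inertia"]) >= 0))
  expect_true(all(diff(feats[, "energy"]) <= 0))
  expect_true(all(diff(feats[, "idm"]) <= 0))
})

test_that("series generation records truth and honors the density map", {
  sp <- series_spec(n_rep = 2, seed = 5)
  ser <- generate_series(sp)
  expect_equal(nrow(ser$manifest), length(sp$x) * 2)
  expect_equal(length(ser$images), nrow(ser$manifest))
  tr <- attr(ser$manifest, "truth")
  expect_equal(unname(tr["k_true"]), sp$k_true)
  dens <- sp$Ds - sp$D0 * exp(-sp$x / sp$k_true)
  expect_equal(unique(ser$manifest$true_density), dens)
  expect_gte(min(dens), 0)
  # rerun reproduces the identical corpus
  ser2 <- generate_series(sp)
  expect_identical(ser$images[[5]]$pixels, ser2$images[[5]]$pixels)
})

test_that("evaporation sequences expose their true stage boundaries", {
  ev <- generate_evaporation_sequence(n_frames = 18,
                                      stage_plan = c(6, 6, 6))
  expect_s3_class(ev$sequence, "frame_sequence")
  expect_equal(ev$sequence$n_frames, 18)
  expect_equal(ev$boundaries, c(6, 12))
  expect_equal(ev$stage_labels,
               c("coffee_ring", "crystal_growth", "water_drying"))
  expect_error(generate_evaporation_sequence(n_frames = 10,
                                             stage_plan = c(5, 5, 5)),
               "stage_plan")
})

test_that("feature tables carry the requested group structure", {
  tab <- generate_feature_table(g = 5, n_per_group = 24,
                                centroid_separation = 10, seed = 1)
  expect_equal(dim(tab$features), c(120L, 10L))
  expect_equal(levels(tab$labels), paste0("grp", 1:5))
  expect_named(tab$features,
               c("mean", "std", "integrated_density", "skewness",
                 "kurtosis_excess", "energy", "inertia", "correlation",
                 "idm", "entropy"))
  null_tab <- generate_feature_table(g = 3, n_per_group = 10,
                                     centroid_separation = 0, seed = 2)
  expect_true(all(abs(colMeans(null_tab$features)) < 1.5))
  expect_warning(generate_feature_table(g = 2, n_per_group = 1, seed = 3),
                 "n_per_group")
})
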