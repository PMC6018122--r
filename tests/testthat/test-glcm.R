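test_that("the 4x4 worked example yields the known count matrix", {
  px <- matrix(c(0, 0, 1, 1,
                 0, 0, 1, 1,
                 0, 2, 2, 2,
                 2, 2, 3, 3), 4, 4, byrow = TRUE)
  g <- compute_glcm(gray_image(px, n_levels = 4), distance = 1, angle = 0,
                    symmetric = TRUE)
  expected <- matrix(c(4, 2, 1, 0,
                       2, 4, 0, 0,
                       1, 0, 6, 1,
                       0, 0, 1, 2), 4, 4, byrow = TRUE)
  expect_equal(g$counts, expected)
  expect_equal(g$n_pairs, 24)
  expect_equal(sum(g$probs), 1, tolerance = 1e-12)
})

test_that("degenerate and symmetric matrices behave as required", {
  const <- gray_image(matrix(9L, 6, 6))
  for (a in c(0, 45, 90, 135)) {
    g <- compute_glcm(const, distance = 2, angle = a)
    expect_equal(g$probs[10, 10], 1)
    expect_equal(sum(g$probs != 0), 1)
  }
  set.seed(3)
  r <- rand_img(10, 10, 8)
  g <- compute_glcm(r, 1, 0, symmetric = TRUE)
  expect_identical(g$probs, t(g$probs))
  # symmetric counts are the two-directional sum of the one-directional ones
  g1 <- compute_glcm(r, 1, 0, symmetric = FALSE)
  expect_equal(g$counts, g1$counts + t(g1$counts))
  expect_error(compute_glcm(gray_image(matrix(0L, 2, 2)), distance = 5,
                            angle = 0), "too small")
})

test_that("marginal moments match the weighted-sum oracle", {
  single <- list(probs = diag(c(0, 0, 1, 0)), distance = 1L, angle = 0,
                 symmetric = TRUE, n_levels = 4L)
  m <- glcm_marginals(single)
  expect_equal(m$ux, 2)
  expect_equal(m$uy, 2)
  expect_equal(m$sd_x, 0)
  two <- single
  two$probs <- matrix(c(0, .5, .5, 0), 2, 2)
  m2 <- glcm_marginals(two)
  expect_equal(m2$ux, 0.5)
  expect_equal(m2$uy, 0.5)
  set.seed(13)
  p <- matrix(stats::runif(36), 6, 6)
  p <- p / sum(p)
  o <- oracle_glcm_features(p)
  m3 <- glcm_marginals(list(probs = p))
  expect_equal(m3$ux, o$ux, tolerance = 1e-12)
  expect_equal(m3$uy, o$uy, tolerance = 1e-12)
  expect_equal(m3$var_x, o$vx, tolerance = 1e-12)
  expect_equal(m3$var_y, o$vy, tolerance = 1e-12)
  # symmetric matrix has equal marginals
  set.seed(14)
  q <- matrix(stats::runif(25), 5, 5); q <- q + t(q); q <- q / sum(q)
  ms <- glcm_marginals(list(probs = q))
  expect_equal(ms$ux, ms$uy, tolerance = 1e-12)
  expect_equal(ms$sd_x, ms$sd_y, tolerance = 1e-12)
})

test_that("trivial-limit features are exact", {
  const <- compute_glcm(gray_image(matrix(3L, 5, 5), n_levels = 8), 1, 0)
  f <- glcm_features(const)
  expect_equal(f$energy, 1)
  expect_equal(f$inertia, 0)
  expect_equal(f$idm, 1)
  expect_equal(f$entropy, 0)
  expect_true(is.na(f$correlation))

  checker <- gray_image(outer(1:8, 1:8, function(r, c)
    ifelse((r + c) %% 2 == 0, 0L, 255L)))
  g <- compute_glcm(checker, 1, 0, symmetric = TRUE)
  expect_equal(g$probs[1, 256], 0.5)
  expect_equal(g$probs[256, 1], 0.5)
  fc <- glcm_features(g)
  expect_equal(fc$energy, 0.5)
  expect_equal(fc$inertia, 255^2)
  expect_equal(fc$idm, 1 / (1 + 255^2))
  expect_equal(fc$entropy, log(2))
  expect_equal(glcm_features(g, log_base = 2)$entropy, 1)
})

test_that("features match the pair-enumeration oracle at every angle", {
  set.seed(99)
  for (rep in 1:10) {
    img <- rand_img(sample(8:20, 1), sample(8:20, 1), sample(c(4, 8, 16), 1))
    d <- sample(1:2, 1)
    for (a in c(0, 45, 90, 135)) {
      C <- oracle_glcm_counts(img$pixels, img$n_levels, d, a)
      o <- oracle_glcm_features(C / sum(C))
      f <- glcm_features(compute_glcm(img, d, a))
      for (nm in c("energy", "inertia", "correlation", "idm", "entropy"))
        expect_equal(f[[nm]], o[[nm]], tolerance = 1e-9,
                     label = sprintf("%s d=%d a=%d", nm, d, a))
    }
  }
})

test_that("literal correlation mode divides by the unrooted sums", {
  set.seed(8)
  img <- rand_img(12, 12, 8)
  g <- compute_glcm(img, 1, 45)
  o <- oracle_glcm_features(g$probs)
  lit <- glcm_features(g, correlation_mode = "literal")
  expect_equal(lit$correlation,
               (o$correlation * sqrt(o$vx * o$vy)) / (o$vx * o$vy),
               tolerance = 1e-9)
  # rooted default is bounded in [-1, 1]
  expect_lte(abs(glcm_features(g)$correlation), 1)
})

test_that("four-angle protocol averages per-angle features", {
  const <- gray_image(matrix(100L, 10, 10))
  f <- glcm_features_protocol(const, distance = 3)
  expect_equal(f$energy, 1)
  expect_equal(f$inertia, 0)
  expect_equal(f$idm, 1)
  expect_equal(f$entropy, 0)

  set.seed(17)
  img <- rand_img(14, 14, 8)
  f <- glcm_features_protocol(img, distance = 2)
  per <- lapply(c(0, 45, 90, 135), function(a)
    glcm_features(compute_glcm(img, 2, a)))
  for (nm in c("energy", "inertia", "correlation", "idm", "entropy"))
    expect_equal(f[[nm]], mean(vapply(per, `[[`, numeric(1), nm)),
                 tolerance = 1e-12)
  # matrix-level averaging is a distinct, supported protocol
  fm <- glcm_features_protocol(img, distance = 2, average = "matrix")
  expect_false(isTRUE(all.equal(fm$entropy, f$entropy)))
})

test_that("rotating the image by 90 degrees permutes per-angle features", {
  set.seed(23)
  img <- rand_img(12, 12, 8)
  rot <- gray_image(t(img$pixels)[, nrow(img$pixels):1, drop = FALSE],
                    img$n_levels)
  pairs <- list(c(0, 90), c(90, 0), c(45, 135), c(135, 45))
  for (pr in pairs) {
    f1 <- glcm_features(compute_glcm(img, 1, pr[1]))
    f2 <- glcm_features(compute_glcm(rot, 1, pr[2]))
    for (nm in c("energy", "inertia", "idm", "entropy"))
      expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-12)
  }
  fa <- glcm_features_protocol(img, distance = 1)
  fb <- glcm_features_protocol(rot, distance = 1)
  for (nm in c("energy", "inertia", "correlation", "idm", "entropy"))
    expect_equal(fa[[nm]], fb[[nm]], tolerance = 1e-12)
})

test_that("entropy and energy attain their extremes together", {
  set.seed(31)
  for (rep in 1:20) {
    img <- rand_img(10, 10, 8)
    f <- glcm_features(compute_glcm(img, 1, 0))
    expect_lte(f$energy, 1)
    expect_lte(f$idm, 1)
    expect_gte(f$entropy, 0)
    expect_lte(f$entropy, log(8^2))
    expect_equal(f$energy == 1, f$entropy == 0)
  }
})
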