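# determinant-based Wilks oracle, independent of the eigen route
oracle_wilks <- function(X, labels) {
  labels <- factor(labels)
  grand <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(labels)) {
    Xi <- X[labels == lev, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  Tm <- crossprod(sweep(X, 2, grand))
  det(W) / det(Tm)
}

test_that("full-model Wilks' lambda equals det(W)/det(W+B)", {
  set.seed(12)
  for (rep in 1:10) {
    g <- sample(2:4, 1); p <- sample(2:5, 1)
    tab <- generate_feature_table(g = g, n_per_group = 15,
                                  centroid_separation = stats::runif(1, 0, 2),
                                  n_features = p, seed = 1000 + rep)
    model <- fit_cda(tab$features, tab$labels)
    expect_equal(model$wilks[1],
                 oracle_wilks(as.matrix(tab$features), tab$labels),
                 tolerance = 1e-9)
    expect_equal(length(model$eigenvalues), min(p, g - 1))
    expect_true(all(model$wilks > 0 & model$wilks <= 1))
  }
})

test_that("Wilks' lambda agrees with the MANOVA reference", {
  tab <- generate_feature_table(g = 3, n_per_group = 20,
                                centroid_separation = 1.5, n_features = 4,
                                seed = 77)
  model <- fit_cda(tab$features, tab$labels)
  mv <- summary(stats::manova(as.matrix(tab$features) ~ tab$labels),
                test = "Wilks")
  expect_equal(model$wilks[1], mv$stats[1, "Wilks"], tolerance = 1e-9)
})

test_that("canonical scores have unit pooled within-group variance", {
  tab <- generate_feature_table(g = 4, n_per_group = 30,
                                centroid_separation = 3, n_features = 6,
                                seed = 5)
  model <- fit_cda(tab$features, tab$labels)
  sc <- canonical_scores(model, cbind(tab$features, .group = tab$labels))
  S <- cbind(sc$scores$CF1, sc$scores$CF2)
  Wp <- matrix(0, 2, 2)
  for (lev in levels(tab$labels)) {
    Si <- S[tab$labels == lev, , drop = FALSE]
    Wp <- Wp + crossprod(sweep(Si, 2, colMeans(Si)))
  }
  Wp <- Wp / (nrow(S) - nlevels(tab$labels))
  expect_equal(diag(Wp), c(1, 1), tolerance = 1e-9)
  expect_equal(Wp[1, 2], 0, tolerance = 1e-9)
})

test_that("null tables are rejected at about the nominal rate", {
  set.seed(202)
  rejections <- vapply(1:200, function(i) {
    tab <- generate_feature_table(g = 2, n_per_group = 50,
                                  centroid_separation = 0, n_features = 5,
                                  seed = 5000 + i)
    fit_cda(tab$features, tab$labels)$p_values[1] < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
})

test_that("well-separated groups classify perfectly at mirrored design size", {
  tab <- generate_feature_table(g = 5, n_per_group = 24,
                                centroid_separation = 10, seed = 9)
  model <- fit_cda(tab$features, tab$labels)
  expect_lt(model$wilks[1], 1e-4)
  expect_lt(model$p_values[1], 0.05)
  er <- error_rate(model, cbind(tab$features, .group = tab$labels))
  expect_equal(er$overall, 0)
  expect_equal(unname(rowSums(er$confusion)), rep(24L, 5))
  # fresh rows from the same populations classify almost perfectly
  new <- generate_feature_table(g = 5, n_per_group = 100,
                                centroid_separation = 10, seed = 10)
  agree <- mean(classify(model, new$features) == new$labels)
  expect_gte(agree, 0.99)
})

test_that("degenerate tables raise the documented errors", {
  # zero within-group variance: rows identical within groups
  feats <- data.frame(a = rep(c(0, 1), each = 5), b = rep(c(1, 0), each = 5))
  expect_error(fit_cda(feats, rep(c("u", "v"), each = 5)), "singular")
  tab <- generate_feature_table(g = 2, n_per_group = 10, seed = 3,
                                n_features = 3)
  expect_error(fit_cda(tab$features, rep("one", 20)), "at least 2 groups")
  expect_error(fit_cda(tab$features[1:11, ],
                       c(rep("a", 10), "b")), "at least 2 observations")
  # undefined feature values are dropped with a warning, then fit proceeds
  tf <- tab$features
  tf$f1[1] <- NA
  expect_warning(m <- fit_cda(tf, tab$labels), "dropped")
  expect_s3_class(m, "cda")
})

test_that("classification ties break to the lexicographically smaller label", {
  tab <- generate_feature_table(g = 2, n_per_group = 20,
                                centroid_separation = 6, n_features = 2,
                                seed = 31)
  model <- fit_cda(tab$features, tab$labels)
  cen <- model$means
  mid <- as.data.frame(t((cen[1, ] + cen[2, ]) / 2))
  expect_equal(as.character(classify(model, mid)), "grp1")
  for (lev in rownames(cen))
    expect_equal(as.character(classify(model,
                                       as.data.frame(t(cen[lev, ])))), lev)
  expect_error(classify(model, data.frame(zz = 1)), "feature mismatch")
})

test_that("permuted labels give chance-level training error", {
  set.seed(404)
  rates <- vapply(1:20, function(i) {
    tab <- generate_feature_table(g = 4, n_per_group = 30,
                                  centroid_separation = 8, n_features = 5,
                                  seed = 7000 + i)
    perm <- sample(tab$labels)
    model <- fit_cda(tab$features, perm)
    error_rate(model, cbind(tab$features, .group = perm))$overall
  }, numeric(1))
  expect_equal(mean(rates), 1 - 1 / 4, tolerance = 0.12)
})

test_that("the model is invariant to feature rescaling", {
  tab <- generate_feature_table(g = 3, n_per_group = 18,
                                centroid_separation = 2, n_features = 4,
                                seed = 55)
  m1 <- fit_cda(tab$features, tab$labels)
  scaled <- as.data.frame(as.matrix(tab$features) * 37.5)
  m2 <- fit_cda(scaled, tab$labels)
  expect_equal(m1$wilks, m2$wilks, tolerance = 1e-9)
  expect_equal(m1$p_values, m2$p_values, tolerance = 1e-9)
  expect_equal(classify(m1, tab$features), classify(m2, scaled))
})

test_that("the formula interface matches the data-frame interface", {
  tab <- generate_feature_table(g = 3, n_per_group = 15,
                                centroid_separation = 4, n_features = 3,
                                seed = 61)
  df <- cbind(tab$features, group = tab$labels)
  m1 <- fit_cda(group ~ ., data = df)
  m2 <- fit_cda(tab$features, tab$labels)
  expect_equal(m1$wilks, m2$wilks)
  expect_equal(m1$coefficients, m2$coefficients)
})
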