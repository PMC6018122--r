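#' Canonical discriminant analysis of texture-feature tables
#'
#' Fits canonical discriminant functions — linear combinations of the
#' features that maximize between-group relative to pooled within-group
#' scatter — by solving the generalized eigenproblem of the between-group
#' scatter matrix against the pooled within-group scatter matrix. The
#' candidate functions (at most `min(p, g - 1)`) are ordered by decreasing
#' eigenvalue and scaled so canonical scores have pooled within-group
#' variance 1. Sequential Wilks' lambda tests with Bartlett's chi-square
#' approximation,
#' \deqn{\Lambda_m = \prod_{i > m} \frac{1}{1 + \lambda_i}, \quad
#'   \chi^2 = -(n - 1 - (p + g)/2)\,\ln \Lambda_m,}
#' with `(p - m)(g - 1 - m)` degrees of freedom, decide how many functions
#' to retain (those with p below `alpha`).
#'
#' Rows with missing feature values (e.g. undefined skewness or correlation
#' from degenerate images) are dropped with a warning before fitting. The
#' pooled within-group scatter uses the `n - g` denominator.
#'
#' @param x a data frame of numeric features (or a formula; see
#'   [fit_cda.formula()]).
#' @param labels group label per row (factor or character); at least 2
#'   groups with at least 2 observations each.
#' @param alpha significance level for function retention (default 0.05).
#' @param ... passed between methods.
#' @return An object of class `cda`: list with `coefficients`
#'   (p x s matrix of unstandardized canonical coefficients plus a
#'   `constant` row), `eigenvalues`, `n_retained`, `wilks`, `chi2`, `dof`,
#'   `p_values`, `centroids` (group means in canonical space), `confusion`
#'   (training classification table), `means`, `features`, `labels`, `n`,
#'   `alpha`.
#' @examples
#' tab <- generate_feature_table(g = 3, n_per_group = 24,
#'                               centroid_separation = 8, seed = 1)
#' model <- fit_cda(tab$features, tab$labels)
#' model$n_retained
#' @export
fit_cda <- function(x, ...) UseMethod("fit_cda")

#' Formula interface to canonical discriminant analysis
#'
#' @param x a formula such as `group ~ .` or
#'   `group ~ energy + entropy + idm`.
#' @param data data frame holding features and the group column.
#' @param alpha significance level for function retention.
#' @param ... unused.
#' @rdname fit_cda
#' @export
fit_cda.formula <- function(x, data, alpha = 0.05, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.pass)
  labels <- mf[[1L]]
  feats <- mf[-1L]
  fit_cda(feats, labels, alpha = alpha)
}

#' @rdname fit_cda
#' @export
fit_cda.data.frame <- function(x, labels, alpha = 0.05, ...) {
  if (length(labels) != nrow(x)) stop("'labels' length must match rows of 'x'")
  X <- as.matrix(x)
  if (!is.numeric(X)) stop("features must be numeric")
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with undefined feature values dropped")
    X <- X[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2L) stop("need at least 2 groups")
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("every group needs at least 2 observations; offending: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  n <- nrow(X); p <- ncol(X)
  grand <- colMeans(X)
  W <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  B <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  means <- matrix(NA_real_, g, p, dimnames = list(levels(labels), colnames(X)))
  for (lev in levels(labels)) {
    Xi <- X[labels == lev, , drop = FALSE]
    mi <- colMeans(Xi)
    means[lev, ] <- mi
    W <- W + crossprod(sweep(Xi, 2, mi))
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  qrW <- qr(W)
  if (qrW$rank < p) {
    bad <- colnames(X)[qrW$pivot[(qrW$rank + 1L):p]]
    stop("within-group scatter is singular; collinear feature(s): ",
         paste(bad, collapse = ", "))
  }
  s <- min(p, g - 1L)
  eig <- eigen(solve(W, B))
  lam <- Re(eig$values)
  ord <- order(lam, decreasing = TRUE)
  lam <- pmax(lam[ord][seq_len(s)], 0)
  A <- Re(eig$vectors)[, ord[seq_len(s)], drop = FALSE]
  # scale so pooled within-group variance of each canonical score is 1
  Sw <- W / (n - g)
  for (k in seq_len(s)) {
    v <- sqrt(drop(crossprod(A[, k], Sw %*% A[, k])))
    A[, k] <- A[, k] / v
    # sign convention: largest-magnitude coefficient positive
    if (A[which.max(abs(A[, k])), k] < 0) A[, k] <- -A[, k]
  }
  dimnames(A) <- list(colnames(X), paste0("CF", seq_len(s)))
  const <- -drop(crossprod(A, grand))
  wilks <- chi2 <- dof <- pv <- numeric(s)
  for (m in 0:(s - 1L)) {
    L <- prod(1 / (1 + lam[(m + 1L):s]))
    ch <- -(n - 1 - (p + g) / 2) * log(L)
    df <- (p - m) * (g - 1L - m)
    wilks[m + 1L] <- L
    chi2[m + 1L] <- ch
    dof[m + 1L] <- df
    pv[m + 1L] <- stats::pchisq(ch, df, lower.tail = FALSE)
  }
  n_retained <- sum(pv < alpha)
  centroids <- sweep(means %*% A, 2, const, `+`)
  model <- structure(
    list(coefficients = rbind(A, constant = const),
         eigenvalues = lam, n_retained = n_retained,
         wilks = wilks, chi2 = chi2, dof = dof, p_values = pv,
         centroids = centroids, means = means,
         features = colnames(X), labels = labels, n = n, n_groups = g,
         alpha = alpha),
    class = "cda")
  model$confusion <- error_rate(model,
                                cbind(as.data.frame(X),
                                      .group = labels))$confusion
  model
}

#' @export
print.cda <- function(x, digits = 4, ...) {
  s <- length(x$eigenvalues)
  cat(sprintf(
    "Canonical discriminant analysis: %d groups, %d features, n = %d\n",
    x$n_groups, length(x$features), x$n))
  cat(sprintf("%d candidate function(s), %d retained at alpha = %g\n",
              s, x$n_retained, x$alpha))
  tab <- data.frame(eigenvalue = x$eigenvalues, wilks_lambda = x$wilks,
                    chi_square = x$chi2, df = x$dof, p_value = x$p_values)
  rownames(tab) <- paste0("through CF", seq_len(s))
  print(signif(tab, digits))
  invisible(x)
}

#' @export
summary.cda <- function(object, ...) {
  structure(list(model = object), class = "summary.cda")
}

#' @export
print.summary.cda <- function(x, digits = 4, ...) {
  m <- x$model
  print(m, digits = digits)
  cat("\nUnstandardized canonical coefficients:\n")
  print(signif(m$coefficients, digits))
  cat("\nGroup centroids in canonical space:\n")
  print(signif(m$centroids, digits))
  cat("\nTraining confusion table (rows = true groups):\n")
  print(m$confusion)
  er <- 1 - sum(diag(m$confusion)) / sum(m$confusion)
  cat(sprintf("Training (resubstitution) error rate: %.4f\n", er))
  invisible(x)
}

#' @export
coef.cda <- function(object, ...) object$coefficients

cda_project <- function(model, rows, n_fun = NULL) {
  rows <- as.data.frame(rows)
  if (!all(model$features %in% names(rows)))
    stop("feature mismatch: need columns ",
         paste(model$features, collapse = ", "))
  X <- as.matrix(rows[, model$features, drop = FALSE])
  A <- model$coefficients[model$features, , drop = FALSE]
  const <- model$coefficients["constant", ]
  sc <- sweep(X %*% A, 2, const, `+`)
  if (!is.null(n_fun)) sc <- sc[, seq_len(n_fun), drop = FALSE]
  sc
}

#' Classify feature rows with a fitted discriminant model
#'
#' Projects rows onto the retained canonical functions (at least one
#' function is always used) and assigns each row to the group with the
#' nearest centroid in canonical space — Euclidean distance, equal priors.
#' Exact ties break deterministically to the lexicographically smallest
#' group label.
#'
#' @param model a fitted [fit_cda()] model.
#' @param rows data frame containing the model's feature columns.
#' @return Factor of predicted group labels.
#' @export
classify <- function(model, rows) {
  stopifnot(inherits(model, "cda"))
  n_fun <- max(1L, model$n_retained)
  sc <- cda_project(model, rows, n_fun)
  cen <- model$centroids[, seq_len(n_fun), drop = FALSE]
  lev <- sort(rownames(cen))  # lexicographic order for deterministic ties
  cen <- cen[lev, , drop = FALSE]
  d2 <- outer(rowSums(sc^2), rep(1, nrow(cen))) -
    2 * sc %*% t(cen) + outer(rep(1, nrow(sc)), rowSums(cen^2))
  idx <- apply(d2, 1L, function(r) which(r <= min(r) + 1e-12)[1L])
  factor(lev[idx], levels = levels(model$labels))
}

#' @export
predict.cda <- function(object, newdata, ...) classify(object, newdata)

#' Resubstitution (or held-out) classification error
#'
#' Classifies a labelled feature table with a fitted discriminant model and
#' tabulates per-group and overall misclassification rates. Applied to the
#' training table this is the resubstitution (training-data) error rate.
#'
#' @param model a fitted [fit_cda()] model.
#' @param table data frame with the model's feature columns plus a group
#'   column (`label_col`).
#' @param label_col name of the group column (default `".group"`).
#' @param loo if `TRUE`, compute leave-one-out error instead by refitting
#'   the model without each row in turn (slow; diagnostic only).
#' @return List with `confusion` (rows = true groups, columns = predicted),
#'   `per_group` misclassification rates, `overall` rate.
#' @export
error_rate <- function(model, table, label_col = ".group", loo = FALSE) {
  stopifnot(inherits(model, "cda"))
  if (!label_col %in% names(table))
    stop("no label column '", label_col, "' in table")
  truth <- factor(table[[label_col]], levels = levels(model$labels))
  feats <- table[, model$features, drop = FALSE]
  if (loo) {
    pred <- factor(rep(NA_character_, nrow(table)),
                   levels = levels(model$labels))
    for (i in seq_len(nrow(table))) {
      m_i <- fit_cda(feats[-i, , drop = FALSE], truth[-i],
                     alpha = model$alpha)
      pred[i] <- classify(m_i, feats[i, , drop = FALSE])
    }
  } else {
    pred <- classify(model, feats)
  }
  confusion <- table(truth = truth, predicted = pred)
  per_group <- 1 - diag(confusion) / pmax(rowSums(confusion), 1L)
  list(confusion = confusion, per_group = per_group,
       overall = 1 - sum(diag(confusion)) / sum(confusion))
}

#' Canonical scores for plotting
#'
#' Scores of each row on the first two canonical functions, plus the group
#' centroids, for the standard discriminant scatter diagram. If only one
#' candidate function exists the second coordinate is zero-padded and
#' flagged.
#'
#' @param model a fitted [fit_cda()] model.
#' @param table data frame with the model's feature columns (and optionally
#'   a label column carried through).
#' @param label_col optional group column name carried into the output.
#' @return List with `scores` (data frame: CF1, CF2, group if available),
#'   `centroids`, and `padded` (TRUE if CF2 was zero-filled).
#' @export
canonical_scores <- function(model, table, label_col = ".group") {
  stopifnot(inherits(model, "cda"))
  sc <- cda_project(model, table)
  padded <- ncol(sc) < 2L
  if (padded) sc <- cbind(sc, CF2 = 0)
  out <- data.frame(CF1 = sc[, 1L], CF2 = sc[, 2L])
  if (label_col %in% names(table)) out$group <- table[[label_col]]
  cen <- model$centroids
  if (ncol(cen) < 2L) cen <- cbind(cen, CF2 = 0)
  list(scores = out, centroids = cen[, 1:2, drop = FALSE], padded = padded)
}

#' @export
plot.cda <- function(x, table = NULL, label_col = ".group", ...) {
  if (is.null(table))
    table <- data.frame(as.data.frame(x$means)[x$labels, , drop = FALSE],
                        check.names = FALSE)
  cs <- canonical_scores(x, table, label_col)
  grp <- if (!is.null(cs$scores$group)) factor(cs$scores$group) else
    factor(rep(1, nrow(cs$scores)))
  graphics::plot(cs$scores$CF1, cs$scores$CF2, col = as.integer(grp),
                 pch = 19, xlab = "Canonical function 1",
                 ylab = "Canonical function 2", ...)
  graphics::points(cs$centroids[, 1L], cs$centroids[, 2L], pch = 3, cex = 2,
                   lwd = 2)
  invisible(x)
}
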