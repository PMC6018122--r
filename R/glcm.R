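#' Offset for a canonical co-occurrence direction
#'
#' Angle-to-offset map with the image row axis pointing down:
#' 0 deg -> (0, d); 45 deg -> (-d, d); 90 deg -> (-d, 0); 135 deg -> (-d, -d).
#' @noRd
glcm_offset <- function(distance, angle) {
  d <- as.integer(distance)
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135 degrees"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs (x, x + offset) lying fully inside the image
#' at the given displacement distance and angle, and normalizes the counts
#' to a probability matrix p(i, j). With `symmetric = TRUE` (the default)
#' pairs are counted in both directions, so the matrix equals its own
#' transpose; a one-directional mode is kept for comparison with
#' single-direction implementations. Only pairs with both pixels inside the
#' image are counted: no padding, one matrix per whole image.
#'
#' @param img a [gray_image].
#' @param distance displacement in pixels, at least 1.
#' @param angle direction in degrees, one of 0, 45, 90, 135.
#' @param symmetric count pairs in both directions (default `TRUE`).
#' @return An object of class `glcm`: list with `probs` (an
#'   `n_levels x n_levels` matrix summing to 1), `counts`, `n_pairs`,
#'   `distance`, `angle`, `symmetric`, `n_levels`.
#' @examples
#' img <- gray_image(matrix(c(0, 0, 2, 2, 0, 0, 2, 2, 1, 1, 2, 3,
#'                            1, 1, 2, 3), 4, 4), n_levels = 4)
#' compute_glcm(img, distance = 1, angle = 0)$counts
#' @export
compute_glcm <- function(img, distance = 3L, angle = 0, symmetric = TRUE) {
  stopifnot(inherits(img, "gray_image"))
  if (distance < 1L) stop("'distance' must be >= 1")
  off <- glcm_offset(distance, angle)
  h <- img$height; w <- img$width
  rows <- seq_len(h); cols <- seq_len(w)
  r1 <- rows[rows + off[1L] >= 1L & rows + off[1L] <= h]
  c1 <- cols[cols + off[2L] >= 1L & cols + off[2L] <= w]
  if (length(r1) == 0L || length(c1) == 0L)
    stop("image too small for distance ", distance, " at angle ", angle)
  a <- as.vector(img$pixels[r1, c1, drop = FALSE])
  b <- as.vector(img$pixels[r1 + off[1L], c1 + off[2L], drop = FALSE])
  ng <- img$n_levels
  counts <- matrix(tabulate(a * ng + b + 1L, nbins = ng * ng),
                   ng, ng, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  structure(
    list(probs = counts / n_pairs, counts = counts, n_pairs = n_pairs,
         distance = as.integer(distance), angle = angle,
         symmetric = symmetric, n_levels = ng),
    class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm> %d x %d, d = %d, angle = %s deg, %s, %d pairs\n",
    x$n_levels, x$n_levels, x$distance, format(x$angle),
    if (x$symmetric) "symmetric" else "one-directional", x$n_pairs))
  invisible(x)
}

#' Marginal means and spreads of a co-occurrence matrix
#'
#' Row/column marginal moments of p(i, j): means
#' `ux = sum i p(i,j)`, `uy = sum j p(i,j)` and the corresponding
#' second central sums. The text convention for the spreads is ambiguous
#' between a variance and a standard deviation; both are returned
#' (`var_x`, `var_y` and their square roots `sd_x`, `sd_y`) and the
#' correlation feature chooses between them via its `correlation_mode`.
#'
#' @param m a [glcm] (any normalized co-occurrence matrix object).
#' @return List with `ux`, `uy`, `var_x`, `var_y`, `sd_x`, `sd_y`.
#' @export
glcm_marginals <- function(m) {
  p <- m$probs
  ng <- nrow(p)
  i <- matrix(seq_len(ng) - 1, ng, ng)        # row index = first gray level
  j <- t(i)
  ux <- sum(i * p); uy <- sum(j * p)
  vx <- sum((i - ux)^2 * p); vy <- sum((j - uy)^2 * p)
  list(ux = ux, uy = uy, var_x = vx, var_y = vy,
       sd_x = sqrt(vx), sd_y = sqrt(vy))
}

#' Co-occurrence texture features
#'
#' The five second-order texture parameters of a normalized co-occurrence
#' matrix p(i, j):
#' \describe{
#'   \item{energy}{angular second moment `sum p^2`, global homogeneity,
#'     in (0, 1] with 1 iff a single cell carries all mass;}
#'   \item{inertia}{contrast `sum (i-j)^2 p`, large for high-contrast
#'     texture;}
#'   \item{correlation}{`(sum ij p - ux uy) / (sx sy)`; with the default
#'     `correlation_mode = "rooted"` the denominators are marginal standard
#'     deviations, giving the standard Haralick correlation bounded in
#'     [-1, 1]; `"literal"` divides by the second central sums themselves
#'     (no square root). Undefined (`NA`) when a marginal spread is zero;}
#'   \item{idm}{inverse difference moment `sum p / (1 + (i-j)^2)`, local
#'     homogeneity in (0, 1];}
#'   \item{entropy}{`-sum p log p` over nonzero cells; natural log by
#'     default, `log_base = 2` switches to bits.}
#' }
#'
#' @param m a [glcm].
#' @param correlation_mode `"rooted"` (default, standard deviations) or
#'   `"literal"` (second central sums as printed).
#' @param log_base base of the entropy logarithm (default `exp(1)`).
#' @return An object of class `glcm_features`: list with `energy`,
#'   `inertia`, `correlation`, `idm`, `entropy` plus the protocol metadata
#'   fields `distance`, `angle`, `symmetric`, `correlation_mode`,
#'   `log_base`, `n_levels`.
#' @export
glcm_features <- function(m, correlation_mode = c("rooted", "literal"),
                          log_base = exp(1)) {
  correlation_mode <- match.arg(correlation_mode)
  p <- m$probs
  ng <- nrow(p)
  i <- matrix(seq_len(ng) - 1, ng, ng)
  j <- t(i)
  mar <- glcm_marginals(m)
  energy <- sum(p^2)
  inertia <- sum((i - j)^2 * p)
  denom <- if (correlation_mode == "rooted") mar$sd_x * mar$sd_y
           else mar$var_x * mar$var_y
  correlation <- if (denom > 0) (sum(i * j * p) - mar$ux * mar$uy) / denom
                 else NA_real_
  idm <- sum(p / (1 + (i - j)^2))
  nz <- p > 0
  entropy <- -sum(p[nz] * log(p[nz], base = log_base))
  structure(
    list(energy = energy, inertia = inertia, correlation = correlation,
         idm = idm, entropy = entropy,
         distance = m$distance, angle = m$angle, symmetric = m$symmetric,
         correlation_mode = correlation_mode, log_base = log_base,
         n_levels = m$n_levels),
    class = "glcm_features")
}

#' @export
print.glcm_features <- function(x, digits = 4, ...) {
  cat(sprintf("Co-occurrence texture features (d = %d, angle = %s)\n",
              x$distance, format(x$angle)))
  v <- unlist(x[c("energy", "inertia", "correlation", "idm", "entropy")])
  print(signif(v, digits))
  invisible(x)
}

#' @export
as.data.frame.glcm_features <- function(x, ...) {
  data.frame(energy = x$energy, inertia = x$inertia,
             correlation = x$correlation, idm = x$idm, entropy = x$entropy)
}

#' Four-angle co-occurrence features (acquisition protocol)
#'
#' Computes the co-occurrence features at all four canonical angles
#' (0, 45, 90, 135 degrees) and averages them, so that no directional
#' arrangement on the deposit surface is favored. The default averages
#' feature values across angles (`average = "features"`); matrix-level
#' averaging (`average = "matrix"`, pool the four probability matrices then
#' compute features once) is available for comparison — the two differ for
#' correlation and entropy.
#'
#' @param img a [gray_image].
#' @param distance displacement in pixels; the acquisition protocol value
#'   is 3, the default.
#' @param symmetric,correlation_mode,log_base passed to [compute_glcm()]
#'   and [glcm_features()].
#' @param average `"features"` (default) or `"matrix"`.
#' @return A `glcm_features` object with `angle = "mean(0,45,90,135)"`.
#' @export
glcm_features_protocol <- function(img, distance = 3L, symmetric = TRUE,
                                   correlation_mode = c("rooted", "literal"),
                                   log_base = exp(1),
                                   average = c("features", "matrix")) {
  correlation_mode <- match.arg(correlation_mode)
  average <- match.arg(average)
  angles <- c(0, 45, 90, 135)
  mats <- lapply(angles, function(a)
    compute_glcm(img, distance = distance, angle = a, symmetric = symmetric))
  if (average == "matrix") {
    pooled <- mats[[1L]]
    pooled$counts <- Reduce(`+`, lapply(mats, `[[`, "counts"))
    pooled$n_pairs <- sum(pooled$counts)
    pooled$probs <- pooled$counts / pooled$n_pairs
    pooled$angle <- "mean(0,45,90,135)"
    return(glcm_features(pooled, correlation_mode, log_base))
  }
  feats <- lapply(mats, glcm_features,
                  correlation_mode = correlation_mode, log_base = log_base)
  avg <- feats[[1L]]
  for (nm in c("energy", "inertia", "correlation", "idm", "entropy"))
    avg[[nm]] <- mean(vapply(feats, `[[`, numeric(1), nm))
  avg$angle <- "mean(0,45,90,135)"
  avg
}
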