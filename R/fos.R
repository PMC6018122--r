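#' Gray-level histogram
#'
#' Normalized histogram H(g) = n_g / N over the image's gray levels, the
#' basis of all first-order statistics.
#'
#' @param img a [gray_image].
#' @return An object of class `gray_histogram`: list with `probs` (length
#'   `n_levels`, sums to 1), `n_pixels`, `n_levels`.
#' @export
compute_histogram <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  n <- length(img$pixels)
  counts <- tabulate(as.vector(img$pixels) + 1L, nbins = img$n_levels)
  structure(list(probs = counts / n, n_pixels = n, n_levels = img$n_levels),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("<gray_histogram> %d levels over %d pixels; %d levels occupied\n",
              x$n_levels, x$n_pixels, sum(x$probs > 0)))
  invisible(x)
}

#' First-order statistics of a gray-level image
#'
#' The five histogram-based texture parameters: mean, standard deviation,
#' integrated density (mean times pixel count), skewness and excess
#' kurtosis. Moments are population moments (N denominator) computed over
#' the normalized histogram; skewness and kurtosis divide by powers of the
#' standard deviation and are reported as `NA` for a constant image, where
#' they are undefined.
#'
#' Integrated density is computed over the analyzed region (after any
#' crop), and that region's pixel count is carried in the result.
#'
#' @param img a [gray_image].
#' @return An object of class `fos_features`: list with `mean`, `std`,
#'   `integrated_density`, `skewness`, `kurtosis_excess`, and bookkeeping
#'   `n_pixels`, `n_levels`.
#' @examples
#' img <- gray_image(matrix(c(0, 0, 255, 255), 2, 2))
#' compute_fos(img)   # mean 127.5, std 127.5, skewness 0, excess kurtosis -2
#' @export
compute_fos <- function(img) {
  h <- compute_histogram(img)
  g <- seq_len(h$n_levels) - 1
  mu <- sum(g * h$probs)
  v <- sum((g - mu)^2 * h$probs)
  sd_ <- sqrt(v)
  if (sd_ > 0) {
    skew <- sum((g - mu)^3 * h$probs) / sd_^3
    kurt <- sum((g - mu)^4 * h$probs) / sd_^4 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  structure(
    list(mean = mu, std = sd_, integrated_density = mu * h$n_pixels,
         skewness = skew, kurtosis_excess = kurt,
         n_pixels = h$n_pixels, n_levels = h$n_levels),
    class = "fos_features")
}

#' @export
print.fos_features <- function(x, digits = 4, ...) {
  cat("First-order texture statistics\n")
  v <- unlist(x[c("mean", "std", "integrated_density",
                  "skewness", "kurtosis_excess")])
  print(signif(v, digits))
  invisible(x)
}

#' @export
as.data.frame.fos_features <- function(x, ...) {
  data.frame(mean = x$mean, std = x$std,
             integrated_density = x$integrated_density,
             skewness = x$skewness, kurtosis_excess = x$kurtosis_excess)
}
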