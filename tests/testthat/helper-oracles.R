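# Independent brute-force oracles used across the suite. These are written
# as plain loops, deliberately sharing no code with the package internals.

# direction -> (row, col) step for the four canonical angles, image row
# axis pointing down (same published convention the package documents)
oracle_offset <- function(angle, d) {
  if (angle == 0) c(0, d)
  else if (angle == 45) c(-d, d)
  else if (angle == 90) c(-d, 0)
  else if (angle == 135) c(-d, -d)
  else stop("bad angle")
}

# enumerate every ordered pixel pair one by one and count co-occurrences
oracle_glcm_counts <- function(px, ng, d, angle, symmetric = TRUE) {
  off <- oracle_offset(angle, d)
  C <- matrix(0, ng, ng)
  for (r in seq_len(nrow(px))) {
    for (c in seq_len(ncol(px))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(px) && c2 >= 1 && c2 <= ncol(px)) {
        i <- px[r, c]; j <- px[r2, c2]
        C[i + 1, j + 1] <- C[i + 1, j + 1] + 1
        if (symmetric) C[j + 1, i + 1] <- C[j + 1, i + 1] + 1
      }
    }
  }
  C
}

# feature sums term by term from a normalized matrix
oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  energy <- 0; inertia <- 0; idm <- 0; entropy <- 0
  ux <- 0; uy <- 0; sxy <- 0
  for (i in 0:(ng - 1)) for (j in 0:(ng - 1)) {
    pij <- p[i + 1, j + 1]
    energy <- energy + pij^2
    inertia <- inertia + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    if (pij > 0) entropy <- entropy - pij * log(pij)
    ux <- ux + i * pij
    uy <- uy + j * pij
    sxy <- sxy + i * j * pij
  }
  vx <- 0; vy <- 0
  for (i in 0:(ng - 1)) for (j in 0:(ng - 1)) {
    pij <- p[i + 1, j + 1]
    vx <- vx + (i - ux)^2 * pij
    vy <- vy + (j - uy)^2 * pij
  }
  corr <- if (vx > 0 && vy > 0) (sxy - ux * uy) / sqrt(vx * vy) else NA_real_
  list(energy = energy, inertia = inertia, correlation = corr,
       idm = idm, entropy = entropy, ux = ux, uy = uy, vx = vx, vy = vy)
}

# population moments straight from the flat pixel list, no histogram
oracle_fos <- function(px) {
  v <- as.numeric(px)
  m <- mean(v)
  sd_ <- sqrt(mean((v - m)^2))
  list(mean = m, std = sd_, integrated_density = m * length(v),
       skewness = if (sd_ > 0) mean((v - m)^3) / sd_^3 else NA_real_,
       kurtosis_excess = if (sd_ > 0) mean((v - m)^4) / sd_^4 - 3
                         else NA_real_)
}

# exhaustive three-segment least-squares segmentation
oracle_segment3 <- function(y) {
  n <- length(y)
  sse <- function(z) sum((z - mean(z))^2)
  best <- Inf; bb <- c(NA, NA)
  for (b1 in 1:(n - 2)) for (b2 in (b1 + 1):(n - 1)) {
    s <- sse(y[1:b1]) + sse(y[(b1 + 1):b2]) + sse(y[(b2 + 1):n])
    if (s < best) { best <- s; bb <- c(b1, b2) }
  }
  list(boundaries = bb, score = best)
}

rand_img <- function(h, w, ng = 16) {
  gray_image(matrix(sample(0:(ng - 1), h * w, replace = TRUE), h, w),
             n_levels = ng)
}
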