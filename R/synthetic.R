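with_seed <- function(seed, code) {
  # run code under a fixed RNG state, restoring the caller's stream
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic droplet deposit
#'
#' Parameters of the stylized deposit images used to exercise the texture
#' pipeline: a dark background, a disc of dried material, a bright
#' coffee-ring annulus at the disc edge, Poisson-placed bright crystals of
#' mixed shapes, and additive Gaussian acquisition noise, quantized to
#' 8-bit. The crystals are deliberately stylized (single speckles, line
#' segments for needles, plus-shaped stars, random-walk branches for
#' dendrites): the generator targets controlled texture statistics, not
#' photorealism.
#'
#' @param size image dimensions `c(height, width)` in pixels.
#' @param background gray level outside the deposit disc.
#' @param disc_intensity gray level of the deposit interior.
#' @param ring_intensity gray level of the coffee-ring annulus.
#' @param ring_width annulus width in pixels.
#' @param crystal_density expected crystal count per pixel of disc area
#'   (the "salt" knob).
#' @param crystal_kinds named mixture weights over
#'   `speckle`, `needle`, `star`, `dendrite`.
#' @param crystal_intensity mean gray level of crystal pixels.
#' @param noise_sd standard deviation of additive Gaussian noise, in gray
#'   levels.
#' @param seed RNG seed; the same spec and seed always yield the identical
#'   image.
#' @return An object of class `deposit_spec`.
#' @export
deposit_spec <- function(size = c(96L, 96L), background = 10,
                         disc_intensity = 60, ring_intensity = 200,
                         ring_width = 5, crystal_density = 0.004,
                         crystal_kinds = c(speckle = 0.25, needle = 0.25,
                                           star = 0.25, dendrite = 0.25),
                         crystal_intensity = 225, noise_sd = 4, seed = 1L) {
  if (crystal_density < 0) stop("'crystal_density' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(size) != 2L || any(size < 16L))
    stop("'size' must be two dimensions of at least 16 pixels")
  kinds <- c("speckle", "needle", "star", "dendrite")
  if (!all(names(crystal_kinds) %in% kinds) || sum(crystal_kinds) <= 0)
    stop("'crystal_kinds' must be non-negative weights over ",
         paste(kinds, collapse = "/"))
  structure(list(size = as.integer(size), background = background,
                 disc_intensity = disc_intensity,
                 ring_intensity = ring_intensity, ring_width = ring_width,
                 crystal_density = crystal_density,
                 crystal_kinds = crystal_kinds / sum(crystal_kinds),
                 crystal_intensity = crystal_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "deposit_spec")
}

# pixel coordinates of one crystal, as a (rows, cols) list around (r0, c0)
crystal_pixels <- function(kind, r0, c0) {
  switch(kind,
    speckle = {
      list(r = r0 + c(0L, 0L, 1L, 1L), c = c0 + c(0L, 1L, 0L, 1L))
    },
    needle = {
      th <- stats::runif(1, 0, pi)
      t <- seq(-4, 4)
      list(r = r0 + round(t * sin(th)), c = c0 + round(t * cos(th)))
    },
    star = {
      arm <- seq(-3L, 3L)
      list(r = c(r0 + arm, rep(r0, 7L)), c = c(rep(c0, 7L), c0 + arm))
    },
    dendrite = {
      steps <- sample(1:4, 18L, replace = TRUE)
      dr <- c(0L, cumsum(c(-1L, 1L, 0L, 0L)[steps]))
      dc <- c(0L, cumsum(c(0L, 0L, -1L, 1L)[steps]))
      list(r = r0 + dr, c = c0 + dc)
    })
}

# internal renderer shared by the deposit and evaporation generators;
# assumes the RNG state is already set by the caller
render_deposit <- function(spec, ring_scale = 1, haze = NULL,
                           crystals = NULL, reveal = 1) {
  h <- spec$size[1L]; w <- spec$size[2L]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  R <- 0.45 * min(h, w)
  dist <- sqrt((rr - ctr[1L])^2 + (cc - ctr[2L])^2)
  img <- matrix(spec$background, h, w)
  disc <- dist <= R
  img[disc] <- spec$disc_intensity
  ring <- dist <= R & dist >= R - spec$ring_width
  img[ring] <- spec$background +
    ring_scale * (spec$ring_intensity - spec$background)
  if (!is.null(haze)) img[disc] <- img[disc] + haze[disc]
  if (!is.null(crystals) && length(crystals) > 0L) {
    n_show <- ceiling(reveal * length(crystals))
    for (cry in crystals[seq_len(n_show)]) {
      ok <- cry$r >= 1L & cry$r <= h & cry$c >= 1L & cry$c <= w
      idx <- cbind(cry$r[ok], cry$c[ok])
      img[idx] <- pmax(img[idx], cry$value)
    }
  }
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
  gray_image(matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w),
             256L, "synthetic")
}

# sample the crystal population for a spec (positions in disc, shapes, values)
sample_crystals <- function(spec) {
  h <- spec$size[1L]; w <- spec$size[2L]
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  R <- 0.45 * min(h, w)
  area <- pi * R^2
  n <- stats::rpois(1L, spec$crystal_density * area)
  if (n == 0L) return(list())
  kinds <- sample(names(spec$crystal_kinds), n, replace = TRUE,
                  prob = spec$crystal_kinds)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    # rejection sampling keeps centers inside the disc; overlaps allowed
    repeat {
      r0 <- sample.int(h, 1L); c0 <- sample.int(w, 1L)
      if ((r0 - ctr[1L])^2 + (c0 - ctr[2L])^2 <= R^2) break
    }
    px <- crystal_pixels(kinds[i], r0, c0)
    px$kind <- kinds[i]
    px$value <- min(255, max(0, round(
      spec$crystal_intensity + stats::rnorm(1, 0, 15))))
    out[[i]] <- px
  }
  out
}

#' Generate one synthetic deposit image
#'
#' Renders the deposit described by a [deposit_spec()]: disc, coffee ring,
#' Poisson-placed crystals, then Gaussian noise clipped to `[0, 255]` and
#' quantized, mirroring 8-bit acquisition. Deterministic under the spec's
#' seed.
#'
#' @param spec a [deposit_spec()].
#' @return A [gray_image] with attributes `n_crystals` (realized crystal
#'   count) and `crystal_kinds` (realized kind table).
#' @export
generate_deposit <- function(spec) {
  stopifnot(inherits(spec, "deposit_spec"))
  with_seed(spec$seed, {
    crystals <- sample_crystals(spec)
    img <- render_deposit(spec, crystals = crystals)
    attr(img, "n_crystals") <- length(crystals)
    attr(img, "crystal_kinds") <-
      table(vapply(crystals, `[[`, character(1), "kind"))
    img
  })
}

#' Specification of a synthetic condition series
#'
#' Maps a pseudo-concentration grid `x` to crystal density through the
#' saturating exponential `density(x) = D_s - D_0 exp(-x / k_true)`, so the
#' measured texture response across the series inherits the exponential
#' law and its characteristic concentration can be recovered by
#' [fit_texture_law()]. Defaults emulate a salt sweep from a bare surface
#' (`density(0) = 0` when `D_0 = D_s`) to saturation near the top of the
#' grid.
#'
#' @param x condition grid, strictly increasing, non-negative.
#' @param D0,k_true,Ds mapping parameters; `density(x)` must be
#'   non-negative on the grid.
#' @param n_rep replicate images per condition; defaults to 24, the
#'   replicate count of the laboratory design this emulates.
#' @param base_spec [deposit_spec()] whose `crystal_density` is overridden
#'   per condition.
#' @param seed series-level seed; per-image seeds are derived from it.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(x = c(0, 0.05, 0.1, 0.2, 0.35, 0.6, 1.0),
                        D0 = 0.012, k_true = 0.25, Ds = 0.012,
                        n_rep = 24L, base_spec = deposit_spec(),
                        seed = 1L) {
  if (any(diff(x) <= 0) || any(x < 0))
    stop("'x' must be non-negative and strictly increasing")
  dens <- Ds - D0 * exp(-x / k_true)
  if (any(dens < 0)) stop("density mapping is negative on the grid")
  structure(list(x = x, D0 = D0, k_true = k_true, Ds = Ds,
                 n_rep = as.integer(n_rep), base_spec = base_spec,
                 seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a synthetic condition series of deposit images
#'
#' @param spec a [series_spec()].
#' @return List with `images` (list of [gray_image]) and `manifest`
#'   (data frame: condition, rep, seed, true_density, n_crystals, plus the
#'   mapping ground truth `D0`, `k_true`, `Ds` as attributes).
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  images <- list()
  rows <- list()
  idx <- 0L
  for (i in seq_along(spec$x)) {
    dens <- spec$Ds - spec$D0 * exp(-spec$x[i] / spec$k_true)
    for (j in seq_len(spec$n_rep)) {
      idx <- idx + 1L
      s <- spec$base_spec
      s$crystal_density <- dens
      s$seed <- spec$seed + 977L * i + j
      img <- generate_deposit(s)
      img$source_id <- sprintf("synthetic_x%g_rep%d", spec$x[i], j)
      images[[idx]] <- img
      rows[[idx]] <- data.frame(condition = spec$x[i], rep = j,
                                seed = s$seed, true_density = dens,
                                n_crystals = attr(img, "n_crystals"))
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "truth") <- c(D0 = spec$D0, k_true = spec$k_true,
                               Ds = spec$Ds)
  list(images = images, manifest = manifest)
}

#' Generate a synthetic evaporation sequence with known stage boundaries
#'
#' Emulates the three formation stages seen during droplet drying: first
#' the coffee ring brightens (stage 1), then crystals accrete cumulatively
#' (stage 2), and finally the residual noisy water haze clears from the
#' disc (stage 3). The haze is a fixed speckle field (a bright water film
#' with pixel-scale roughness) present through stages 1-2 and gone from
#' the first stage-3 frame on — residual water evaporates quickly — so
#' texture statistics shift sharply at both true boundaries. Returns the
#' true boundaries for segmentation recovery tests.
#'
#' @param spec a [deposit_spec()]; its `crystal_density` sets the stage-2
#'   crystal load (sequences default to a dense deposit if the spec keeps
#'   the [deposit_spec()] default).
#' @param n_frames total frame count.
#' @param stage_plan frame counts of the three stages; must sum to
#'   `n_frames`, each at least 2.
#' @param haze_sd standard deviation of the haze speckle (gray levels).
#' @param haze_offset mean brightness of the water film (gray levels).
#' @return List with `sequence` (a [frame_sequence]), `boundaries`
#'   (1-based indices of the last frame of stages 1 and 2), and
#'   `stage_labels`.
#' @export
generate_evaporation_sequence <- function(spec = deposit_spec(
                                            crystal_density = 0.03),
                                          n_frames = 24L,
                                          stage_plan = c(8L, 8L, 8L),
                                          haze_sd = 12, haze_offset = 30) {
  stopifnot(inherits(spec, "deposit_spec"))
  stage_plan <- as.integer(stage_plan)
  if (length(stage_plan) != 3L || sum(stage_plan) != n_frames ||
      any(stage_plan < 2L))
    stop("'stage_plan' must be three counts of at least 2 summing to n_frames")
  with_seed(spec$seed, {
    h <- spec$size[1L]; w <- spec$size[2L]
    haze <- matrix(haze_offset + stats::rnorm(h * w, 0, haze_sd), h, w)
    crystals <- sample_crystals(spec)
    frames <- vector("list", n_frames)
    s1 <- stage_plan[1L]; s2 <- stage_plan[2L]; s3 <- stage_plan[3L]
    for (f in seq_len(n_frames)) {
      if (f <= s1) {                      # coffee ring forms
        ring_scale <- min(1, f / 2)
        frames[[f]] <- render_deposit(spec, ring_scale = ring_scale,
                                      haze = haze)
      } else if (f <= s1 + s2) {          # crystals accrete
        j <- f - s1
        reveal <- 0.6 + 0.4 * j / s2
        frames[[f]] <- render_deposit(spec, haze = haze,
                                      crystals = crystals, reveal = reveal)
      } else {                            # water haze has evaporated
        frames[[f]] <- render_deposit(spec, crystals = crystals, reveal = 1)
      }
    }
    list(sequence = frame_sequence(frames),
         boundaries = c(s1, s1 + s2),
         stage_labels = c("coffee_ring", "crystal_growth", "water_drying"))
  })
}

#' Generate a labelled multivariate feature table
#'
#' Draws multivariate normal feature rows per group with identity
#' within-group covariance and group centroids separated by a stated
#' multiple of the within-group standard deviation, for discriminant-model
#' testing. With `centroid_separation = 0` the table is an exact null
#' (all groups share one population).
#'
#' @param g number of groups (at least 2).
#' @param n_per_group observations per group (the laboratory design used
#'   24 replicates per condition; fewer than 2 triggers a warning and will
#'   fail downstream fitting).
#' @param centroid_separation distance of each group centroid from the
#'   origin, in within-group standard deviation units; group `j` is
#'   displaced along feature axis `((j - 1) mod n_features) + 1`.
#' @param n_features number of features; when 10, columns carry the ten
#'   texture-parameter names.
#' @param seed RNG seed.
#' @return List with `features` (data frame), `labels` (factor), and
#'   `centroids` (true group means).
#' @export
generate_feature_table <- function(g = 5L, n_per_group = 24L,
                                   centroid_separation = 10,
                                   n_features = 10L, seed = 1L) {
  if (g < 2L) stop("need at least 2 groups")
  if (n_per_group < 2L)
    warning("n_per_group < 2: downstream discriminant fitting will fail")
  nm <- if (n_features == 10L)
    c("mean", "std", "integrated_density", "skewness", "kurtosis_excess",
      "energy", "inertia", "correlation", "idm", "entropy")
  else paste0("f", seq_len(n_features))
  cen <- matrix(0, g, n_features,
                dimnames = list(paste0("grp", seq_len(g)), nm))
  for (j in seq_len(g))
    cen[j, ((j - 1L) %% n_features) + 1L] <- centroid_separation
  with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(g), function(j)
      matrix(MASS::mvrnorm(n_per_group, cen[j, ], diag(n_features)),
             nrow = n_per_group)))
    labels <- factor(rep(rownames(cen), each = n_per_group))
    df <- as.data.frame(X)
    names(df) <- nm
    list(features = df, labels = labels, centroids = cen)
  })
}
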