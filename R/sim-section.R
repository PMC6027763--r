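# Synthetic multi-channel section generator.
#
# Object classes and their shapes:
#   plaque     -- radially decaying disc with a bright core (ThioS channel)
#   tangle     -- flame-like soma approximated by an anisotropic Gaussian
#                 thresholded at half maximum (a rotated ellipse)
#   lipofuscin -- small bright granule present in EVERY channel
#   thread     -- random-walk polyline dilated to thread width
#   nucleus    -- disc in the nuclear channel
# Overlaps between classes are resolved by the fixed priority order above
# (earlier classes claim pixels), so the emitted ground-truth masks are
# mutually disjoint and the per-class true area fractions are exact pixel
# counts by construction.

CLASS_PRIORITY <- c("plaque", "tangle", "lipofuscin", "thread", "nucleus")

# ---- rasterizers: return integer pixel indices (column-major) -----------

disc_idx <- function(cy, cx, r, nr, nc) {
  y0 <- max(1L, floor(cy - r)); y1 <- min(nr, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(nc, ceiling(cx + r))
  ys <- y0:y1; xs <- x0:x1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  keep <- which(d2 <= r^2, arr.ind = TRUE)
  list(idx = (xs[keep[, 2]] - 1L) * nr + ys[keep[, 1]],
       dist = sqrt(d2[keep]))
}

ellipse_idx <- function(cy, cx, a, b, theta, nr, nc) {
  r <- max(a, b)
  y0 <- max(1L, floor(cy - r)); y1 <- min(nr, ceiling(cy + r))
  x0 <- max(1L, floor(cx - r)); x1 <- min(nc, ceiling(cx + r))
  ys <- y0:y1; xs <- x0:x1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- which((u / a)^2 + (v / b)^2 <= 1)
  yy <- ((keep - 1L) %% length(ys)) + 1L
  xx <- ((keep - 1L) %/% length(ys)) + 1L
  (xs[xx] - 1L) * nr + ys[yy]
}

thread_idx <- function(y0, x0, length_px, width_px, nr, nc) {
  n_steps <- max(2L, ceiling(length_px))
  ang <- runif(1, 0, 2 * pi) + cumsum(rnorm(n_steps, 0, 0.25))
  ys <- pmin(pmax(y0 + cumsum(sin(ang)), 1), nr)
  xs <- pmin(pmax(x0 + cumsum(cos(ang)), 1), nc)
  r <- max(width_px / 2, 0.71)  # at least one pixel wide after rounding
  idx <- integer(0)
  for (i in seq_len(n_steps))
    idx <- c(idx, disc_idx(ys[i], xs[i], r, nr, nc)$idx)
  unique(idx)
}

# ---- candidate object draw ----------------------------------------------

draw_object <- function(class, params, nr, nc) {
  px <- params$pixel_size_um
  switch(class,
    plaque = {
      d <- runif(1, params$plaque_diameter_um[1],
                 params$plaque_diameter_um[2]) / px
      r <- d / 2
      m <- min(r + 1, (min(nr, nc) - 1) / 2)
      cy <- runif(1, 1 + m, nr - m); cx <- runif(1, 1 + m, nc - m)
      dd <- disc_idx(cy, cx, r, nr, nc)
      # bright core out to half the radius, then linear falloff to 0.6
      prof <- ifelse(dd$dist <= r / 2, 1, 1 - 0.8 * (dd$dist / r - 0.5))
      list(idx = dd$idx, profile = prof)
    },
    tangle = {
      d <- runif(1, params$tangle_diameter_um[1],
                 params$tangle_diameter_um[2]) / px
      ratio <- runif(1, 2, 3)
      theta <- runif(1, 0, pi)
      a <- d / 2; b <- d / (2 * ratio)
      m <- min(a + 1, (min(nr, nc) - 1) / 2)
      cy <- runif(1, 1 + m, nr - m); cx <- runif(1, 1 + m, nc - m)
      idx <- ellipse_idx(cy, cx, a, b, theta, nr, nc)
      list(idx = idx, profile = rep(1, length(idx)))
    },
    lipofuscin = {
      d <- runif(1, params$lipofuscin_diameter_um[1],
                 params$lipofuscin_diameter_um[2]) / px
      cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
      dd <- disc_idx(cy, cx, max(d / 2, 0.6), nr, nc)
      list(idx = dd$idx, profile = rep(1, length(dd$idx)))
    },
    thread = {
      L <- runif(1, params$thread_length_um[1],
                 params$thread_length_um[2]) / px
      w <- runif(1, params$thread_width_um[1],
                 params$thread_width_um[2]) / px
      idx <- thread_idx(runif(1, 1, nr), runif(1, 1, nc), L, w, nr, nc)
      list(idx = idx, profile = rep(1, length(idx)))
    },
    nucleus = {
      d <- runif(1, params$nucleus_diameter_um[1],
                 params$nucleus_diameter_um[2]) / px
      cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
      dd <- disc_idx(cy, cx, d / 2, nr, nc)
      list(idx = dd$idx, profile = rep(1, length(dd$idx)))
    })
}

# ---- noise and illumination ---------------------------------------------

illumination_gradient <- function(nr, nc, amplitude) {
  if (amplitude == 0) return(matrix(0, nr, nc))
  X <- outer(rep(1, nr), seq(-1, 1, length.out = nc))
  Y <- outer(seq(-1, 1, length.out = nr), rep(1, nc))
  cf <- runif(5, -1, 1)
  G <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * X^2 + cf[5] * Y^2
  amplitude * G / max(abs(G))
}

# Shot noise (Poisson with poisson_scale photons per intensity unit) is
# applied as its variance-matched Gaussian approximation: at the photon
# counts simulated (>= background_level * poisson_scale, i.e. >= 100 at
# the defaults) the approximation is indistinguishable from exact Poisson
# draws and an order of magnitude faster. Read noise adds in quadrature.
apply_noise <- function(pixels, poisson_scale, gaussian_sd, maxval) {
  var_total <- gaussian_sd^2 +
    if (poisson_scale > 0) pixels / poisson_scale else 0
  if (any(var_total > 0))
    pixels <- pixels + sqrt(var_total) *
      matrix(rnorm(length(pixels)), nrow(pixels))
  matrix(as.numeric(round(pmin(pmax(pixels, 0), maxval))), nrow(pixels))
}

# ---- generator ----------------------------------------------------------

#' Generate one synthetic multi-channel section
#'
#' Places objects class by class in priority order (plaque, tangle,
#' lipofuscin, thread, nucleus). For classes with a numeric burden target,
#' candidate objects are accepted while they move the realized area
#' fraction closer to the target, so the emitted ground truth tracks the
#' target to within about half an object; for `NA` targets the fixed
#' count from `params` is placed. Renders the four channels (signal,
#' autofluorescence, nuclear, thios) with a shared low-order polynomial
#' illumination gradient, Poisson shot noise and Gaussian read noise.
#' Lipofuscin granules appear at `af_intensity` in every channel; tangles
#' appear in the ThioS channel at
#' `tangle_thios_brightness_factor * signal_intensity`.
#'
#' Deterministic for fixed `(params, burden, seed)`; the caller's RNG
#' state is left untouched.
#'
#' @param params A [section_sim_params()].
#' @param burden A [stage_burden_profile()].
#' @param seed Integer seed.
#' @return A `simulated_section`: list with `channels` (named list of
#'   [channel_image] by role), `ground_truth` (list with `masks`, a named
#'   list of logical matrices, and `true_area_fraction`, exact pixel-count
#'   fractions), `seed` and `params`.
#' @export
generate_section <- function(params = section_sim_params(),
                             burden = stage_burden_profile(),
                             seed = 1L) {
  stopifnot(inherits(params, "section_sim_params"),
            inherits(burden, "stage_burden_profile"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  nr <- params$image_size_px[1]; nc <- params$image_size_px[2]
  npx <- nr * nc
  counts <- c(plaque = params$n_plaques, tangle = params$n_tangles,
              lipofuscin = params$n_lipofuscin, thread = params$n_threads,
              nucleus = params$n_nuclei)

  occupied <- matrix(FALSE, nr, nc)
  masks <- list()
  layer <- list()   # per-class intensity profile (0..~1.15 with jitter)
  for (class in CLASS_PRIORITY) {
    mask <- matrix(FALSE, nr, nc)
    lay <- matrix(0, nr, nc)
    target <- burden$fractions[[class]]
    if (is.na(target)) {
      for (i in seq_len(counts[[class]])) {
        ob <- draw_object(class, params, nr, nc)
        new <- !occupied[ob$idx] & !mask[ob$idx]
        mask[ob$idx[new]] <- TRUE
        lay[ob$idx[new]] <- ob$profile[new] * runif(1, 0.85, 1.15)
      }
    } else if (target > 0) {
      frac <- 0
      fails <- 0L
      while (frac < target && fails < 8L) {
        ob <- draw_object(class, params, nr, nc)
        new <- ob$idx[!occupied[ob$idx] & !mask[ob$idx]]
        gain <- length(new) / npx
        if (abs(frac + gain - target) < abs(frac - target)) {
          mask[new] <- TRUE
          lay[new] <- ob$profile[match(new, ob$idx)] * runif(1, 0.85, 1.15)
          frac <- frac + gain
          fails <- 0L
        } else fails <- fails + 1L
      }
    }
    occupied <- occupied | mask
    masks[[class]] <- mask
    layer[[class]] <- lay
  }

  base <- params$background_level *
    (1 + illumination_gradient(nr, nc, params$gradient_amplitude))
  af_lay <- params$af_intensity * layer$lipofuscin
  si <- params$signal_intensity
  raw <- list(
    signal = base + si * (layer$tangle + layer$thread) + af_lay,
    autofluorescence = base + af_lay,
    nuclear = base + 0.6 * si * layer$nucleus + af_lay,
    thios = base + si * layer$plaque +
      params$tangle_thios_brightness_factor * si * layer$tangle + af_lay
  )
  maxval <- 65535
  channels <- lapply(names(raw), function(role) {
    channel_image(apply_noise(raw[[role]], params$poisson_scale,
                              params$gaussian_sd, maxval),
                  role = role, pixel_size_um = params$pixel_size_um,
                  bit_depth = 16L)
  })
  names(channels) <- names(raw)

  gt <- list(masks = masks,
             true_area_fraction = vapply(masks, function(m) sum(m) / npx,
                                         numeric(1)))
  structure(list(channels = channels, ground_truth = gt,
                 seed = as.integer(seed), params = params,
                 group = burden$group),
            class = "simulated_section")
}

#' @export
print.simulated_section <- function(x, ...) {
  cat(sprintf("<simulated_section> %d x %d px, %.3g um/px, seed %d\n",
              x$params$image_size_px[1], x$params$image_size_px[2],
              x$params$pixel_size_um, x$seed))
  fr <- x$ground_truth$true_area_fraction
  cat("  true area fractions:",
      paste(sprintf("%s %.4f", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}
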