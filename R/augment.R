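# Training-time data augmentation. Geometric transforms (flip, scale) are
# applied identically to the image and both targets; photometric transforms
# (contrast, blur, noise) touch the image only. Each transform fires
# independently with its configured probability.

#' Augmentation configuration
#'
#' Application probabilities default to the 0.25-0.3 band; any value in
#' `[0, 1]` may be set explicitly.
#'
#' @param p_flip,p_contrast,p_scale,p_blur,p_noise per-transform application
#'   probabilities.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(p_flip = 0.3, p_contrast = 0.3, p_scale = 0.25,
                           p_blur = 0.25, p_noise = 0.25) {
  p <- list(p_flip = p_flip, p_contrast = p_contrast, p_scale = p_scale,
            p_blur = p_blur, p_noise = p_noise)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  class(p) <- "augment_config"
  p
}

resize_plane <- function(x, nh, nw, nearest = FALSE) {
  as.matrix(EBImage::resize(x, w = nh, h = nw,
                            filter = if (nearest) "none" else "bilinear"))
}

# Center-crop or zero-pad a matrix back to (H, W).
fit_to <- function(x, H, W) {
  h <- nrow(x); w <- ncol(x)
  if (h > H) {
    off <- (h - H) %/% 2
    x <- x[(off + 1):(off + H), , drop = FALSE]
  }
  if (ncol(x) > W) {
    off <- (ncol(x) - W) %/% 2
    x <- x[, (off + 1):(off + W), drop = FALSE]
  }
  if (nrow(x) < H || ncol(x) < W) {
    out <- matrix(0, H, W)
    oh <- (H - nrow(x)) %/% 2
    ow <- (W - ncol(x)) %/% 2
    out[(oh + 1):(oh + nrow(x)), (ow + 1):(ow + ncol(x))] <- x
    x <- out
  }
  x
}

#' Augment an image and its target pair
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param dmap distance-target matrix (same shape).
#' @param cmap integer class-target matrix (same shape; resampled with
#'   nearest-neighbour interpolation).
#' @param cfg an [augment_config()].
#' @param seed optional integer; when given, the draw is made reproducible
#'   and the caller's RNG state is left untouched.
#' @return List with elements `image`, `dmap`, `cmap`.
#' @export
augment <- function(image, dmap, cmap, cfg = augment_config(), seed = NULL) {
  stopifnot(inherits(cfg, "augment_config"),
            identical(dim(image), dim(dmap)),
            identical(dim(image), dim(cmap)))
  run <- function() {
    H <- nrow(image); W <- ncol(image)
    if (runif(1) < cfg$p_flip) {
      if (runif(1) < 0.5) {
        image <- image[H:1, , drop = FALSE]
        dmap <- dmap[H:1, , drop = FALSE]
        cmap <- cmap[H:1, , drop = FALSE]
      } else {
        image <- image[, W:1, drop = FALSE]
        dmap <- dmap[, W:1, drop = FALSE]
        cmap <- cmap[, W:1, drop = FALSE]
      }
    }
    if (runif(1) < cfg$p_scale) {
      s <- runif(1, 0.9, 1.1)
      nh <- max(8L, round(H * s)); nw <- max(8L, round(W * s))
      image <- fit_to(resize_plane(image, nh, nw), H, W)
      dmap <- fit_to(clamp(resize_plane(dmap, nh, nw), 0, 1), H, W)
      cmap <- fit_to(resize_plane(cmap + 0, nh, nw, nearest = TRUE), H, W)
      storage.mode(cmap) <- "integer"
    }
    if (runif(1) < cfg$p_contrast) {
      gamma <- exp(runif(1, -0.35, 0.35))
      image <- clamp(image, 0, 1)^gamma
    }
    if (runif(1) < cfg$p_blur) {
      image <- as.matrix(EBImage::gblur(image, sigma = runif(1, 0.5, 1.5)))
    }
    if (runif(1) < cfg$p_noise) {
      image <- image + rnorm(length(image), 0, runif(1, 0.01, 0.05))
    }
    list(image = clamp(image, 0, 1), dmap = dmap, cmap = cmap)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
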