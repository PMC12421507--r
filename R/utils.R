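# Shared internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic package operations route through
# this so that a single integer seed makes them bit-reproducible.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Min-max normalize a matrix to [0, 1]; a constant plane maps to all zeros.
minmax_norm <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite intensities")
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 8- or 4-connected component labelling of a logical matrix.
label_components <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "logical"
  cpp_label_components(mask, as.integer(connectivity))
}

# Centroids (row, col) of each positive label; rows named by label.
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  out <- t(vapply(ids, function(k) {
    w <- which(labels == k, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  dimnames(out) <- list(as.character(ids), c("row", "col"))
  out
}

# Bounding box (rmin, rmax, cmin, cmax) of a logical mask, grown by `pad`
# and clipped to the image.
mask_bbox <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  c(
    max(1L, min(w[, 1]) - pad), min(nrow(mask), max(w[, 1]) + pad),
    max(1L, min(w[, 2]) - pad), min(ncol(mask), max(w[, 2]) + pad)
  )
}

# Relabel positive labels densely to 1..K preserving label order.
relabel_dense <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) return(labels)
  out <- labels
  out[labels > 0] <- match(labels[labels > 0], ids)
  out
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}
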