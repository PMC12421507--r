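# Brute-force oracles and shared fixtures. The oracles deliberately use
# naive O(N^2) algorithms independent of the package implementation.

# Euclidean distance of each pixel of `mask` to the nearest complement
# pixel, with out-of-grid counting as complement (per-pixel exhaustive
# search over a grid padded with one background ring).
brute_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  bg <- which(!pad, arr.ind = TRUE)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!mask[i, j]) next
      out[i, j] <- sqrt(min((bg[, 1] - (i + 1))^2 + (bg[, 2] - (j + 1))^2))
    }
  }
  out
}

# Brute-force per-instance normalized distance target.
brute_distance_target <- function(labels) {
  out <- matrix(0, nrow(labels), ncol(labels))
  for (k in sort(unique(labels[labels > 0]))) {
    m <- labels == k
    d <- brute_edt(m)
    out[m] <- d[m] / max(d)
  }
  out
}

# Brute-force border/interior/background map: per instance pixel, scan all
# complement pixels for the distance rule and the 8-neighbourhood for
# adjacency to a different instance.
brute_border_target <- function(labels, bw) {
  h <- nrow(labels); w <- ncol(labels)
  out <- matrix(0L, h, w)
  out[labels > 0] <- 1L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      k <- labels[i, j]
      if (k == 0) next
      d <- brute_edt(labels == k)[i, j]
      isb <- d <= bw
      if (!isb) {
        for (di in -1:1) for (dj in -1:1) {
          ni <- i + di; nj <- j + dj
          if (ni < 1 || ni > h || nj < 1 || nj > w) next
          if (labels[ni, nj] > 0 && labels[ni, nj] != k) isb <- TRUE
        }
      }
      if (isb) out[i, j] <- 2L
    }
  }
  out
}

# Dice loss recomputed with explicit loops.
brute_dice <- function(pred, target, eps = 1e-6) {
  C <- dim(pred)[3]
  acc <- 0
  for (c in seq_len(C)) {
    num <- eps; denp <- 0; dent <- 0
    for (i in seq_len(nrow(target))) {
      for (j in seq_len(ncol(target))) {
        p <- pred[i, j, c]
        t <- as.numeric(target[i, j] == c - 1)
        num <- num + 2 * p * t
        denp <- denp + p
        dent <- dent + t
      }
    }
    acc <- acc + num / (denp + dent + eps)
  }
  1 - acc / C
}

# Random small label image: a few discs/rectangles stamped in order (later
# instances may touch or overwrite earlier ones).
random_label_image <- function(h = 24, w = 24, n = 4) {
  lab <- matrix(0L, h, w)
  for (k in seq_len(n)) {
    if (runif(1) < 0.5) {
      r <- sample(2:4, 1)
      ci <- sample(seq_len(h), 1); cj <- sample(seq_len(w), 1)
      ii <- pmax(1, ci - r):pmin(h, ci + r)
      jj <- pmax(1, cj - r):pmin(w, cj + r)
      d2 <- outer((ii - ci)^2, (jj - cj)^2, `+`)
      sub <- lab[ii, jj, drop = FALSE]
      sub[d2 <= r^2] <- k
      lab[ii, jj] <- sub
    } else {
      a <- sample(2:5, 1); b <- sample(2:5, 1)
      i0 <- sample(seq_len(h - a), 1); j0 <- sample(seq_len(w - b), 1)
      lab[i0:(i0 + a), j0:(j0 + b)] <- k
    }
  }
  lab
}

# Exact label-permutation equality of two instance label images.
labels_match_exact <- function(truth, rec) {
  tids <- sort(unique(truth[truth > 0]))
  rids <- sort(unique(rec[rec > 0]))
  if (length(tids) != length(rids)) return(FALSE)
  for (k in tids) {
    m <- truth == k
    rl <- unique(rec[m])
    if (length(rl) != 1 || rl == 0) return(FALSE)
    if (!identical(unname(m), unname(rec == rl))) return(FALSE)
  }
  TRUE
}

one_hot3 <- function(cmap) {
  out <- array(0, dim = c(nrow(cmap), ncol(cmap), 3))
  for (c in 1:3) out[, , c] <- (cmap == c - 1) + 0
  out
}

# Instance-level F1 between predicted and truth label images at IoU >= 0.5
# with greedy one-to-one matching.
instance_f1_counts <- function(truth, pred) {
  tids <- sort(unique(truth[truth > 0]))
  pids <- sort(unique(pred[pred > 0]))
  used <- integer(0)
  tp <- 0L
  for (k in tids) {
    m <- truth == k
    best <- 0; bj <- 0L
    for (j in setdiff(pids, used)) {
      pj <- pred == j
      iou <- sum(m & pj) / sum(m | pj)
      if (iou > best) { best <- iou; bj <- j }
    }
    if (best >= 0.5) { tp <- tp + 1L; used <- c(used, bj) }
  }
  c(tp = tp, fp = length(pids) - tp, fn = length(tids) - tp)
}

# ---------------------------------------------------------------------------
# Study-condition fixtures: four simulated conditions varying EV load, noise
# and border sparsity, six training scenes each (plus held-out scenes).

fixture_scenes <- function(seeds_per_cond) {
  out <- list()
  for (ci in 1:4) {
    for (s in seeds_per_cond[[ci]]) {
      sc <- generate_scene(condition_params(ci, s))
      out[[length(out) + 1L]] <- list(frame = sc$frame, truth = sc$truth)
    }
  }
  out
}

fixture_train_seeds <- function() lapply(1:4, function(ci) 100 * ci + 1:6)
fixture_test_seeds <- function() lapply(1:4, function(ci) 100 * ci + 51:53)

# One model trained on the 24-scene fixture, shared across test files.
.fixture_cache <- new.env(parent = emptyenv())
trained_fixture_run <- function() {
  if (is.null(.fixture_cache$run)) {
    ds <- fixture_scenes(fixture_train_seeds())
    .fixture_cache$run <- train_model(
      ds, model_config(depth = 2L, base_features = 16L),
      aug_cfg = augment_config(), epochs = 50L, seed = 42L
    )
  }
  .fixture_cache$run
}
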