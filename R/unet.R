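# Dual-branch U-Net implemented from first principles: an encoder-decoder
# with 3x3 convolutions (Rcpp/Armadillo kernels), 2x2 max-pooling, nearest
# neighbour upsampling and skip connections, ending in two 1x1 heads -- a
# sigmoid-bounded distance-regression plane and a 3-class softmax
# (background / interior / border). Backpropagation and the Adam optimizer
# are written out explicitly; everything is deterministic given the seed in
# single-threaded BLAS.

#' Dual U-Net model configuration
#'
#' @param depth number of resolution levels (>= 2); spatial dimensions are
#'   halved `depth - 1` times.
#' @param base_features feature maps at the first level (>= 8); doubled at
#'   each deeper level.
#' @param in_channels input image channels (the aggregated channel is 1).
#' @param n_classes categorical-branch classes (background/interior/border).
#' @param loss_weights named numeric `(reg, cls)` weights of the two branch
#'   losses.
#' @param cls_loss `"dice_ce"` (default) uses Dice plus a
#'   frequency-weighted cross-entropy term in the categorical branch --
#'   the per-pixel CE term is what sharpens the rare border pixels between
#'   blur-merged EV puncta; `"dice"` uses pure Dice.
#' @param beta smooth-L1 transition point of the regression branch.
#' @param eps Dice smoothing constant.
#' @return An object of class `model_config`.
#' @export
model_config <- function(depth = 2L, base_features = 16L, in_channels = 1L,
                         n_classes = 3L, loss_weights = c(reg = 1, cls = 1),
                         cls_loss = c("dice_ce", "dice"), beta = 1,
                         eps = 1e-6) {
  cls_loss <- match.arg(cls_loss)
  cfg <- list(
    depth = as.integer(depth), base_features = as.integer(base_features),
    in_channels = as.integer(in_channels), n_classes = as.integer(n_classes),
    loss_weights = c(reg = unname(loss_weights["reg"]),
                     cls = unname(loss_weights["cls"])),
    cls_loss = cls_loss, beta = beta, eps = eps
  )
  stopifnot(cfg$depth >= 2L, cfg$base_features >= 8L,
            all(cfg$loss_weights > 0), cfg$beta > 0)
  class(cfg) <- "model_config"
  cfg
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Initialize a dual U-Net
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return A list of class `unet_model` with elements `cfg` and `params`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_local_seed(seed, {
    feats <- cfg$base_features * 2^(seq_len(cfg$depth) - 1L)
    enc <- vector("list", cfg$depth)
    for (d in seq_len(cfg$depth)) {
      cin <- if (d == 1L) cfg$in_channels else feats[d - 1L]
      enc[[d]] <- list(
        W1 = he_init(9L * cin, feats[d]), b1 = numeric(feats[d]),
        W2 = he_init(9L * feats[d], feats[d]), b2 = numeric(feats[d])
      )
    }
    dec <- vector("list", max(cfg$depth - 1L, 0L))
    for (d in seq_len(cfg$depth - 1L)) {
      cin <- feats[d + 1L] + feats[d]
      dec[[d]] <- list(
        W1 = he_init(9L * cin, feats[d]), b1 = numeric(feats[d]),
        W2 = he_init(9L * feats[d], feats[d]), b2 = numeric(feats[d])
      )
    }
    params <- list(
      enc = enc, dec = dec,
      head_reg = list(W = he_init(feats[1], 1L), b = numeric(1L)),
      head_cls = list(W = he_init(feats[1], cfg$n_classes),
                      b = numeric(cfg$n_classes))
    )
    structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
              class = "unet_model")
  })
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. `x` must have spatial dims divisible by 2^(depth-1).
# Returns list(reg = H x W in [0,1], cls = H x W x n_classes simplex,
# cache = activations for backprop when requested).
unet_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg; P <- model$params
  H <- nrow(x); W <- ncol(x)
  m <- 2^(cfg$depth - 1L)
  if (H %% m != 0L || W %% m != 0L) {
    stop(sprintf("input %dx%d not divisible by %d", H, W, m))
  }
  cur <- array(as.numeric(x), dim = c(H, W, cfg$in_channels))
  enc_acts <- vector("list", cfg$depth)
  cache <- list(enc = vector("list", cfg$depth),
                dec = vector("list", max(cfg$depth - 1L, 0L)))
  for (d in seq_len(cfg$depth)) {
    z1 <- cpp_conv3_fwd(cur, P$enc[[d]]$W1, P$enc[[d]]$b1)
    a1 <- relu(z1)
    z2 <- cpp_conv3_fwd(a1, P$enc[[d]]$W2, P$enc[[d]]$b2)
    a2 <- relu(z2)
    enc_acts[[d]] <- a2
    if (keep_cache) {
      cache$enc[[d]] <- list(inp = cur, a1 = a1, m1 = z1 > 0, m2 = z2 > 0)
    }
    if (d < cfg$depth) {
      mp <- cpp_maxpool2_fwd(a2)
      if (keep_cache) {
        cache$enc[[d]]$poolidx <- mp$idx
        cache$enc[[d]]$preH <- dim(a2)[1]
        cache$enc[[d]]$preW <- dim(a2)[2]
      }
      cur <- mp$y
    }
  }
  cur <- enc_acts[[cfg$depth]]
  for (d in rev(seq_len(cfg$depth - 1L))) {
    up <- cpp_upsample2(cur)
    skip <- enc_acts[[d]]
    cat_in <- array(c(up, skip),
                    dim = c(dim(up)[1], dim(up)[2],
                            dim(up)[3] + dim(skip)[3]))
    z1 <- cpp_conv3_fwd(cat_in, P$dec[[d]]$W1, P$dec[[d]]$b1)
    a1 <- relu(z1)
    z2 <- cpp_conv3_fwd(a1, P$dec[[d]]$W2, P$dec[[d]]$b2)
    a2 <- relu(z2)
    if (keep_cache) {
      cache$dec[[d]] <- list(inp = cat_in, a1 = a1, m1 = z1 > 0, m2 = z2 > 0,
                             c_up = dim(up)[3])
    }
    cur <- a2
  }
  F1 <- dim(cur)[3]
  X <- matrix(cur, H * W, F1)
  reg_z <- drop(X %*% P$head_reg$W) + P$head_reg$b
  cls_z <- sweep(X %*% P$head_cls$W, 2, P$head_cls$b, `+`)
  reg <- matrix(sigmoid(reg_z), H, W)
  p <- softmax_rows(cls_z)
  cls <- array(p, dim = c(H, W, cfg$n_classes))
  if (keep_cache) {
    cache$X <- X
    cache$reg <- reg
    cache$p <- p
    cache$H <- H
    cache$W <- W
  }
  list(reg = reg, cls = cls, cache = if (keep_cache) cache else NULL)
}

# Backward pass. g_reg: gradient of the loss wrt the sigmoid output
# (H x W); g_cls: gradient wrt the softmax probabilities (H x W x C).
# Returns gradients with the same structure as model$params.
unet_backward <- function(model, cache, g_reg, g_cls) {
  cfg <- model$cfg; P <- model$params
  H <- cache$H; W <- cache$W; N <- H * W
  # through sigmoid and softmax
  s <- as.numeric(cache$reg)
  gz_reg <- as.numeric(g_reg) * s * (1 - s)
  Gp <- matrix(g_cls, N, cfg$n_classes)
  Pp <- cache$p
  gz_cls <- Pp * (Gp - rowSums(Gp * Pp))
  # heads
  X <- cache$X
  g <- list(
    enc = vector("list", cfg$depth),
    dec = vector("list", max(cfg$depth - 1L, 0L)),
    head_reg = list(W = crossprod(X, gz_reg), b = sum(gz_reg)),
    head_cls = list(W = crossprod(X, gz_cls), b = colSums(gz_cls))
  )
  gX <- matrix(gz_reg, ncol = 1L) %*% t(P$head_reg$W) +
    gz_cls %*% t(P$head_cls$W)
  gcur <- array(gX, dim = c(H, W, ncol(X)))
  skip_grads <- vector("list", cfg$depth)
  for (d in seq_len(cfg$depth - 1L)) {
    cc <- cache$dec[[d]]
    ga2 <- gcur
    gz2 <- ga2 * cc$m2
    b2g <- cpp_conv3_bwd(cc$a1, P$dec[[d]]$W2, gz2)
    gz1 <- b2g$gx * cc$m1
    b1g <- cpp_conv3_bwd(cc$inp, P$dec[[d]]$W1, gz1)
    g$dec[[d]] <- list(W1 = b1g$gw, b1 = b1g$gb, W2 = b2g$gw, b2 = b2g$gb)
    gcat <- b1g$gx
    c_up <- cc$c_up
    gup <- gcat[, , seq_len(c_up), drop = FALSE]
    skip_grads[[d]] <- gcat[, , -seq_len(c_up), drop = FALSE]
    gcur <- cpp_upsample2_bwd(gup)
  }
  # gcur now holds the gradient wrt enc_acts[[depth]]
  for (d in rev(seq_len(cfg$depth))) {
    cc <- cache$enc[[d]]
    ga2 <- gcur
    if (d < cfg$depth && !is.null(skip_grads[[d]])) {
      ga2 <- ga2 + skip_grads[[d]]
    }
    gz2 <- ga2 * cc$m2
    b2g <- cpp_conv3_bwd(cc$a1, P$enc[[d]]$W2, gz2)
    gz1 <- b2g$gx * cc$m1
    b1g <- cpp_conv3_bwd(cc$inp, P$enc[[d]]$W1, gz1)
    g$enc[[d]] <- list(W1 = b1g$gw, b1 = b1g$gb, W2 = b2g$gw, b2 = b2g$gb)
    if (d > 1L) {
      cp <- cache$enc[[d - 1L]]
      gcur <- cpp_maxpool2_bwd(cp$poolidx, b1g$gx, cp$preH, cp$preW)
    }
  }
  g
}

# ---------------------------------------------------------------------------
# Generic walkers over the nested parameter structure.

param_walk2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- param_walk2(a[[k]], b[[k]], f)
    out
  } else {
    f(a, b)
  }
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- param_map(a[[k]], f)
    out
  } else {
    f(a)
  }
}

adam_init <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_walk2(state$m, grads, function(m, g) beta1 * m +
                           (1 - beta1) * g)
  state$v <- param_walk2(state$v, grads, function(v, g) beta2 * v +
                           (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_walk2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- param_walk2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# Sum two gradient structures.
param_add <- function(a, b) param_walk2(a, b, `+`)
param_scale <- function(a, s) param_map(a, function(x) x * s)
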